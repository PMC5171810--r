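# Internal helpers shared across modules.

#' @useDynLib spikeinfo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd var cor cor.test ks.test quantile
#'   p.adjust coef lm
#' @importFrom utils head tail
NULL

# Deterministic sub-seed derivation. Streams keep stimulus and noise RNG
# sequences disjoint for any master seed; all products stay well below 2^53
# so the arithmetic is exact in doubles, and results stay below 2^31.
derive_seed <- function(master_seed, stream, index = 0L) {
  m <- 2147483629
  s <- (as.double(master_seed) %% m)
  ((s * 1000003 + as.double(stream) * 97561 + as.double(index) * 7919) %% m) + 1
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Trapezoidal integral on an arbitrary grid.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Plug-in (maximum likelihood) entropy of a count vector, in bits.
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

# Order-insensitive content hash for config provenance (FNV-1a over the
# serialized object), returned as a hex string.
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
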