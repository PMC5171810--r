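#' Spike auto- and cross-correlation functions
#'
#' The autocorrelation is the within-trial time-averaged lagged product of
#' the binned spike train, pooled across trials; its zero-lag bin carries
#' the `rate / bin_width` delta contribution of the point process. The
#' cross-correlation averages lagged products over *distinct* trial pairs
#' only, which makes it an unbiased estimate of the PSTH autocorrelation:
#' squaring the PSTH directly would retain a `S_auto / M` self-term that the
#' pair construction removes. Both estimates use the unbiased `1/(N - k)`
#' time normalization and are returned in Hz^2 (optionally normalized by the
#' squared rate).
#'
#' @param binned A [bin_ensemble()] result.
#' @param max_lag Largest lag, ms.
#' @param normalize If `TRUE`, divide values by the squared mean rate.
#' @return List with elements `auto` and `cross` (the latter `NULL` for
#'   fewer than 2 trials of a varying ensemble), each a `corr_fun` with
#'   fields `lags` (ms, symmetric about 0), `values`, `kind`, `rate` and
#'   `normalized`.
#' @export
estimate_correlation_functions <- function(binned, max_lag = 100,
                                           normalize = FALSE) {
  stopifnot(inherits(binned, "binned_ensemble"))
  delta <- binned$bin_width
  n_bins <- ncol(binned$counts)
  m <- nrow(binned$counts)
  n_lag <- floor(max_lag / delta)
  if (n_lag < 1 || n_lag >= n_bins) stopf("max_lag out of range")
  pad <- stats::nextn(n_bins + n_lag, 2)
  delta_s <- delta / 1000
  ff <- t(apply(binned$counts, 1, function(cc) fft(c(cc, numeric(pad - n_bins)))))
  if (m == 1) ff <- matrix(ff, nrow = 1)
  self_spec <- ff * Conj(ff)
  auto_sum <- Re(fft(colSums(self_spec), inverse = TRUE))[1:(n_lag + 1)] / pad
  denom <- (n_bins - 0:n_lag) * delta_s^2
  auto_half <- auto_sum / (m * denom)
  auto_vals <- c(rev(auto_half[-1]), auto_half)
  lags <- (-n_lag:n_lag) * delta
  mk <- function(values, kind) {
    v <- if (normalize) values / binned$rate^2 else values
    structure(list(lags = lags, values = v, kind = kind, rate = binned$rate,
                   normalized = normalize), class = "corr_fun")
  }
  out <- list(auto = mk(auto_vals, "auto"), cross = NULL)
  if (m >= 2) {
    tot <- colSums(ff)
    cross_spec <- tot * Conj(tot) - colSums(self_spec)
    cross_sum <- Re(fft(cross_spec, inverse = TRUE))[1:(n_lag + 1)] / pad
    cross_half <- cross_sum / (m * (m - 1) * denom)
    out$cross <- mk(c(rev(cross_half[-1]), cross_half), "cross")
  } else if (binned$ensemble_kind == "repeated") {
    stopf("cross-correlation requires at least 2 trials")
  }
  out
}

#' Spike power spectrum and trial cross-spectrum
#'
#' Bartlett-averaged periodograms of the binned counts. Each trial is cut
#' into non-overlapping segments of `t_seg` seconds; the total spectrum
#' `S_auto(f)` averages `|F|^2 / T` over trials and segments, and the
#' stimulus-locked cross spectrum `S_cross(f)` averages the real part of
#' cross-periodograms over *distinct* trial pairs within the same absolute
#' segment window (frozen-stimulus alignment). The normalization is anchored
#' by the Poisson convention: a homogeneous Poisson train of rate `nu` has
#' `S_auto(f) = nu` at all `f > 0`. The DC bin is excluded throughout.
#'
#' If the frozen `stimulus` trace is supplied, the spectrum additionally
#' carries `S_lin(f)`, the stimulus-locked power captured by the best linear
#' (first-order kernel) transfer from the stimulus to the trial-averaged
#' response, `|S_xr|^2 / S_xx`. This is the quantity the coherence-style
#' lower bound substitutes for the full cross spectrum (see
#' [info_lower_bound()]).
#'
#' @param binned A [bin_ensemble()] result.
#' @param t_seg Segment length, s. Frequency resolution is `1/t_seg`.
#' @param taper `"none"` (default) or `"hann"`. The Hann branch removes the
#'   per-segment mean before tapering (a tapered window is no longer
#'   orthogonal to the mean) and renormalizes by the window power.
#' @param stimulus Optional `current_trace` of the frozen stimulus component
#'   (same duration as the ensemble, any integer refinement of the bin grid).
#' @return A `spectral_pair`: `freqs` (Hz, one-sided, DC excluded),
#'   `S_auto`, `S_cross` (`NULL` unless >= 2 trials), optional `S_lin`,
#'   `rate`, `n_trials`, `n_segments`, `t_seg`, `bin_width`.
#' @export
estimate_spectra <- function(binned, t_seg = 4, taper = c("none", "hann"),
                             stimulus = NULL) {
  stopifnot(inherits(binned, "binned_ensemble"))
  taper <- match.arg(taper)
  delta_s <- binned$bin_width / 1000
  seg_bins <- round(t_seg / delta_s)
  n_bins <- ncol(binned$counts)
  m <- nrow(binned$counts)
  if (seg_bins > n_bins) stopf("t_seg exceeds the recording duration")
  if (seg_bins < 4) stopf("t_seg too short for the bin width")
  n_win <- n_bins %/% seg_bins
  n_freq <- seg_bins %/% 2
  keep <- 2:(n_freq + 1)
  win <- if (taper == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (0:(seg_bins - 1)) / (seg_bins - 1)))
    w / sqrt(mean(w^2))
  } else NULL
  stim_bins <- NULL
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "current_trace"))
    ratio <- binned$bin_width / stimulus$dt
    if (abs(ratio - round(ratio)) > 1e-8)
      stopf("stimulus dt must divide the bin width")
    ratio <- round(ratio)
    n_need <- n_bins * ratio
    if (length(stimulus$values) < n_need)
      stopf("stimulus trace shorter than the binned recording")
    stim_bins <- colMeans(matrix(stimulus$values[1:n_need], nrow = ratio))
  }
  s_auto <- numeric(n_freq)
  s_cross <- numeric(n_freq)
  lin_num <- complex(n_freq)
  lin_den <- numeric(n_freq)
  for (w_i in seq_len(n_win)) {
    cols <- ((w_i - 1) * seg_bins + 1):(w_i * seg_bins)
    seg <- binned$counts[, cols, drop = FALSE]
    if (!is.null(win)) {
      seg <- (seg - rowMeans(seg)) * rep(win, each = m)
    }
    ff <- t(apply(seg, 1, fft))[, keep, drop = FALSE]
    if (m == 1) ff <- matrix(ff, nrow = 1)
    pw <- Re(ff * Conj(ff))
    s_auto <- s_auto + colMeans(pw)
    if (m >= 2) {
      tot <- colSums(ff)
      s_cross <- s_cross + (Re(tot * Conj(tot)) - colSums(pw)) / (m * (m - 1))
    }
    if (!is.null(stim_bins)) {
      seg_s <- stim_bins[cols]
      if (!is.null(win)) seg_s <- (seg_s - mean(seg_s)) * win
      fs <- fft(seg_s)[keep]
      lin_num <- lin_num + Conj(fs) * colMeans(ff)
      lin_den <- lin_den + Re(fs * Conj(fs))
    }
  }
  t_seg_s <- seg_bins * delta_s
  out <- list(freqs = (1:n_freq) / t_seg_s,
              S_auto = s_auto / (n_win * t_seg_s),
              S_cross = if (m >= 2) s_cross / (n_win * t_seg_s) else NULL,
              S_lin = if (!is.null(stim_bins))
                Re(lin_num * Conj(lin_num)) / (lin_den * n_win * t_seg_s)
              else NULL,
              rate = binned$rate, n_trials = m, n_segments = m * n_win,
              t_seg = t_seg_s, bin_width = binned$bin_width)
  structure(out, class = "spectral_pair")
}

#' @export
print.spectral_pair <- function(x, ...) {
  cat(sprintf(paste0("<spectral_pair: %d frequencies up to %.4g Hz ",
                     "(df = %.4g Hz), %d trials, %d segments%s%s>\n"),
              length(x$freqs), max(x$freqs), 1 / x$t_seg, x$n_trials,
              x$n_segments, if (is.null(x$S_cross)) ", no cross" else "",
              if (is.null(x$S_lin)) "" else ", with S_lin"))
  invisible(x)
}

#' Export a spectral pair as a data frame
#'
#' @param x A `spectral_pair`.
#' @param row.names,optional,... S3 compatibility; unused.
#' @return Data frame with `freq_hz`, `s_auto` and (when present) `s_cross`
#'   and `s_lin` columns.
#' @export
as.data.frame.spectral_pair <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  d <- data.frame(freq_hz = x$freqs, s_auto = x$S_auto)
  if (!is.null(x$S_cross)) d$s_cross <- x$S_cross
  if (!is.null(x$S_lin)) d$s_lin <- x$S_lin
  d
}
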