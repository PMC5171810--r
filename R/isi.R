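#' Interspike-interval statistics
#'
#' Pools within-trial interspike intervals (no cross-trial intervals),
#' returning the pooled ISI list, a density histogram (Freedman-Diaconis
#' binning with a floor of 50 bins), the lag-1 serial correlation between
#' successive intervals and the coefficient of variation.
#'
#' @param ens A `spike_train_ensemble`.
#' @return An `isi_statistics` object with fields `isi_values` (s),
#'   `histogram` (data frame `mid`, `density`), `breaks`, `rho1`, `cv`,
#'   `n_isis` and `flags`.
#' @export
isi_statistics <- function(ens) {
  stopifnot(inherits(ens, "spike_train_ensemble"))
  per_trial <- lapply(ens$trains, function(tt) if (length(tt) >= 2) diff(tt)
                      else numeric(0))
  isis <- unlist(per_trial)
  if (length(isis) < 2) stopf("fewer than 2 interspike intervals in total")
  flags <- character(0)
  iqr <- stats::IQR(isis)
  fd <- if (iqr > 0) 2 * iqr / length(isis)^(1 / 3) else 0
  n_bins <- if (fd > 0) max(50, ceiling(diff(range(isis)) / fd)) else 50
  breaks <- seq(min(isis), max(isis), length.out = n_bins + 1)
  if (breaks[1] == breaks[n_bins + 1]) breaks <- breaks[1] + c(-1e-9, 1e-9)
  h <- graphics::hist(isis, breaks = breaks, plot = FALSE)
  if (sd(isis) <= 1e-7 * mean(isis)) {
    rho1 <- NA_real_
    flags <- c(flags, "rho1 undefined: zero ISI variance")
  } else {
    pairs <- do.call(rbind, lapply(per_trial, function(v) {
      if (length(v) >= 2) cbind(head(v, -1), tail(v, -1)) else NULL
    }))
    rho1 <- if (is.null(pairs) || nrow(pairs) < 2) {
      flags <- c(flags, "rho1 undefined: too few successive pairs")
      NA_real_
    } else cor(pairs[, 1], pairs[, 2])
  }
  structure(list(isi_values = isis,
                 histogram = data.frame(mid = h$mids, density = h$density),
                 breaks = h$breaks, rho1 = rho1,
                 cv = sd(isis) / mean(isis), n_isis = length(isis),
                 flags = flags),
            class = "isi_statistics")
}

#' @export
print.isi_statistics <- function(x, ...) {
  cat(sprintf("<isi_statistics: %d ISIs, mean %.4g ms, CV %.3g, rho1 %.3g>\n",
              x$n_isis, mean(x$isi_values) * 1000, x$cv, x$rho1))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
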