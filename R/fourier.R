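# Diagnostics for the Fourier statistics that underpin the spectral
# information estimate: across trials of a stationary finite-memory spike
# train, the Fourier coefficients at each frequency approach a complex
# normal distribution (Rayleigh amplitudes, uniform phases, uncorrelated
# real/imaginary parts) and are asymptotically independent across
# frequencies.

#' Trial Fourier coefficients of a spike-train ensemble
#'
#' Computes `c_i(f) = T^{-1/2} * sum_j exp(-2 pi i f t_ij)` per trial, so
#' the across-trial variance of the coefficients estimates the spike power
#' spectrum (a homogeneous Poisson train of rate `nu` gives variance `nu`
#' at every frequency).
#'
#' @param ens A `spike_train_ensemble`.
#' @param freqs Frequencies, Hz, in `(0, Nyquist]` of any later binning;
#'   the transform itself is exact for point events.
#' @param mean_correct Subtract the across-trial mean per frequency
#'   (appropriate for frozen-stimulus repeats, whose coefficients have a
#'   stimulus-locked non-zero mean).
#' @return A `fourier_ensemble`: complex `coefficients` (trials x
#'   frequencies), `freqs`, `mean_corrected`, `ensemble_kind`, `duration`.
#' @export
trial_fourier_coefficients <- function(ens, freqs, mean_correct = FALSE) {
  stopifnot(inherits(ens, "spike_train_ensemble"), length(freqs) >= 1,
            all(freqs > 0))
  if (ens$n_trials < 1 || all(lengths(ens$trains) == 0))
    stopf("empty ensemble")
  tt <- ens$duration
  co <- t(vapply(ens$trains, function(times) {
    if (!length(times)) return(complex(length(freqs)))
    vapply(freqs, function(f) sum(exp(-2i * pi * f * times)), complex(1))
  }, complex(length(freqs)))) / sqrt(tt)
  if (length(freqs) == 1) co <- matrix(co, ncol = 1)
  if (mean_correct) co <- sweep(co, 2, colMeans(co))
  structure(list(coefficients = co, freqs = freqs,
                 mean_corrected = mean_correct,
                 ensemble_kind = ens$ensemble_kind, duration = tt,
                 n_trials = ens$n_trials),
            class = "fourier_ensemble")
}

rayleigh_cdf <- function(q, scale) 1 - exp(-q^2 / (2 * scale^2))

# Rayleigh test of circular uniformity (phases).
phase_uniformity_p <- function(phi) {
  n <- length(phi)
  rbar <- Mod(mean(exp(1i * phi)))
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  min(max(p, 0), 1)
}

#' Complex-Gaussianity tests on trial Fourier coefficients
#'
#' Per frequency: (i) correlation between real and imaginary parts
#' (Pearson test), (ii) Kolmogorov-Smirnov goodness of fit of the
#' mean-corrected amplitudes against a Rayleigh distribution with fitted
#' scale, (iii) Rayleigh test of phase uniformity. P-values are
#' Benjamini-Hochberg adjusted across frequencies within each family; a
#' frequency passes a test when its adjusted p-value exceeds `level`.
#'
#' Coefficients of frozen-stimulus ensembles should be mean-corrected
#' before testing (their raw mean is stimulus-locked and non-zero).
#'
#' @param fe A [trial_fourier_coefficients()] result.
#' @param level Significance level after adjustment.
#' @return A `fourier_report`: data frame `table` (per frequency: the three
#'   adjusted p-values and pass flags) plus pass fractions in `summary`.
#' @export
gaussianity_tests <- function(fe, level = 0.01) {
  stopifnot(inherits(fe, "fourier_ensemble"))
  if (fe$n_trials < 200)
    warnf("only %d trials; the tests are underpowered below ~200", fe$n_trials)
  co <- fe$coefficients
  if (!fe$mean_corrected) co <- sweep(co, 2, colMeans(co))
  res <- t(vapply(seq_along(fe$freqs), function(k) {
    z <- co[, k]
    p_ri <- cor.test(Re(z), Im(z))$p.value
    amp <- Mod(z)
    scale_hat <- sqrt(mean(amp^2) / 2)
    p_ray <- suppressWarnings(
      ks.test(amp, rayleigh_cdf, scale = scale_hat)$p.value)
    p_phase <- phase_uniformity_p(Arg(z))
    c(p_ri, p_ray, p_phase)
  }, numeric(3)))
  tab <- data.frame(freq_hz = fe$freqs,
                    p_realimag = p.adjust(res[, 1], "BH"),
                    p_rayleigh = p.adjust(res[, 2], "BH"),
                    p_phase = p.adjust(res[, 3], "BH"))
  tab$pass_realimag <- tab$p_realimag > level
  tab$pass_rayleigh <- tab$p_rayleigh > level
  tab$pass_phase <- tab$p_phase > level
  structure(list(table = tab, level = level,
                 summary = c(realimag = mean(tab$pass_realimag),
                             rayleigh = mean(tab$pass_rayleigh),
                             phase = mean(tab$pass_phase))),
            class = "fourier_report")
}

#' @export
print.fourier_report <- function(x, ...) {
  cat(sprintf("<fourier_report: pass fractions at level %g -- real/imag %.2f, Rayleigh %.2f, phase %.2f>\n",
              x$level, x$summary["realimag"], x$summary["rayleigh"],
              x$summary["phase"]))
  invisible(x)
}

#' Cross-frequency independence of Fourier coefficients
#'
#' Across-trial complex correlation between coefficients at frequency pairs
#' separated by `delta_f`. For stationary finite-memory trains the residual
#' correlations are finite-size effects that decay with recording length.
#'
#' @param fe A [trial_fourier_coefficients()] result with >= 2 frequencies.
#' @param delta_f Frequency separation, Hz; pairs are formed between each
#'   frequency and the nearest grid frequency `delta_f` away.
#' @return Data frame with `freq_hz`, `partner_hz` and `abs_correlation`.
#' @export
independence_tests <- function(fe, delta_f) {
  stopifnot(inherits(fe, "fourier_ensemble"), length(fe$freqs) >= 2)
  co <- sweep(fe$coefficients, 2, colMeans(fe$coefficients))
  rows <- lapply(seq_along(fe$freqs), function(k) {
    target <- fe$freqs[k] + delta_f
    j <- which.min(abs(fe$freqs - target))
    if (abs(fe$freqs[j] - target) > 1e-6) return(NULL)
    if (j == k && delta_f != 0) return(NULL)
    z1 <- co[, k]
    z2 <- co[, j]
    r <- Mod(mean(z1 * Conj(z2))) /
      sqrt(mean(Mod(z1)^2) * mean(Mod(z2)^2))
    data.frame(freq_hz = fe$freqs[k], partner_hz = fe$freqs[j],
               abs_correlation = r)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no frequency pairs at separation %g Hz", delta_f)
  out
}
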