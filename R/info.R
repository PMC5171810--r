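# Information estimators. All rates are one-sided frequency integrals of the
# per-frequency density
#
#   I(f) = 1/2 * log2( S_auto(f) / (S_auto(f) - S_cross(f)) ),
#
# in bit (s Hz)^-1. The 1/2 reflects that, for stationary finite-memory
# trains, the information at each frequency is carried solely by the
# Rayleigh-distributed amplitude of the mean-corrected trial Fourier
# coefficient -- the uniform phase carries none, and the Euler-Mascheroni
# terms of the two Rayleigh differential entropies cancel in the difference.

new_info_result <- function(rate, nu, method, cutoff, diagnostics) {
  structure(list(rate = rate, per_spike = rate / nu, method = method,
                 cutoff_hz = cutoff, rate_hz = nu,
                 diagnostics = diagnostics),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("<info_result [%s]: %.4g bits/s, %.4g bits/spike (rate %.4g Hz, cutoff %.4g Hz)>\n",
              x$method, x$rate, x$per_spike, x$rate_hz, x$cutoff_hz))
  invisible(x)
}

info_density <- function(freqs, s_total, noise, cutoff, eps) {
  if (is.null(cutoff)) cutoff <- max(freqs)
  if (cutoff > max(freqs) + 1e-9)
    stopf("cutoff %g Hz exceeds the available band (%g Hz)", cutoff, max(freqs))
  keep <- freqs <= cutoff
  f <- freqs[keep]
  st <- s_total[keep]
  noise <- noise[keep]
  floor_v <- eps * st
  clipped <- noise < floor_v
  density <- 0.5 * log2(st / pmax(noise, floor_v))
  density_raw <- rep(NA_real_, length(noise))
  pos <- noise > 0
  density_raw[pos] <- 0.5 * log2(st[pos] / noise[pos])
  list(freqs = f, density = density, density_raw = density_raw,
       clipped_fraction = mean(clipped),
       rate = trapz(f, density), cutoff = cutoff)
}

#' Correlation-theory information rate
#'
#' Computes the mutual information rate between stimulus and spike train
#' from the spectral pair: per frequency, the log ratio of the total
#' Fourier-coefficient variance `S_auto` to the mean-corrected
#' repeated-trial (noise) variance `S_auto - S_cross`, integrated over the
#' one-sided frequency grid (DC excluded; under stationarity the DC bin
#' carries the mean rate, not stimulus modulation).
#'
#' Where sampling noise makes `S_auto - S_cross` non-positive, the noise
#' spectrum is floored at `eps * S_auto`; the affected fraction of
#' frequencies is reported as `clipped_fraction` and the unfloored density
#' is kept alongside (`density_raw`).
#'
#' @param sp A [estimate_spectra()] result from a repeated ensemble
#'   (supplies `S_cross`).
#' @param cutoff Integration cutoff, Hz; defaults to the Nyquist frequency
#'   of the spectral grid.
#' @param auto_from Optional second `spectral_pair` (typically from a
#'   matched varying-stimulus ensemble) whose `S_auto` replaces `sp$S_auto`
#'   in the numerator. Must share the frequency grid. The noise spectrum in
#'   the denominator is always `sp$S_auto - sp$S_cross`: estimated within
#'   the repeated ensemble, the stimulus-locked sampling fluctuations of the
#'   two terms cancel window by window (the difference is the across-trial
#'   variance around the trial mean), which keeps the log ratio unbiased at
#'   strongly locked frequencies even for modest trial counts.
#' @param eps Noise-spectrum floor, relative to `S_auto`.
#' @return List with `spectrum` (an `info_spectrum`: `freqs`, `density`,
#'   `density_raw`, `clipped_fraction`) and `result` (an `info_result`:
#'   `rate` bits/s, `per_spike` bits/spike, `method`, diagnostics).
#' @export
info_correlation_theory <- function(sp, cutoff = NULL, auto_from = NULL,
                                    eps = 1e-6) {
  stopifnot(inherits(sp, "spectral_pair"))
  if (is.null(sp$S_cross)) stopf("sp carries no cross spectrum")
  s_auto <- sp$S_auto
  if (!is.null(auto_from)) {
    stopifnot(inherits(auto_from, "spectral_pair"))
    if (length(auto_from$freqs) != length(sp$freqs) ||
        max(abs(auto_from$freqs - sp$freqs)) > 1e-9)
      stopf("auto_from is on a different frequency grid")
    s_auto <- auto_from$S_auto
  }
  d <- info_density(sp$freqs, s_auto, sp$S_auto - sp$S_cross, cutoff, eps)
  spec <- structure(list(freqs = d$freqs, density = d$density,
                         density_raw = d$density_raw,
                         clipped_fraction = d$clipped_fraction),
                    class = "info_spectrum")
  res <- new_info_result(d$rate, sp$rate, "correlation", d$cutoff,
                         list(n_trials = sp$n_trials,
                              n_segments = sp$n_segments,
                              clipped_fraction = d$clipped_fraction))
  list(spectrum = spec, result = res)
}

#' Coherence-style lower bound on the information rate
#'
#' The linear-kernel variant of the correlation-theory rate: the full cross
#' spectrum is replaced by the stimulus-locked power captured by the best
#' first-order (linear) transfer from the stimulus, `S_lin = |S_xr|^2 /
#' S_xx` (computed by [estimate_spectra()] when the frozen stimulus trace is
#' supplied). Because the linear projection can only capture part of the
#' stimulus-locked variance, `S_lin <= S_cross` up to sampling error and the
#' resulting rate is a lower bound on the full estimate, with equality for a
#' linear encoder.
#'
#' If `sp` carries no `S_lin`, the measured `S_cross` is used instead (the
#' bound then degenerates to the full estimate) and a warning is raised.
#'
#' @inheritParams info_correlation_theory
#' @return An `info_result` with `method = "lower_bound"`.
#' @export
info_lower_bound <- function(sp, cutoff = NULL, auto_from = NULL, eps = 1e-6) {
  stopifnot(inherits(sp, "spectral_pair"))
  s_locked <- sp$S_lin
  if (is.null(s_locked)) {
    if (is.null(sp$S_cross)) stopf("sp carries neither S_lin nor S_cross")
    warnf("no linear-kernel spectrum in sp; lower bound degenerates to the full estimate")
    s_locked <- sp$S_cross
  }
  s_auto <- if (!is.null(auto_from)) auto_from$S_auto else sp$S_auto
  d <- info_density(sp$freqs, s_auto, sp$S_auto - s_locked, cutoff, eps)
  new_info_result(d$rate, sp$rate, "lower_bound", d$cutoff,
                  list(n_trials = sp$n_trials, n_segments = sp$n_segments,
                       clipped_fraction = d$clipped_fraction))
}

#' PSTH-based Poisson approximation of the information rate
#'
#' Keeps the measured stimulus-locked cross spectrum but discards the
#' train's internal temporal structure by substituting the flat Poisson
#' spectrum `nu` for `S_auto` -- the information carried by an
#' inhomogeneous-Poisson surrogate with the same PSTH. Exact when the
#' spikes are conditionally Poisson; under- or overestimates the full rate
#' when genuine temporal correlations help or hurt, respectively.
#'
#' @inheritParams info_correlation_theory
#' @param nu Firing rate substituted as the flat spectrum, Hz; defaults to
#'   the ensemble mean rate.
#' @return An `info_result` with `method = "psth_poisson"`.
#' @export
info_psth_poisson <- function(sp, nu = NULL, cutoff = NULL, eps = 1e-6) {
  stopifnot(inherits(sp, "spectral_pair"))
  if (is.null(sp$S_cross)) stopf("sp carries no cross spectrum")
  if (is.null(nu)) nu <- sp$rate
  d <- info_density(sp$freqs, rep(nu, length(sp$freqs)),
                    nu - sp$S_cross, cutoff, eps)
  new_info_result(d$rate, sp$rate, "psth_poisson", d$cutoff,
                  list(n_trials = sp$n_trials, n_segments = sp$n_segments,
                       clipped_fraction = d$clipped_fraction))
}

# Plug-in entropy (bits) of ISIs over fixed bin edges.
isi_hist_entropy <- function(isis, edges) {
  idx <- findInterval(isis, edges, all.inside = TRUE)
  entropy_bits(tabulate(idx, nbins = length(edges) - 1))
}

#' Interspike-interval information rate
#'
#' Information carried by interspike intervals treated as independent
#' symbols. The total entropy comes from the pooled ISI distribution of a
#' varying-stimulus ensemble; the noise entropy is the spike-time-conditioned
#' ISI entropy in a matched frozen-stimulus ensemble: spikes are grouped by
#' their time bin within the repeated stimulus, and the entropy of the
#' following interval is estimated per group (same discretization) and
#' averaged with group weights. The difference, in bits per interval, is
#' multiplied by the firing rate to give bits per second. Both entropies are
#' extrapolated linearly in inverse data fraction to control finite-sampling
#' bias; the discretization terms cancel in the difference.
#'
#' This construction ignores serial correlations between successive
#' intervals, which is exactly why comparing it with the full
#' correlation-theory rate quantifies the information carried by those
#' correlations.
#'
#' @param ens_repeated Frozen-stimulus `spike_train_ensemble`.
#' @param ens_varying Matched varying-stimulus `spike_train_ensemble`.
#' @param isi_bins Number of equal-occupancy ISI bins (quantiles of the
#'   varying-ensemble ISIs).
#' @param t_bin Width of the spike-time conditioning bins, s. Default picks
#'   the smallest width expected to collect `min_count` intervals per bin.
#' @param min_count Minimum intervals for a conditioning bin to contribute.
#' @param fractions Data fractions used for the inverse-sample-size
#'   extrapolation.
#' @param min_isis Required number of pooled varying-ensemble intervals.
#' @return An `info_result` with `method = "isi"`; diagnostics carry group
#'   coverage and the extrapolation fits.
#' @export
info_isi <- function(ens_repeated, ens_varying, isi_bins = 32, t_bin = NULL,
                     min_count = 20, fractions = c(1, 0.5, 0.25),
                     min_isis = 1000) {
  stopifnot(inherits(ens_repeated, "spike_train_ensemble"),
            inherits(ens_varying, "spike_train_ensemble"))
  isis_var <- unlist(lapply(ens_varying$trains,
                            function(tt) if (length(tt) >= 2) diff(tt)))
  if (length(isis_var) < min_isis)
    stopf(paste("insufficient ISIs: %d pooled intervals, need >= %d;",
                "increase the varying-ensemble duration or trial count"),
          length(isis_var), min_isis)
  edges <- unique(quantile(isis_var, probs = seq(0, 1, length.out = isi_bins + 1),
                           names = FALSE))
  if (length(edges) < 9) stopf("degenerate ISI distribution: too few distinct quantiles")
  edges[1] <- -Inf
  edges[length(edges)] <- Inf

  # total entropy at decreasing data fractions (subsampled intervals)
  h_tot <- vapply(fractions, function(f) {
    sub <- if (f >= 1) isis_var else
      with_seed(round(1e5 * f) + 11L,
                sample(isis_var, max(64L, round(f * length(isis_var)))))
    isi_hist_entropy(sub, edges)
  }, numeric(1))

  # (spike time, following interval) pairs from the frozen-stimulus repeats
  pairs <- do.call(rbind, lapply(seq_along(ens_repeated$trains), function(i) {
    tt <- ens_repeated$trains[[i]]
    if (length(tt) < 2) return(NULL)
    cbind(trial = i, t = head(tt, -1), isi = diff(tt))
  }))
  if (is.null(pairs) || nrow(pairs) < min_count)
    stopf("insufficient spikes in the repeated ensemble")
  m <- ens_repeated$n_trials
  nu_rep <- ens_repeated$rate
  if (is.null(t_bin)) {
    t_bin <- max(0.002, min_count / (m * nu_rep))
    t_bin <- min(t_bin, ens_repeated$duration / 20)
  }
  grp_all <- floor(pairs[, "t"] / t_bin)

  cond_entropy <- function(trials_kept) {
    sel <- pairs[, "trial"] %in% trials_kept
    grp <- grp_all[sel]
    isi <- pairs[sel, "isi"]
    cnt <- table(grp)
    keep_g <- names(cnt)[cnt >= min_count]
    if (!length(keep_g)) return(c(NA_real_, 0))
    ink <- grp %in% as.numeric(keep_g)
    hs <- tapply(isi[ink], grp[ink], isi_hist_entropy, edges = edges)
    ws <- tapply(isi[ink], grp[ink], length)
    c(sum(hs * ws) / sum(ws), mean(ink))
  }

  h_noise <- numeric(length(fractions))
  coverage <- numeric(length(fractions))
  for (k in seq_along(fractions)) {
    f <- fractions[k]
    trials_kept <- if (f >= 1) seq_len(m) else
      with_seed(round(1e5 * f) + 23L, sample(m, max(2L, round(f * m))))
    ce <- cond_entropy(trials_kept)
    h_noise[k] <- ce[1]
    coverage[k] <- ce[2]
  }
  ok <- is.finite(h_noise)
  if (sum(ok) < 2) stopf("conditional ISI entropy could not be estimated; increase trials")
  inv <- 1 / fractions
  fit_tot <- lm(h_tot ~ inv)
  fit_noise <- lm(h_noise[ok] ~ inv[ok])
  h_tot_inf <- unname(coef(fit_tot)[1])
  h_noise_inf <- unname(coef(fit_noise)[1])
  bits_per_isi <- h_tot_inf - h_noise_inf
  nu <- ens_varying$rate
  new_info_result(nu * bits_per_isi, nu, "isi", NA_real_,
                  list(bits_per_isi = bits_per_isi, h_total = h_tot_inf,
                       h_noise = h_noise_inf, t_bin = t_bin,
                       coverage = coverage[1], n_isis = length(isis_var),
                       h_total_raw = h_tot[1], h_noise_raw = h_noise[1]))
}
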