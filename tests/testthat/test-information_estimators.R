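test_that("the spectral rate matches the Gaussian-channel closed form", {
  # smooth surrogate channel with known signal and noise spectra
  s_noise <- function(f) 12 + 3 * exp(-f / 150)
  s_sig <- function(f) 40 / (1 + (f / 30)^2)
  f <- seq(0.25, 1000, by = 0.25)
  sp <- synthetic_spectral_pair(f, s_noise(f) + s_sig(f), s_sig(f), rate = 8)
  got <- info_correlation_theory(sp)
  oracle <- stats::integrate(function(x)
    0.5 * log2((s_noise(x) + s_sig(x)) / s_noise(x)), 0.25, 1000,
    rel.tol = 1e-10)$value
  expect_equal(got$result$rate, oracle, tolerance = 0.002)
  expect_identical(got$spectrum$clipped_fraction, 0)
  expect_equal(got$result$per_spike * 8, got$result$rate)
  # no stimulus-locked structure: exactly zero information
  sp0 <- synthetic_spectral_pair(f, s_noise(f), rep(0, length(f)))
  expect_identical(info_correlation_theory(sp0)$result$rate, 0)
  # cutoff restricts the integral and rejects out-of-band requests
  expect_lt(info_correlation_theory(sp, cutoff = 100)$result$rate,
            got$result$rate)
  expect_error(info_correlation_theory(sp, cutoff = 2000), "cutoff")
})

test_that("noise-floor clipping is reported, not hidden", {
  f <- 1:100
  s_auto <- rep(10, 100)
  s_cross <- c(rep(12, 5), rep(2, 95))  # impossible locking at 5 freqs
  sp <- synthetic_spectral_pair(f, s_auto, s_cross)
  got <- info_correlation_theory(sp)
  expect_equal(got$spectrum$clipped_fraction, 0.05)
  expect_true(all(is.na(got$spectrum$density_raw[1:5])))
  expect_true(all(is.finite(got$spectrum$density)))
})

test_that("the linear-kernel bound is tight for a linear channel and below the full rate otherwise", {
  # linear Gaussian surrogate: rows = gain * stimulus + independent noise
  set.seed(42)
  n_bins <- 8000; m <- 40; dt_ms <- 0.5
  zp <- input_params("ou", tau_stim = 10, sigma_eta = 1, snr = 0, dt = 0.5,
                     duration = 4)
  stim <- generate_ou(zp, 7)
  gain <- 0.9
  counts <- t(sapply(seq_len(m), function(i)
    gain * stim$values + rnorm(n_bins, 0, 1.5)))
  fake <- structure(list(counts = counts, bin_width = dt_ms, duration = 4,
                         ensemble_kind = "repeated", n_trials = m,
                         rate = 10), class = "binned_ensemble")
  sp <- estimate_spectra(fake, t_seg = 1, stimulus = stim)
  full <- info_correlation_theory(sp)$result
  low <- info_lower_bound(sp)
  expect_equal(low$rate, full$rate, tolerance = 0.07)
  # nonlinear spiking encoder: the bound stays below the full estimate
  s <- tb_fig_setup(n_trials = 30, duration = 10, seed = 3)
  er <- build_input_ensemble(s$input, 30, "repeated", 3)
  warm <- round((s$input$duration - s$rep$duration) * 1000 / s$input$dt)
  st <- input_trace(er, 1, "stimulus")
  st$values <- sqrt(s$input$snr) * st$values[-seq_len(warm)]
  st$duration <- s$rep$duration
  spr <- estimate_spectra(bin_ensemble(s$rep), t_seg = 2, stimulus = st)
  full2 <- info_correlation_theory(spr)$result
  low2 <- info_lower_bound(spr)
  expect_lt(low2$rate, full2$rate)
  expect_gt(low2$rate, 0)
  # without a stimulus spectrum the bound degenerates with a warning
  spr_plain <- estimate_spectra(bin_ensemble(s$rep), t_seg = 2)
  expect_warning(info_lower_bound(spr_plain), "degenerates")
})

test_that("the PSTH-Poisson approximation is exact for conditionally Poisson spiking", {
  mp <- modulated_poisson(seed = 7)
  sp <- estimate_spectra(bin_ensemble(mp$rep), t_seg = 2)
  full <- info_correlation_theory(sp)$result
  pois <- info_psth_poisson(sp)
  expect_gt(full$rate, 0.3)
  expect_equal(pois$rate / full$rate, 1, tolerance = 0.15)
})

test_that("per-frequency log variance ratio equals the Rayleigh-amplitude entropy difference", {
  # nonparametric differential entropies of the amplitude distributions of
  # two zero-mean complex Gaussians; the Euler-Mascheroni terms cancel
  set.seed(5)
  s1 <- 24; s2 <- 6
  amp <- function(s, n) sqrt(s / 2) * sqrt(rnorm(n)^2 + rnorm(n)^2)
  h_amp <- function(x) {
    br <- seq(0, max(x) * 1.02, length.out = 250)
    h <- hist(x, breaks = br, plot = FALSE)
    p <- h$counts / length(x)
    keep <- p > 0
    -sum(p[keep] * log2(p[keep] / diff(br)[keep]))
  }
  n <- 2e5
  diff_h <- h_amp(amp(s1, n)) - h_amp(amp(s2, n))
  expect_equal(diff_h, 0.5 * log2(s1 / s2), tolerance = 0.02)
})

test_that("ISI information approaches the full rate when the stimulus is faster than the ISIs", {
  ip <- input_params("ou", tau_stim = 1, sigma_eta = 1, snr = 0.6,
                     duration = 50, dt = 0.05)
  nrn <- neuron_params("LIF", tau_mem = 10, v_th = 0.12, v_reset = -0.12)
  sr <- simulate_ensemble(nrn, build_input_ensemble(ip, 60, "repeated", 31))
  ipv <- ip; ipv$duration <- 100
  sv <- simulate_ensemble(nrn, build_input_ensemble(ipv, 20, "varying", 32))
  sp <- estimate_spectra(bin_ensemble(sr), t_seg = 2)
  full <- info_correlation_theory(sp)$result
  isi <- info_isi(sr, sv)
  expect_equal(isi$rate / full$rate, 1, tolerance = 0.25)
  # insufficient data fails with a actionable hint
  tiny <- generate_poisson_ensemble(5, 5, 2, 1)
  expect_error(info_isi(tiny, tiny), "insufficient ISIs")
})
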