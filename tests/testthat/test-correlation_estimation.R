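test_that("binning is exact, conservative and half-open", {
  ens <- spike_train_ensemble(list(c(1.0, 2.0)), "varying", 3)
  b <- bin_ensemble(ens, 0.5)
  expect_identical(sum(b$counts), 2L)
  expect_identical(sum(b$counts > 0), 2L)
  expect_identical(unname(b$counts[1, 2001]), 1L)  # spike at 1.0 s opens bin 2001
  # conservation on a simulated ensemble
  p <- ou_params(duration = 5)
  sim <- simulate_ensemble(neuron_params("LIF", tau_mem = 10, v_th = 1,
                                         v_reset = -1),
                           build_input_ensemble(p, 3, "varying", 2))
  expect_identical(sum(bin_ensemble(sim, 1)$counts),
                   as.integer(sum(lengths(sim$trains))))
  empty <- spike_train_ensemble(list(numeric(0), numeric(0)), "varying", 1)
  expect_true(all(bin_ensemble(empty, 1)$counts == 0))
  expect_error(bin_ensemble(ens, 4000), "duration")
})

test_that("the PSTH recovers known rate profiles", {
  ens <- spike_train_ensemble(rep(list(c(0.1, 0.25, 0.7)), 5), "repeated", 1)
  ps <- compute_psth(bin_ensemble(ens, 50))
  expect_equal(sum(ps$rate_hz) * 0.05, 3, tolerance = 1e-9)
  # sinusoidal inhomogeneous Poisson: amplitude recovered by regression
  nu0 <- 30; m <- 0.5; f0 <- 4
  er <- generate_poisson_ensemble(function(t) nu0 * (1 + m * cos(2 * pi * f0 * t)),
                                  20, 200, 3, "repeated",
                                  rate_max = nu0 * (1 + m))
  ps2 <- compute_psth(bin_ensemble(er, 5))
  X <- cbind(cos(2 * pi * f0 * ps2$time_s), sin(2 * pi * f0 * ps2$time_s))
  amp <- sqrt(sum(coef(lm(ps2$rate_hz ~ X))[2:3]^2))
  expect_equal(amp, nu0 * m, tolerance = 0.1)
  expect_warning(compute_psth(bin_ensemble(
    generate_poisson_ensemble(10, 2, 3, 1), 1)), "flat")
})

test_that("Poisson correlation functions match the closed form", {
  nu <- 20
  ens <- generate_poisson_ensemble(nu, 50, 4, 8)
  b <- bin_ensemble(ens, 1)
  cf <- estimate_correlation_functions(b, max_lag = 50)
  v <- cf$auto$values
  l <- cf$auto$lags
  expect_equal(mean(v[abs(l) >= 2]), nu^2, tolerance = 0.05)
  expect_equal(v[l == 0], nu / 1e-3 + nu^2, tolerance = 0.05)
  # copied identical trains: cross equals auto exactly
  ens2 <- spike_train_ensemble(rep(ens$trains[1], 4), "repeated",
                               ens$duration)
  cf2 <- estimate_correlation_functions(bin_ensemble(ens2, 1), max_lag = 20)
  expect_equal(cf2$cross$values, cf2$auto$values, tolerance = 1e-12)
})

test_that("pair cross-correlation matches a brute-force loop on a toy ensemble", {
  ens <- generate_poisson_ensemble(15, 2, 3, 4, "repeated")
  b <- bin_ensemble(ens, 5)
  cf <- estimate_correlation_functions(b, max_lag = 50)
  cc <- b$counts
  n <- ncol(cc); m <- nrow(cc); ds <- 5e-3
  brute <- sapply(0:10, function(k) {
    acc <- 0
    for (i in 1:m) for (j in 1:m) {
      if (i == j) next
      acc <- acc + sum(cc[i, 1:(n - k)] * cc[j, (1 + k):n])
    }
    acc / (m * (m - 1) * (n - k) * ds^2)
  })
  expect_equal(cf$cross$values[cf$cross$lags >= 0], brute, tolerance = 1e-9)
})

test_that("the PSTH autocorrelation identity holds exactly", {
  # mean over ordered pairs including i = j:
  #   corr(PSTH) = ((M-1) * cross + auto) / M
  ens <- generate_poisson_ensemble(function(t) 25 * (1 + 0.5 * sin(2 * pi * 3 * t)),
                                   10, 6, 5, "repeated", rate_max = 40)
  b <- bin_ensemble(ens, 2)
  cf <- estimate_correlation_functions(b, max_lag = 40)
  m <- b$n_trials
  cc <- b$counts; n <- ncol(cc); ds <- 2e-3
  pbar <- colMeans(cc)
  psth_corr <- sapply(0:20, function(k)
    sum(pbar[1:(n - k)] * pbar[(1 + k):n]) / ((n - k) * ds^2))
  combined <- ((m - 1) * cf$cross$values + cf$auto$values)[cf$auto$lags >= 0] / m
  expect_equal(combined, psth_corr, tolerance = 1e-9)
})

test_that("spectra satisfy the Poisson floor and vanish without a stimulus", {
  nu <- 20
  ens <- generate_poisson_ensemble(nu, 40, 10, 6)
  sp <- estimate_spectra(bin_ensemble(ens), t_seg = 2)
  expect_equal(band_mean(sp$S_auto, sp$freqs, 5, 900), nu, tolerance = 0.05)
  expect_true(all(sp$S_auto >= 0))
  # frozen-stimulus label with snr = 0: no locking anywhere
  p0 <- ou_params(snr = 0, duration = 20)
  sim0 <- simulate_ensemble(neuron_params("LIF", tau_mem = 10, v_th = 1,
                                          v_reset = -1),
                            build_input_ensemble(p0, 20, "repeated", 3))
  sp0 <- estimate_spectra(bin_ensemble(sim0), t_seg = 2)
  expect_lt(abs(mean(sp0$S_cross)), 0.05 * sim0$rate)
  expect_error(estimate_spectra(bin_ensemble(ens), t_seg = 100), "duration")
})

test_that("binned spectra agree with direct point-process Fourier statistics", {
  # duality/normalization check: the across-trial variance of the exact
  # (unbinned) Fourier coefficients must match the FFT-based S_auto
  p <- ou_params(duration = 10)
  sim <- simulate_ensemble(neuron_params("LIF", tau_mem = 10, v_th = 1,
                                         v_reset = -1),
                           build_input_ensemble(p, 60, "varying", 13))
  sp <- estimate_spectra(bin_ensemble(sim), t_seg = sim$duration)
  fr <- c(5, 11, 23, 47, 101, 199)
  fe <- trial_fourier_coefficients(sim, fr)
  v <- apply(fe$coefficients, 2, function(z)
    mean(Mod(z - mean(z))^2))
  idx <- sapply(fr, function(f) which.min(abs(sp$freqs - f)))
  expect_equal(mean(v / sp$S_auto[idx]), 1, tolerance = 0.12)
})

test_that("estimates are invariant under trial permutation and stable in bin width", {
  s <- tb_fig_setup(n_trials = 10, duration = 5, seed = 31)
  b <- bin_ensemble(s$rep)
  perm <- s$rep
  perm$trains <- perm$trains[c(3, 1, 2, 7, 10, 4, 6, 5, 9, 8)]
  bp <- bin_ensemble(perm)
  sp1 <- estimate_spectra(b, t_seg = 1)
  sp2 <- estimate_spectra(bp, t_seg = 1)
  expect_equal(sp1$S_auto, sp2$S_auto, tolerance = 1e-12)
  expect_equal(sp1$S_cross, sp2$S_cross, tolerance = 1e-12)
  cf1 <- estimate_correlation_functions(b, 20)
  cf2 <- estimate_correlation_functions(bp, 20)
  expect_equal(cf1$cross$values, cf2$cross$values, tolerance = 1e-12)
  # halving the bin width moves the sub-500 Hz spectrum only slightly
  spa <- estimate_spectra(bin_ensemble(s$rep, 0.5), t_seg = 1)
  spb <- estimate_spectra(bin_ensemble(s$rep, 0.25), t_seg = 1)
  lo_a <- band_mean(spa$S_auto, spa$freqs, 1, 500)
  lo_b <- band_mean(spb$S_auto, spb$freqs, 1, 500)
  expect_equal(lo_a / lo_b, 1, tolerance = 0.05)
})

test_that("ISI statistics recover renewal and degenerate regimes", {
  ens <- generate_poisson_ensemble(20, 100, 5, 9)
  st <- isi_statistics(ens)
  expect_equal(st$cv, 1, tolerance = 0.05)
  expect_lt(abs(st$rho1), 0.05)
  # exponential density at the short end: p(0)/p(mean) = e
  lam <- 1 / mean(st$isi_values)
  d_near0 <- st$histogram$density[1]
  expect_equal(d_near0, lam * exp(-lam * st$histogram$mid[1]),
               tolerance = 0.15)
  per <- spike_train_ensemble(list(seq(0.1, 9.9, by = 0.1)), "varying", 10)
  stp <- isi_statistics(per)
  expect_equal(stp$cv, 0)
  expect_true(is.na(stp$rho1))
  expect_match(stp$flags, "zero ISI variance", all = FALSE)
  expect_error(isi_statistics(spike_train_ensemble(list(c(0.5)), "varying", 1)),
               "fewer than 2")
})
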