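# Shared fixture builders. Everything is generated in code at test time.

ou_params <- function(tau_stim = 10, sigma_eta = 1, snr = 0.6, duration = 10,
                      dt = 0.05, ...) {
  input_params("ou", tau_stim = tau_stim, sigma_eta = sigma_eta, snr = snr,
               duration = duration, dt = dt, ...)
}

# Small threshold-based pipeline at the slow-stimulus operating point.
tb_fig_setup <- function(n_trials = 20, duration = 10, seed = 1) {
  ip <- ou_params(tau_stim = 3, sigma_eta = 0.45, snr = 0.8,
                  duration = duration)
  nrn <- neuron_params("TB", tau_mem = 5, v_th = 0.6)
  list(
    input = ip, neuron = nrn,
    rep = simulate_ensemble(nrn, build_input_ensemble(ip, n_trials,
                                                      "repeated", seed)),
    var = simulate_ensemble(nrn, build_input_ensemble(ip, n_trials,
                                                      "varying", seed + 1)))
}

# OU-rate-modulated Poisson ensembles with a frozen or per-trial profile.
# Weak broadband modulation: the regime where conditionally-Poisson spiking
# makes the PSTH-based approximation exact.
modulated_poisson <- function(nu0 = 20, m = 0.35, tau_z = 20, duration = 40,
                              n_rep = 100, n_var = 60, seed = 7) {
  zp <- input_params("ou", tau_stim = tau_z, sigma_eta = sqrt(2 / tau_z),
                     snr = 0, dt = 0.5, duration = duration)
  mk_rate <- function(s) {
    z <- generate_ou(zp, s)$values
    function(t) nu0 * pmax(1 + m * z[pmin(floor(t * 2000) + 1, length(z))], 0)
  }
  er <- generate_poisson_ensemble(mk_rate(seed), duration, n_rep, seed + 1,
                                  "repeated", rate_max = nu0 * 3)
  vt <- lapply(seq_len(n_var), function(i)
    generate_poisson_ensemble(mk_rate(seed + 10 + i), duration, 1,
                              seed + 500 + i,
                              rate_max = nu0 * 3)$trains[[1]])
  list(rep = er, var = spike_train_ensemble(vt, "varying", duration))
}

# Hand-built spectral pair for closed-form channel checks.
synthetic_spectral_pair <- function(freqs, s_auto, s_cross, rate = 10) {
  structure(list(freqs = freqs, S_auto = s_auto, S_cross = s_cross,
                 S_lin = NULL, rate = rate, n_trials = NA_integer_,
                 n_segments = NA_integer_, t_seg = NA_real_,
                 bin_width = NA_real_),
            class = "spectral_pair")
}

band_mean <- function(x, f, lo, hi) mean(x[f >= lo & f <= hi])
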