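#' Input-current parameter set
#'
#' Describes the stationary stochastic current ensembles that drive the
#' neuron models. The input current is a variance-preserving mixture
#' \eqn{X(t) = \sqrt{SNR}\, s(t) + \sqrt{1-SNR}\, n(t)} of a stimulus
#' \eqn{s(t)} and an independent noise process \eqn{n(t)} with identical
#' statistics. Both are either Ornstein-Uhlenbeck (OU) processes with time
#' constant `tau_stim` or i.i.d. draws per time step from a zero-mean
#' two-component Gaussian mixture ("bimodal").
#'
#' For the OU kind the generating equation is
#' \deqn{dx = -x/\tau_{stim}\, dt + \sigma_\eta\, dW,}
#' with time measured in ms, so the stationary variance is
#' \eqn{\sigma_\eta^2 \tau_{stim}/2} (the "diffusion" convention, the
#' default). Set `sigma_convention = "stationary-sd"` to instead interpret
#' `sigma_eta` as the stationary standard deviation of the process.
#'
#' @param kind `"ou"` or `"bimodal"`.
#' @param tau_stim OU time constant, ms. Must be positive for the OU kind.
#' @param sigma_eta Amplitude scale, mV (see Details for the convention).
#' @param snr Stimulus-to-noise ratio in `[0, 1)`: the stimulus's share of
#'   the input-current variance.
#' @param dt Sample step, ms. For OU inputs `dt <= tau_stim / 10` is
#'   enforced so the process is well resolved.
#' @param duration Trace duration, s.
#' @param bimodal_spec Data frame with columns `location` (mV), `width`
#'   (mV) and `weight` for the mixture components (bimodal kind only).
#'   Weights must sum to 1. The default places symmetric modes at
#'   +/- 34 mV with width 8.5 mV, chosen to drive a leaky
#'   integrate-and-fire neuron (threshold 3 mV, membrane constant 10 ms)
#'   at roughly 12 Hz.
#' @param sigma_convention `"diffusion"` (default) or `"stationary-sd"`.
#' @return An object of class `input_params`.
#' @export
#' @examples
#' p <- input_params(kind = "ou", tau_stim = 10, sigma_eta = 1, snr = 0.6,
#'                   duration = 2)
#' tr <- generate_ou(p, seed = 1)
#' var(tr$values)  # ~ sigma_eta^2 * tau_stim / 2
input_params <- function(kind = c("ou", "bimodal"), tau_stim = 10,
                         sigma_eta = 1, snr = 0.5, dt = 0.05, duration = 10,
                         bimodal_spec = NULL,
                         sigma_convention = c("diffusion", "stationary-sd")) {
  kind <- match.arg(kind)
  sigma_convention <- match.arg(sigma_convention)
  if (snr < 0 || snr >= 1) stopf("snr must lie in [0, 1), got %g", snr)
  if (dt <= 0) stopf("dt must be positive")
  if (duration <= 0) stopf("duration must be positive")
  if (kind == "ou") {
    if (tau_stim <= 0) stopf("tau_stim must be positive for OU inputs")
    if (dt > tau_stim / 10)
      stopf("invalid resolution: dt = %g ms exceeds tau_stim/10 = %g ms",
            dt, tau_stim / 10)
  }
  if (kind == "bimodal") {
    if (is.null(bimodal_spec)) {
      bimodal_spec <- data.frame(location = c(-34, 34), width = 8.5,
                                 weight = 0.5)
    }
    stopifnot(is.data.frame(bimodal_spec),
              all(c("location", "width", "weight") %in% names(bimodal_spec)))
    if (nrow(bimodal_spec) == 0) stopf("bimodal_spec must be nonempty")
    if (abs(sum(bimodal_spec$weight) - 1) > 1e-8)
      stopf("invalid bimodal_spec: weights sum to %g, not 1",
            sum(bimodal_spec$weight))
    if (any(bimodal_spec$width < 0)) stopf("bimodal widths must be >= 0")
  }
  structure(list(kind = kind, tau_stim = tau_stim, sigma_eta = sigma_eta,
                 snr = snr, dt = dt, duration = duration,
                 bimodal_spec = bimodal_spec,
                 sigma_convention = sigma_convention),
            class = "input_params")
}

# Stationary standard deviation implied by the sigma_eta convention.
ou_stationary_sd <- function(params) {
  if (params$sigma_convention == "diffusion") {
    params$sigma_eta * sqrt(params$tau_stim / 2)
  } else {
    params$sigma_eta
  }
}

n_samples <- function(params) round(params$duration * 1000 / params$dt)

new_current_trace <- function(values, dt, duration, seed) {
  structure(list(values = values, dt = dt, duration = duration, seed = seed),
            class = "current_trace")
}

#' Construct a current trace from raw values
#'
#' Mainly useful for feeding deterministic diagnostic drives (for example a
#' constant suprathreshold current) to the simulators.
#'
#' @param values Numeric vector of current values, mV, sampled at `dt`.
#' @param dt Sample step, ms.
#' @return A `current_trace`.
#' @export
as_current_trace <- function(values, dt) {
  stopifnot(is.numeric(values), all(is.finite(values)), dt > 0)
  new_current_trace(values, dt, length(values) * dt / 1000, seed = NA_integer_)
}

#' Generate one Ornstein-Uhlenbeck sample path
#'
#' Uses the exact discretization (exponential decay plus Gaussian
#' innovation), so `dt` affects only the temporal resolution and not the
#' stationary statistics. The initial value is drawn from the stationary
#' distribution; the path is stationary from the first sample.
#'
#' @param params An [input_params()] object with `kind = "ou"`.
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   traces. The caller's RNG state is left untouched.
#' @return A `current_trace` with fields `values` (mV), `dt` (ms),
#'   `duration` (s) and `seed`.
#' @export
generate_ou <- function(params, seed) {
  stopifnot(inherits(params, "input_params"))
  if (params$kind != "ou") stopf("generate_ou requires kind = 'ou'")
  if (params$dt >= params$tau_stim)
    stopf("invalid resolution: dt >= tau_stim")
  n <- n_samples(params)
  sd_x <- ou_stationary_sd(params)
  a <- exp(-params$dt / params$tau_stim)
  values <- with_seed(seed, {
    x0 <- rnorm(1, 0, sd_x)
    innov <- rnorm(n, 0, sd_x * sqrt(1 - a^2))
    as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
  })
  new_current_trace(values, params$dt, params$duration, seed)
}

#' Generate an i.i.d. bimodal current trace
#'
#' Each sample is drawn independently from the zero-mean two-component
#' Gaussian mixture in `params$bimodal_spec`, producing a white (memoryless)
#' input at the sampling resolution.
#'
#' @inheritParams generate_ou
#' @return A `current_trace`.
#' @export
generate_bimodal <- function(params, seed) {
  stopifnot(inherits(params, "input_params"))
  if (params$kind != "bimodal") stopf("generate_bimodal requires kind = 'bimodal'")
  spec <- params$bimodal_spec
  n <- n_samples(params)
  values <- with_seed(seed, {
    comp <- sample.int(nrow(spec), n, replace = TRUE, prob = spec$weight)
    rnorm(n, spec$location[comp], spec$width[comp])
  })
  new_current_trace(values, params$dt, params$duration, seed)
}

#' Mix stimulus and noise traces at a given SNR
#'
#' Variance-preserving mixture `X = sqrt(snr) * s + sqrt(1 - snr) * n`: when
#' `s` and `n` have equal variance, `X` keeps that variance and the stimulus
#' contributes the fraction `snr` of it.
#'
#' @param s,n `current_trace` objects on the same grid.
#' @param snr Stimulus-to-noise ratio in `[0, 1)`.
#' @return A `current_trace`.
#' @export
mix_stimulus_noise <- function(s, n, snr) {
  stopifnot(inherits(s, "current_trace"), inherits(n, "current_trace"))
  if (snr < 0 || snr >= 1) stopf("snr must lie in [0, 1)")
  if (s$dt != n$dt || length(s$values) != length(n$values))
    stopf("shape error: stimulus and noise traces are on different grids")
  new_current_trace(sqrt(snr) * s$values + sqrt(1 - snr) * n$values,
                    s$dt, s$duration, NA_integer_)
}

#' Build a trial ensemble of input currents
#'
#' A `"repeated"` ensemble freezes one stimulus realization across all
#' trials (fresh independent noise per trial); a `"varying"` ensemble
#' redraws both per trial. The ensemble object is lightweight: it stores
#' parameters and derived sub-seeds, and trials are materialized on demand
#' with [input_trace()], so long ensembles never need to be held in memory
#' at once.
#'
#' @param params An [input_params()] object.
#' @param n_trials Number of trials, >= 1.
#' @param ensemble_kind `"repeated"` or `"varying"`.
#' @param master_seed Integer master seed; stimulus and noise sub-seeds are
#'   derived from it on disjoint streams.
#' @return An object of class `input_ensemble`.
#' @export
build_input_ensemble <- function(params, n_trials,
                                 ensemble_kind = c("repeated", "varying"),
                                 master_seed) {
  stopifnot(inherits(params, "input_params"), n_trials >= 1)
  ensemble_kind <- match.arg(ensemble_kind)
  stim_seeds <- if (ensemble_kind == "repeated") {
    rep(derive_seed(master_seed, 1L, 0L), n_trials)
  } else {
    vapply(seq_len(n_trials), function(i) derive_seed(master_seed, 1L, i),
           numeric(1))
  }
  noise_seeds <- vapply(seq_len(n_trials),
                        function(i) derive_seed(master_seed, 2L, i), numeric(1))
  structure(list(params = params, ensemble_kind = ensemble_kind,
                 n_trials = as.integer(n_trials), stimulus_seeds = stim_seeds,
                 noise_seeds = noise_seeds, master_seed = master_seed),
            class = "input_ensemble")
}

#' Materialize one trial of an input ensemble
#'
#' @param ens An [build_input_ensemble()] object.
#' @param i Trial index, 1-based.
#' @param component `"mixed"` (default) for the SNR mixture driving the
#'   neuron, or `"stimulus"`/`"noise"` for the unmixed components.
#' @return A `current_trace`.
#' @export
input_trace <- function(ens, i, component = c("mixed", "stimulus", "noise")) {
  stopifnot(inherits(ens, "input_ensemble"), i >= 1, i <= ens$n_trials)
  component <- match.arg(component)
  gen <- if (ens$params$kind == "ou") generate_ou else generate_bimodal
  if (component == "stimulus") return(gen(ens$params, ens$stimulus_seeds[i]))
  if (component == "noise") return(gen(ens$params, ens$noise_seeds[i]))
  s <- gen(ens$params, ens$stimulus_seeds[i])
  n <- gen(ens$params, ens$noise_seeds[i])
  mix_stimulus_noise(s, n, ens$params$snr)
}

#' @export
print.input_ensemble <- function(x, ...) {
  cat(sprintf("<input_ensemble: %d %s trials, %s input, %.3g s at dt = %g ms>\n",
              x$n_trials, x$ensemble_kind, x$params$kind, x$params$duration,
              x$params$dt))
  invisible(x)
}

#' Export a current trace as a two-column data frame
#'
#' @param x A `current_trace`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A data frame with columns `time_s` and `value_mV`.
#' @export
as.data.frame.current_trace <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(time_s = (seq_along(x$values) - 1) * x$dt / 1000,
             value_mV = x$values)
}
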