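#' Generate Poisson spike-train ensembles
#'
#' Homogeneous or inhomogeneous Poisson processes, used throughout the test
#' suite as closed-form references: a homogeneous train of rate `rate` has a
#' flat spike spectrum `S_auto(f) = rate`, exponential interspike intervals
#' and unit coefficient of variation; an inhomogeneous train generated from
#' a known rate function is the regime in which the PSTH-based Poisson
#' approximation of the information rate is exact.
#'
#' @param rate Rate in Hz: a single number, or a function of time (s)
#'   returning Hz for the inhomogeneous case (generated by thinning).
#' @param duration Trial duration, s.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param ensemble_kind `"varying"` (default) or `"repeated"`. For a
#'   rate-function drive, `"repeated"` means every trial is an independent
#'   thinning of the same rate profile (the profile plays the role of the
#'   frozen stimulus).
#' @param rate_max Upper bound on the rate function, Hz (thinning envelope);
#'   defaults to `rate` for constant rates.
#' @return A `spike_train_ensemble`.
#' @export
#' @examples
#' ens <- generate_poisson_ensemble(10, duration = 5, n_trials = 4, seed = 1)
#' ens$rate
generate_poisson_ensemble <- function(rate, duration, n_trials, seed,
                                      ensemble_kind = c("varying", "repeated"),
                                      rate_max = NULL) {
  ensemble_kind <- match.arg(ensemble_kind)
  if (is.function(rate)) {
    if (is.null(rate_max)) stopf("rate_max is required for a rate function")
  } else {
    rate_max <- rate
  }
  trains <- with_seed(seed, {
    lapply(seq_len(n_trials), function(i) {
      n_cand <- stats::rpois(1, rate_max * duration)
      tt <- sort(runif(n_cand, 0, duration))
      if (is.function(rate)) tt <- tt[runif(n_cand) < rate(tt) / rate_max]
      tt
    })
  })
  spike_train_ensemble(trains, ensemble_kind, duration)
}
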