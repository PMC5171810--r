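# spikeinfo

Spectral estimation of single-neuron mutual information from pairwise
spike correlations.

## The problem

How many bits per second does a neuron's spike train carry about the
stimulus component of its input current? Word-entropy ("direct")
estimators answer this by histogramming binary spike words and
extrapolating entropies, which demands enormous trial counts. For
stationary spike trains with finite memory there is a far cheaper route:
across trials, the Fourier coefficients of the spike train are complex
Gaussian — zero-mean for varying stimuli, stimulus-locked mean for
frozen-stimulus repeats — so the full information is fixed by just two
pairwise statistics, the spike autocorrelation (spectrum
`S_auto(f)`) and the trial cross-correlation under a frozen stimulus
(spectrum `S_cross(f)`, the PSTH autocorrelation). The per-frequency
information density is

```
I(f) = 1/2 * log2( S_auto(f) / (S_auto(f) - S_cross(f)) )   bit (s Hz)^-1
```

and the information rate is its one-sided frequency integral (DC
excluded). spikeinfo implements this estimator for anyone analyzing
stationary spike trains — simulated or recorded, supplied as plain-text
trial-indexed spike files — together with:

* simulators for four stochastic neuron models (threshold-based level
  crossing, leaky / adaptive / exponential integrate-and-fire) driven by
  Ornstein–Uhlenbeck or bimodal current ensembles with a controlled
  stimulus-to-noise ratio;
* the standard comparison estimators: coherence-style linear lower bound,
  PSTH-based Poisson approximation, interspike-interval information, and
  the binary-word direct method with its extrapolations;
* diagnostics that test the statistical foundations on any ensemble
  (real/imaginary decorrelation, Rayleigh amplitudes, uniform phases,
  cross-frequency independence);
* a sweep driver and pre-baked experiment presets, plus a thin CLI
  (`inst/cli/spikeinfo`).

## Worked example

Simulate a threshold-based neuron in the fluctuation-driven regime
(stimulus time constant 3 ms, stimulus-to-noise ratio 0.8, membrane
constant 5 ms, threshold 0.6 mV) under 60 frozen-stimulus repeats, and
estimate its information rate:

```r
library(spikeinfo)

ip  <- input_params("ou", tau_stim = 3, sigma_eta = 0.45, snr = 0.8,
                    duration = 20)
nrn <- neuron_params("TB", tau_mem = 5, v_th = 0.6)
ens <- build_input_ensemble(ip, n_trials = 60, "repeated", master_seed = 1)

spikes <- simulate_ensemble(nrn, ens)
spikes
#> <spike_train_ensemble: 60 repeated trials of 19.9 s, mean rate 8.52 Hz>

sp <- estimate_spectra(bin_ensemble(spikes, bin_width = 0.5), t_seg = 4)
info_correlation_theory(sp)$result
#> <info_result [correlation]: 49.68 bits/s, 5.828 bits/spike (rate 8.525 Hz, cutoff 1000 Hz)>

info_psth_poisson(sp)
#> <info_result [psth_poisson]: 73.05 bits/s, 8.569 bits/spike (rate 8.525 Hz, cutoff 1000 Hz)>

isi_statistics(spikes)
#> <isi_statistics: 10144 ISIs, mean 117 ms, CV 1.07, rho1 -0.021>
```

The neuron fires at 8.5 Hz (mean interval 117 ms) yet transmits ~50
bits/s, i.e. ~5.8 bits per spike, almost all of it below 500 Hz — spike
timing is informative on a scale two orders of magnitude finer than the
mean interval. The PSTH-based Poisson approximation, which keeps the rate
modulation but discards the train's internal temporal structure,
overestimates the rate by ~50% at this operating point; the
interval statistics (CV near 1, vanishing serial correlation) show why
interval-based shortcuts are unreliable here. The methods vignette
(`vignettes/correlation-information.Rmd`) documents the estimator, its
assumptions, all conventions and the known limitations.

Pre-baked sweep experiments are run via `reproduce()`:

```r
res <- reproduce("fig6e", scale = "reduced", master_seed = 1)
```

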