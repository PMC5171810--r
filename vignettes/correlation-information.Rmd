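---
title: "Estimating single-neuron information from pairwise spike correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating single-neuron information from pairwise spike correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeinfo)
```

## The model and its assumptions

spikeinfo estimates the mutual information rate $I(R,S)$ between a
stationary stimulus process $s(t)$ and the spike train $r(t) = \sum_j
\delta(t - t_j)$ it evokes, using only two pairwise statistics of the
spikes:

* the **spike autocorrelation** within a trial, whose Fourier transform is
  the spike power spectrum $S_{\mathrm{auto}}(f)$, and
* the **trial cross-correlation** between distinct trials that share a
  frozen stimulus, whose transform $S_{\mathrm{cross}}(f)$ is the spectrum
  of the stimulus-locked response (equivalently, the PSTH autocorrelation
  with the finite-trial self-term removed).

The estimator rests on three assumptions about the spiking process:
stationarity (statistics invariant under time translation), finite memory
(correlations vanish beyond some lag), and a finite, non-zero coefficient
of variation. Under these assumptions the Fourier coefficients of the
spike train, pooled across trials, converge to complex normal
distributions: zero-mean for varying stimuli, stimulus-locked mean for
frozen-stimulus repeats. After mean correction the coefficient amplitudes
are Rayleigh distributed and the phases uniform, and the information at
each frequency is carried entirely by the amplitude. The per-frequency
information density is the difference of the two Rayleigh differential
entropies (their Euler–Mascheroni terms cancel),

$$ I(f) \;=\; \tfrac12 \log_2
   \frac{S_{\mathrm{auto}}(f)}{S_{\mathrm{auto}}(f) - S_{\mathrm{cross}}(f)}
   \quad \text{bit (s Hz)}^{-1}, $$

and the total rate is the one-sided frequency integral of $I(f)$, excluding
DC (which carries the mean rate, not stimulus modulation, under
stationarity). `gaussianity_tests()` and `independence_tests()` verify the
distributional assumptions on any ensemble, so the estimate never has to be
taken on faith for a new preparation.

## Which spectra enter the ratio, and why

Both spectra are estimated from the *same* frozen-stimulus ensemble.
The noise spectrum $S_{\mathrm{auto}} - S_{\mathrm{cross}}$ is computed
window by window as the across-trial variance of the Fourier coefficients
around their trial mean. Written this way the stimulus-locked sampling
fluctuations of the two terms cancel exactly; if instead
$S_{\mathrm{auto}}$ is taken from a separately simulated varying-stimulus
ensemble (the `auto_from` argument), any mismatch between the two
ensembles' mean rates shifts the density by $\tfrac12 \log_2(\nu_v/\nu_r)$
at *every* frequency and can dominate the integral at realistic recording
lengths. Under the stationarity assumption the time-averaged autocorrelation
of a long frozen-stimulus recording converges to the marginal one, so the
single-ensemble route loses nothing. We validated the whole pipeline
against an exactly solvable reference — a conditionally Poisson encoder
with weak Ornstein–Uhlenbeck rate modulation, where
$I(f) = \tfrac12\log_2(1 + S_{\mathrm{mod}}(f)/\nu)$ in closed form — and
recover the closed-form rate to better than 1%.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bin_width` | 0.5 ms | count-bin width; 1 kHz Nyquist covers the informative band (empirically $\ge$ 95% of the rate lies below 500 Hz at the operating points studied here) |
| `t_seg` | 4 s | Bartlett segment length; frequency resolution $1/T_{seg}$ = 0.25 Hz |
| `cutoff` | Nyquist | upper limit of the information integral |
| `eps` | $10^{-6}$ | relative floor applied where sampling noise makes $S_{\mathrm{auto}} - S_{\mathrm{cross}} \le 0$; the affected fraction is reported as `clipped_fraction` and should stay below 1% |
| `taper` | none | optional Hann taper (with per-segment mean removal); rectangular segments are the default because the locked spectra here are broad |

Negative sampling excursions of $S_{\mathrm{cross}}$ are never clipped in
the stored estimates — only inside the logarithm, where the floored and the
raw densities are both reported.

## The input and neuron models

Inputs are mixtures $X(t) = \sqrt{\mathrm{SNR}}\, s(t) +
\sqrt{1-\mathrm{SNR}}\, n(t)$ of two independent, identically distributed
processes, so the stimulus owns the fraction SNR of the input variance and
the total variance is SNR-invariant. Both are either Ornstein–Uhlenbeck
processes, $dx = -x/\tau_{\mathrm{stim}}\,dt + \sigma_\eta\,dW$ (time in
ms), or i.i.d. draws per sample step from a zero-mean bimodal Gaussian
mixture. Two readings of $\sigma_\eta$ are possible — white-noise intensity
(stationary variance $\sigma_\eta^2 \tau_{\mathrm{stim}}/2$) or stationary
standard deviation. We adopted the **diffusion convention as the default**
because it, and only it, reproduces the published firing rates of the
threshold-based model at three independent parameter sets (8.3 Hz and
5 Hz operating points, verified additionally by the Rice upward-crossing
formula applied to the simulated voltage) and the leaky
integrate-and-fire sweep endpoints (107 and 1.1 Hz). The alternative
reading remains available via `sigma_convention = "stationary-sd"`.

Four spiking models are provided. All integrate their linear subthreshold
dynamics with the exact exponential (matrix-exponential for the adaptive
model) one-step update, with the input held constant across a sample step,
so the step size affects resolution only:

* **TB** — threshold-based level crossing: low-pass filtered input, a spike
  at every upward crossing of $V_{th}$ (linearly interpolated), no reset.
* **LIF** — leaky integrate-and-fire with threshold and reset.
* **aLIF** — voltage coupled to an adaptation variable,
  $\tau_m \dot V = -V + \alpha w + X$, $\tau_w \dot w = \beta V - w$, with
  spike-and-reset on $V$ and $w$ continuous through the spike. The
  equations' published rendering was unavailable to us in display form;
  this two-variable damped-oscillator form was adopted because it produces
  the documented subthreshold resonance, reduces exactly to the LIF when
  $\alpha = \beta = 0$, and reproduces the published 50 Hz operating point
  at $\tau_w = 10$ ms within 7%. No jump of $w$ at the spike is applied,
  since none is stated.
* **EIF** — exponential integrate-and-fire with slope factor $\Delta_T$;
  the spike is registered at $V \ge V_{th}$, which also bounds the
  exponential term and keeps the explicit step stable.

Voltage transients are removed by discarding a warm-up window of ten times
the slowest time constant; the inputs themselves start in their stationary
distribution.

The default bimodal spec (modes at $\pm 34$ mV, width 8.5 mV, equal
weights) is our own calibration: the published distribution is shown only
graphically, so we chose a symmetric two-component mixture that drives the
matched leaky integrate-and-fire neuron (threshold 3 mV) at roughly the
documented ~12 Hz. Quantities that depend on this choice are treated as
qualitative, not numeric, targets.

## Comparison estimators

**Lower bound.** The coherence-style bound replaces the full cross
spectrum by the stimulus-locked power captured by the best *linear*
transfer from the stimulus, $S_{\mathrm{lin}} = |S_{xr}|^2/S_{xx}$
(available when `estimate_spectra()` is given the frozen stimulus trace).
Because the linear projection can only capture part of the locked
variance, the bound sits below the full rate, with equality for a linear
encoder — both behaviors are exercised in the test suite. When no
stimulus spectra are present the bound degenerates to the full estimate
and says so; we chose this explicit-fallback design over guessing a
kernel from spike data alone.

**PSTH-Poisson approximation.** Substitutes the flat Poisson spectrum
$\nu$ for $S_{\mathrm{auto}}$ while keeping the measured
$S_{\mathrm{cross}}$ — the information of an inhomogeneous-Poisson
surrogate with the same PSTH. It is exact for conditionally Poisson
spiking in the weak-modulation regime and misestimates the rate in either
direction once genuine spike-train temporal structure matters.

**ISI information.** Treats interspike intervals as independent symbols:
total entropy from the pooled ISI distribution of a varying-stimulus
ensemble, noise entropy from the spike-time-conditioned ISI distributions
across frozen-stimulus repeats (spikes grouped into time bins sized to
collect at least `min_count` intervals), both over shared equal-occupancy
bin edges so the discretization terms cancel, both extrapolated linearly
in inverse data fraction. The published procedure's full details live in
supplementary material unavailable to us; this independent-symbol
construction with finite-sampling extrapolation is our documented
approximation to it. Conditioning on binned spike times smooths genuinely
fast stimulus structure, which biases the conditional entropy upward —
another reason ISI information is a *comparison* quantity here, not the
primary estimator.

**Direct (word-entropy) method.** Binary words of `L` bins; plug-in
entropies extrapolated first in inverse data fraction (quadratically when
three or more fractions are available, the cited method's standard bias
control) and then in inverse word duration over the stably sampled word
lengths (those whose finite-sampling extrapolation moves the pooled
entropy by under 20%); unstable fits are flagged, never silently accepted.
Per-time noise entropies are restricted to data fractions that keep at
least 16 trials, since below that the plug-in bias leaves the linear
regime and poisons the extrapolation. By default the total entropy comes
from the time-pooled words of the same frozen-stimulus recording (the
marginal distribution, under stationarity), which keeps total and noise
entropies on an identical mean rate. The bin width and maximum word length
must be matched to the neuron: `L * dt` should span the spike-train
correlation memory while the word Nyquist `1/(2 dt)` still covers the
informative band — with 2 ms bins and 8–10-bin words the method is only
trustworthy for fast, short-memory trains, and its upward bias elsewhere
at desk-scale data sizes is exactly the data hunger that motivates the
correlation-based estimator.

## Numerical choices and degenerate inputs

* Sub-seeds for stimulus and noise streams are derived from the master
  seed on disjoint integer streams; ensembles are pure functions of
  (parameters, master seed), and generators restore the caller's RNG
  state.
* The cross-correlation and cross-spectrum use distinct-trial pairs only;
  the identity PSTH-correlation $= ((M-1)\,\mathrm{cross} +
  \mathrm{auto})/M$ is asserted exactly in the tests.
* Zero ISI variance flags `rho1` as undefined rather than returning a
  spurious correlation; empty trials are legal everywhere and survive
  spike-file round trips.
* Resolution guards reject `dt` coarser than a tenth of any time constant;
  the exact OU update keeps input statistics `dt`-independent regardless.

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the estimators are demonstrably
converged: the headline operating point uses 150 frozen-stimulus trials of
40 s (the estimate is stable under doubling of segment length and trial
count and agrees with a direct, unbinned Fourier evaluation), the
model-comparison sweeps use 20–100 trials of 20–100 s per condition, and
ISI comparisons pool at least $10^4$ intervals per condition.

## Known limitations

* The synthetic inputs are stationary OU or white-bimodal currents. Real
  sensory drives are neither Gaussian nor stationary; the passing tests
  show estimator correctness under the stated assumptions, not robustness
  to nonstationary data. The Fourier diagnostics are the tool to check a
  recording before trusting the estimate.
* At the headline operating point our converged numerical rate is ~50–53
  bits/s against a published exact analytic value of 59.0 bits/s. The
  closed-form correlation functions needed to evaluate the analytic route
  are deliberately out of scope, so the residual ~11% gap — stable across
  spectral resolutions, trial counts and two independent estimator
  implementations, while all published firing rates reproduce to within a
  few percent — is documented rather than tuned away.
* The ISI estimator needs long recordings (its error message says how
  much) and degrades for very low rates, where few conditioning groups
  reach the minimum count.
* The direct method inherits the severe sample-hunger of word-entropy
  estimation; it is included as the standard of comparison, not as a
  recommended estimator.
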