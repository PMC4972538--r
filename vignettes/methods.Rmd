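---
title: "Dissociating spatial tuning and brain state from stimulus-evoked CA1 firing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating spatial tuning and brain state from stimulus-evoked CA1 firing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoblink)
```

## The problem

During trace eyeblink conditioning a tone (CS) is followed, after a
stimulus-free trace interval, by an eyelid stimulation (US); the animal
learns to blink in anticipation. Dorsal CA1 pyramidal neurons recorded in
such tasks often change their firing after the CS, which is tempting to read
as a non-spatial stimulus code. But these same neurons are place cells, and
their firing is gated by brain state: place-specific while the animal moves
or is alert, ripple-associated bursting during quiet wakefulness. A tone
that merely *arouses* a quiet animal will therefore change firing — the cell
resumes place-specific firing at the animal's current location and stops
participating in ripples — without encoding anything about the tone.

This package implements the analyses needed to separate these accounts on a
per-session basis, together with a synthetic-session generator that encodes
each account explicitly, so every analysis stage can be validated by
parameter recovery against a known ground truth.

## The three response models

The generator (`simulate_spikes()`) implements three generative accounts of
CS-responsiveness:

* **CS cell** — a space-invariant additive rate bump after every CS,
  regardless of location or state. Under this model observed trial-to-trial
  reliability matches the independent-Poisson expectation.
* **CS-place cell** — a conjunctive response: the bump is scaled by the
  cell's field intensity at the animal's current location, in every
  behavioural state. Its signature is a field-gated CS response that is
  present on running trials.
* **Arousal place cell** — no CS response at all. The CS switches a quiet
  animal to the alert state after a short latency; place-specific firing
  resumes and ripple bursts cease. On running trials (already alert) the
  rate trace is untouched.

The pipeline discriminates the three by combining (i) the Spearman
correlation between CS-evoked counts and place-field intensity, (ii) the
presence or absence of pre/post-CS rate changes on running trials, and
(iii) the peri-CS ripple rate.

## The reliability statistic

For each cell, observed reliability is the fraction of trials with strictly
more post-CS than pre-CS spikes (ties never count; direction flipped for
rate-decreasing cells). Expected reliability is
$P(k_2 > k_1) = \sum_{k_1} f(k_1;\lambda_1)\, P(k_2 > k_1;\lambda_2)$
for independent Poisson counts at the cell's trial-averaged rates. The inner
tail is evaluated with `ppois`, and the outer sum truncated at the
$1 - 10^{-13}$ Poisson quantile, so the neglected mass is below $10^{-12}$;
the implementation is tested against closed forms
($\lambda_1 = 0 \Rightarrow 1 - e^{-\lambda_2}$; at $\lambda_1 = \lambda_2 = \lambda$
the tie probability is $e^{-2\lambda} I_0(2\lambda)$) and a $10^6$-draw
Monte Carlo oracle.

Spatial or state gating makes spike counts overdispersed relative to a
Poisson with the same mean, so observed reliability falls below expectation
— the arousal model's population signature. A caveat found while validating
at desk scale: for cells with only a handful of post-CS spikes the observed
reliability has one-trial granularity and can sit within that granularity of
the expected value, so the strict inequality is only meaningful for cells
with enough spikes to resolve it (the test suite uses 20 post-CS spikes,
the same activity floor used for the tuning-correlation signature).

## The signed-rank change is a heuristic

`signed_rank_change()` reports a two-sided Wilcoxon signed-rank p-value per
cell (an exact tie-aware enumeration for up to 20 non-tied pairs, the
normal approximation with tie correction otherwise). It carries a
`heuristic` flag: spatial tuning and brain state violate the test's i.i.d.
assumption, so it screens cells, it does not calibrate inference. No
multiple-comparison correction is applied, deliberately.

## Place-field maps and their numerical choices

Maps divide smoothed spike-count by smoothed occupancy maps (numerator and
denominator smoothed separately, the standard occupancy-map practice),
with a Gaussian kernel truncated at $4\sigma$ and renormalized over valid
bins. Bin sizes are 1 cm (track) and 1 cm² (endbox) so the 3 cm / 1 cm
kernels span at least three bins. The occupancy-validity criterion is
areal (50 ms/cm²): a 1 cm track bin spans the 7.5 cm track width, so its
threshold is 0.375 s; an endbox bin needs 0.05 s. Only moving samples
(speed > 2 cm/s, estimated by central differences on 200 ms
boxcar-smoothed positions) contribute, and the 2 s window after each CS is
excluded so evoked firing cannot contaminate the maps. A sample on the
track uses the direction-matched map when moving and the mean of the two
directional maps when stationary; endbox samples use the non-directional
2-D map. "Has a field" means a contiguous suprathreshold region (peak
> 2 Hz) of at least 3 valid bins, guarding against single-bin noise; the
classification is threshold-sensitive, so `classify_spatial()` takes the
threshold as an argument rather than fixing one interpretation.

## The locality-guaranteed STFT

All theta quantities come from a short-time Fourier transform with a 400 ms
Kaiser window (shape α = 1, i.e. β = π): the coefficient at time *t* is a
function of samples within *t* ± 200 ms only. Frames that would extend past
the data are marked invalid, never padded, so the guarantee cannot be
silently violated — in contrast to Hilbert-transform or IIR phase
estimators, whose impulse responses are unbounded. This matters because the
US often leaves a high-amplitude transient in the LFP: with the STFT,
estimates 200 ms away are bitwise unaffected (a property the tests check
literally).

Instantaneous frequency is the 4–12 Hz power peak per frame, refined by
quadratic interpolation of log-power around the argmax bin after 4× zero
padding (bin spacing 0.625 Hz); phase and amplitude are the argument and
modulus at that frequency, with the DFT's time origin moved to the frame
centre so the argument *is* the instantaneous phase.

The phase-transition analysis uses two non-overlapping frames — pre ending
at stimulus onset, post starting 100 ms after it (after US offset for the
US variant) — and extrapolates both to the gap midpoint with their own
frequency estimates ($\varphi_{\mathrm{ref}} = \varphi + 2\pi f\,\Delta t$,
wrapped). Diagonal structure in (pre, post) means the rhythm is unaffected;
a horizontal band means a reset to a fixed phase; a displaced diagonal a
constant shift. Because the figure-level summary statistic is not uniquely
determined by the scatter, the summary reports both a Fisher–Lee circular
correlation and the mean resultant of the per-trial shift, plus Rayleigh
statistics of the post-phase distribution; the mean resultant length is
unweighted by default with an amplitude-weighted variant available.

## Ripple detection

Per channel: 80–250 Hz zero-phase band-pass (window-method FIR, order set
by the Hamming transition-band rule, applied forward and backward), 10 ms
sliding RMS, candidate peaks above mean + 5 SD with extents at mean + 2 SD
and durations restricted to 20–200 ms. Candidate frequency comes from a
100 ms STFT frame at the peak and must fall in 120–250 Hz; events must
coincide within ±15 ms on at least 3 channels; overlapping detections merge
keeping the longest. Thresholds are per-channel with a global coincidence
rule (the plausible alternatives — global thresholds — are a configuration
choice, not a data-driven one). The 5 SD default is conventional practice
and is validated on synthetic data: ≥ 90% sensitivity to injected in-band
wavelets, < 0.05 events/s false rate on noise, and invariance to channel
permutation and global rescaling.

## The synthetic generator: what it emulates, and what it does not

Behaviour is an alternating renewal process: exponential endbox dwells
(mean 20 s) between constant-speed (30 cm/s) track traversals. Within a
dwell the animal alternates stationary pauses (mean 4 s) with short
wanders (5 cm/s) through the box — this intra-box movement is what gives
endbox bins moving-state occupancy, without which endbox fields could not
be mapped. Dwell parameters are not measured quantities; they are chosen
to resemble track-running sessions and are configurable. The stationary
sitting fraction has the closed form
`sit_mean / (sit_mean + track_length/run_speed)`, which the tests verify.

Place fields are Gaussian tuning curves (peak 8 Hz, σ = 10 cm on the
track; σ = 4 cm in the endboxes; baseline 0.1 Hz), one directional track
field and/or one endbox field per cell, with the spatial-class mix set to
the observed population fractions (38% no field, 24% endbox only, 26%
track, 12% both). Quiet-state firing is concentrated in ripple windows
(participation probability 0.3, Poisson bursts of mean 2 spikes) over a
near-zero residual rate; ripples arrive at 0.4/s during quiet wakefulness.
The arousal latency (50 ms) and alert duration (2.5 s) are configurable
because the transition time course is not a measured quantity. Spiking is
inhomogeneous Poisson given the rate trace at the 25 Hz trajectory
resolution.

The LFP is additive — theta sinusoid with Ornstein–Uhlenbeck frequency
drift during alert epochs, pink noise (larger during quiet, emulating
large irregular activity), Gaussian-windowed ripple wavelets, an optional
post-US transient — not a biophysical model. The EMG is Gaussian noise
with Hann-windowed broadband bursts (an unconditioned blink after every
US, a conditioned one on Bernoulli trials).

Consequences for interpretation: passing recovery tests shows the analysis
code is correct under the stated generative assumptions. It does not show
robustness to real-data features the generator omits — theta harmonics and
asymmetric cycle shapes, phase precession in the spike trains (present only
in a dedicated test generator), movement artifacts, electrode drift,
cluster contamination, or learning dynamics across sessions.

## Problem sizes and determinism

The validation suite runs everything at desk scale, chosen so each check has
statistical power without waste: the benchmark arousal session is 100 cells
x 150 trials (~25 min of simulated behaviour); field recovery uses a
40-minute dense-sampling session (short dwells, so track coverage is high)
and averages six fields; the Monte Carlo reliability oracle uses $10^6$
draws per rate pair; detector calibration uses 500 null trials (CR), 1000
null cells (signed-rank) and 120 s of multi-channel noise (ripples). Every
generator takes an explicit integer seed and restores the caller's RNG
state; identical seeds give bitwise-identical sessions, which the manifest
hashes in `run_session_analysis()` turn into an end-to-end reproducibility
check.

## Known limitations

* Units are treated independently even though repeated sessions are likely
  to resample the same neurons; session/cell identifiers are carried so a
  downstream deduplication can be applied.
* The post-US analyses reuse the CS machinery but are flagged: the
  unconditioned blink moves the head, and nothing in the pipeline corrects
  for that.
* Trial-state thresholds (sit ≤ 2 cm/s, run ≥ 8 cm/s over the 500 ms
  pre-CS window) are configuration, not estimates; the sit threshold
  matches the 2 cm/s moving criterion used for the maps.
* The CR detector's 95th-percentile construction has a built-in ~5% false
  positive floor; CR rates near 0.05 are indistinguishable from chance.
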