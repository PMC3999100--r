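---
title: "Simulating contextual stop-signal experiments: models, estimators and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating contextual stop-signal experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextstop)
library(dplyr)
```

## The task and why it is simulated

`contextstop` models a stop-signal experiment in which the *meaning* of an
infrequent stimulus depends on a blockwise stimulus-response context. The
design has one frequent go signal and two deviants (Stim1, presented on 13%
of trials; Stim2, on 26%). In context 1 both deviants are stop signals; in
context 2 only Stim1 must be stopped while Stim2 requires a response; in
context 3 the mapping is reversed. Per context the design presents 236 go,
48 Stim1 and 100 Stim2 trials (384 trials per context; 1152 in total, of
which 708 are pure go, 296 are stop-relevant and 148 are stop-irrelevant
deviants). Same-context trials come in runs of 13–18, and onsets are
jittered by 0–2000 ms to sample the haemodynamic response densely relative
to a 2 s scan repetition.

Because every quantity of interest here — the stop-signal reaction time
(SSRT), event-related spectral perturbation (ERSP) features, EEG-informed
fMRI modulation effects — is an *estimate* produced by a non-trivial
estimator, the package pairs every estimator with a generator whose ground
truth is known. All empirical claims in this vignette are the ones the test
suite computes.

## Behaviour: independent horse race with adaptive tracking

A trial's response behaviour is the outcome of an independent race:

* the **go process** finishes after an ex-Gaussian latency,
  `N(mu, sigma) + Exp(tau)`, defaults `mu = 450`, `sigma = 60`,
  `tau = 120` ms;
* on stop-relevant trials a **stop process** starts at the stop-signal
  delay (SOA) and finishes `SOA + latency` later, with latency
  `N(200, 30)` ms truncated at zero;
* a response is emitted iff the go process finishes first *and* within the
  1350 ms response window. A trigger-failure probability (default 0) lets
  the stop process fail to launch; a go-omission probability (default 0)
  censors the go process.

The defaults were chosen once so that simulated go RTs (~570 ms mean),
SSRTs (~200 ms) and tracked delays fall in the ranges typical of adult
stop-signal performance; context effects on behaviour are off by default
and available as per-context shifts of `mu`.

Independence of the two processes is an assumption, not a finding: the
classic race framework treats context effects on stopping as changes in
the marginal distributions, and nothing in the simulation induces
go–stop dependence.

**Tracking.** One staircase per context starts at 128 ms; successful
inhibition adds 16 ms, a failed stop subtracts 64 ms, clamped to
[64, 928] ms. For any subject whose response probability increases
continuously with the delay, the asymmetric steps balance when
`P(respond) = 16 / (16 + 64) = 0.20`, so the long-run failure rate is 20%
regardless of the subject's parameters. Measured on one continuous
35-session tracked run (`simulate_long_run()`, ~10,360 stop trials) the
simulated rate is within half a point of 20%. When the staircase restarts
at 128 ms each session — as it does in a real experiment — the climb toward
equilibrium deflates the observed rate to roughly 18–19%, which is exactly
the regime the published per-context response rates of such experiments
occupy.

**SSRT.** The integration method sorts the context's go RTs, takes the RT
at rank `ceiling(N × response rate)` (the `nearest` convention is
available), and subtracts the mean SOA of that context's stop trials. Go
omissions are replaced by the maximum observed RT before ranking — the
standard guard against censoring bias; with the default zero omission rate
it is a no-op. The estimator is shift-equivariant by construction and, in
the tests, recovers a deterministic 200 ms stop latency within ±15 ms when
~10,000 trials are pooled and within ±50 ms from single-session-sized
splits. Response rates enter per context, matching the per-context SSRTs
the summary table reports.

A note on the design's arithmetic: the 296 stop-relevant trials are 25.7%
of all trials, while all deviants together (444) are 38.5%; summaries in
this package always separate stop-relevant from stop-irrelevant deviants,
so no ambiguity arises downstream.

## Synthetic EEG and the ERSP estimator

Epochs span −800…1212 ms around stimulus onset at 250 Hz over the 26
electrodes that make up the six electrode sites of interest (EOIs). The
background is Gaussian noise with power spectral density
`scale² / (f + 1)` (pink with a 1 Hz knee, `scale = 5 µV`), synthesized by
spectral shaping so its theoretical PSD is known exactly.

**Estimator.** Time-frequency power is computed with a Morlet (Gaussian
Gabor) filter bank with constant spectral bandwidth `sigma_f = 0.7` Hz,
i.e. temporal sd ~227 ms, on a linear grid of 100 frequencies from 2 to
35 Hz, frames every 20 ms. Two numerical choices matter:

* *Grid floor.* 0 Hz is unattainable for a finite epoch; 2 Hz is the lowest
  frequency whose wavelet both remains analytic (carrier ≳ 2.5 bandwidths)
  and fits the 800 ms baseline. The delta band therefore uses the bins in
  (0, 4] Hz that exist on the grid, i.e. 2–4 Hz.
* *Bandwidth.* A fixed-window short-time Fourier transform wide enough to
  separate delta from theta (e.g. 512 ms) smears a 100 ms analysis window
  over half a second, and one short enough for the delta window leaks ~25%
  of theta power into delta bins. The constant-bandwidth Gaussian bank is
  the compromise that keeps both failure modes bounded; with 4 Hz-wide
  bands the adjacent-band remnant of an injected effect stays below a
  quarter of the effect (verified in the tests), while spectrally distant
  bands stay at noise level. This resolution limit is a property of any
  estimator at these band widths, not of the implementation.

Wavelet coefficients near the epoch edges are renormalized by the in-epoch
kernel energy, so expected power is position-independent. Baseline
normalization divides each trial's power by the frequency- and
channel-specific mean power over −800…−100 ms, averaged across *all*
trials (condition-blind), then converts to dB (`10·log10`). dB conversion
precedes averaging over bins, frames and electrodes; condition averages
are formed in the power domain first and then converted, which keeps the
condition-mean features unbiased (single-trial log power carries the usual
negative chi-square bias, which is irrelevant for the z-scored fMRI
modulators built from it).

**Calibrated effects.** An effect specification requests, e.g., "+3 dB
theta at the frontocentral EOI on stop trials". The generator adds
band-limited noise bursts (spectrum matched to the background inside the
band with a 0.5 Hz guard; raised-cosine envelope covering the extraction
window padded by one wavelet sd) whose gain is solved analytically: the
expected wavelet power of burst and background at every band bin and
window frame is a quadratic form in the known synthesis PSD, and the gain
is the root of "expected feature contrast = requested dB". The request is
therefore a *condition contrast* (affected minus unaffected trials): the
condition-blind baseline absorbs any pre-stimulus envelope tail equally in
both conditions. Trial-to-trial burst power varies lognormally (sd 0.5 on
the log scale, unit mean) and is stored as ground truth. At 200 trials per
condition the injected +3 dB contrast is recovered within ±0.5 dB and the
null generator's features stay within their 99% confidence band of 0 dB.

What the generator does *not* emulate: scanner and ballistocardiogram
artifacts (epochs are artifact-free by construction, so no Allen-type
correction or ICA cleaning is implemented), evoked phase-locked components
(effects are purely induced power), realistic cross-channel covariance
(bursts are independent across electrodes), or non-stationary background.
Passing recovery tests therefore validates the estimator pipeline, not
robustness to real-world artifacts.

## EEG-informed fMRI model

The canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s,
unit dispersions, peak:undershoot 6, 32 s support, unit peak) is convolved
with event sticks on a 100 ms microtime grid and sampled at the 2 s scan
times. For each condition, every per-trial EEG modulator (e.g. the
single-trial frontocentral theta feature) is z-scored across that
condition's events, used as stick weights, convolved, and residualized
against the unmodulated regressor and previously entered modulators
(serial orthogonalization in column order, delta → theta → high beta by
default, matching the convention of entering the three bands in one
design). Orthogonality of each modulated column to its companion is exact
to 1e-12. Z-scoring is global across a condition's trials; per-condition
versus global centering and the orthogonalization order are configurable
because both are conventions rather than identities. Discrete-cosine
drifts with periods above 128 s and a constant complete the design;
movement regressors can be appended as nuisance columns but are never
generated.

Noise is stationary AR(1) with marginal sd `sigma`. Fitting is OLS with
one-step Cochrane–Orcutt/Prais–Winsten prewhitening: the AR coefficient is
the lag-1 autocorrelation of the OLS residuals, data and design are
quasi-differenced once, and the model is refit — a deliberately simple,
testable stand-in for pooled restricted-maximum-likelihood AR modelling,
operating on one time series (no spatial model, smoothing or group level).
Under the null with `rho = 0.4`, 600 scans and 100 events, the modulator's
t-statistic is calibrated (two-sided 5% rejection within [0.03, 0.07]
across 500 replicates); a true modulation beta of 0.8 at contrast-to-noise
~1 is recovered without bias; and when BOLD amplitude is generated from
the theta feature, the theta-modulated column — not delta or high beta —
carries the effect.

## The pipeline and problem sizes

`run_pipeline()` chains the stages from one configuration and master seed
(stage seeds are derived deterministically; outputs are byte-identical
across reruns) and writes per-subject events TSVs, trial records, the
per-context behavioural summary, per-trial and condition-mean ERSP
features, GLM estimates, and a JSON run log with seeds and file checksums.
`validate_config()` reports impossible settings (counts that cannot form
13–18-trial runs, feature windows outside the analysable frames) as errors
and suspicious ones (overridden staircase steps and their implied
equilibrium rate, heavy censoring probabilities) as warnings.

Default analysis sizes were chosen so that each estimator's sampling error
is comfortably below the property being asserted: 35 sessions (~10⁴ stop
trials) for staircase and SSRT properties, 200 trials per condition and
the six-electrode frontocentral EOI for ERSP recovery, and 600 scans /
100 events / 500 replicates for GLM calibration. The pipeline defaults use
a 21-subject cohort for behaviour and a 240-trial subset of subject 1's
session for the EEG and fMRI stages.

## Worked example

```{r example, eval = FALSE}
sched <- generate_schedule(design_config(), seed = 1)
rec <- simulate_session(subject_params(), sched, seed = 1)
summarize_behavior(rec)

ep <- synthesize_epochs(
  rec[rec$context == 1 & rec$stimulus != "go", ][1:40, ],
  effects = ersp_effect("theta", "frontocentral", 3, stimulus = "stim1"),
  channels = dplyr::filter(eoi_sets(), eoi == "frontocentral")$electrode,
  seed = 2
)
feats <- extract_features(baseline_normalize(compute_ersp(ep)),
                          eois = dplyr::filter(eoi_sets(),
                                               eoi == "frontocentral"))
head(feats)
```

## Known limitations

* Behavioural context effects (go-RT differences between contexts, response
  slowing on stop-irrelevant deviants) are not produced by the default
  parameters; they require explicit `context_mu_shift` settings. The race
  model also has no attentional capture mechanism, so irrelevant-deviant
  slowing is not emergent.
* The ERSP delta band is measured over 2–4 Hz, and adjacent-band separation
  is resolution-limited as described above.
* The GLM stage models a single "voxel" time series; spatial preprocessing,
  group-level inference and anatomical localization are out of scope.
* The session-duration bookkeeping excludes feedback screens and pauses;
  with the default jitter the simulated session is ~45 minutes of trials.
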