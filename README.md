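# contextstop

Simulation and analysis of **contextual stop-signal experiments** — a
stop-signal task in which the behavioural relevance of infrequent stimuli
changes with a blockwise stimulus-response context — together with the
EEG and EEG-informed fMRI models used to analyse such experiments. The
package is aimed at researchers who want to study the estimators of this
paradigm (SSRT, ERSP band features, single-trial parametric modulation)
under known ground truth before touching real data.

## What it implements

* **Task design.** The three-context schedule: per context 236 go, 48
  Stim1 and 100 Stim2 trials (1152 trials total; 708 go, 296
  stop-relevant, 148 stop-irrelevant deviants), same-context runs of
  13–18 trials, uniform 0–2000 ms onset jitter, BIDS-style events TSV
  round-tripping.
* **Behaviour.** The independent horse-race model: ex-Gaussian go
  latencies race a truncated-normal stop process launched at the
  stop-signal delay (SOA). One adaptive staircase per context (init
  128 ms, +16 ms after successful inhibition, −64 ms after a failed stop,
  bounds 64–928 ms) tracks a 20% failure rate, since the asymmetric steps
  balance when `P(respond) = 16/(16+64) = 0.20`.
* **Behavioural statistics.** Per-context response rate, go-RT
  summaries, mean SOA, failed-stop RTs, and the integration-method SSRT:
  sort go RTs, take the RT at rank `ceiling(N × response rate)`, subtract
  the mean SOA.
* **EEG.** Synthetic stimulus-locked epochs (250 Hz, −800…1212 ms, 1/f
  background) with *calibrated* band-limited power effects, and ERSP
  feature extraction: Morlet filter bank (100 frequencies, 2–35 Hz,
  0.7 Hz bandwidth), divide-by-baseline (−800…−100 ms) + `10·log10` dB
  conversion, and band × window × electrode-site averages (delta 0–4 Hz @
  300–400 ms, theta 4–8 Hz @ 150–250 ms, low/high beta 12–21/21–30 Hz @
  220–500 ms; frontocentral, centroparietal, frontal and motor EOIs).
* **EEG-informed fMRI.** Canonical double-gamma HRF designs at TR = 2 s
  with 128 s discrete-cosine high-pass, per-trial EEG modulators z-scored
  and serially orthogonalized, AR(1) BOLD synthesis, and OLS fitting with
  one-step Cochrane–Orcutt prewhitening (broom-style `tidy()`/`glance()`).
* **Pipeline.** `run_pipeline()` chains everything from one config and
  master seed into a reproducible report bundle; `validate_config()`
  checks a configuration before running. A thin CLI wrapper lives at
  `inst/scripts/contextstop-run.R`.

## Worked example

```r
library(contextstop)

rec <- simulate_cohort(n_subjects = 5, seed = 1)
summarize_behavior(rec)
#>   context n_go n_stop go_rt go_rt_sem     rr mean_soa  ssrt failed_stop_rt
#> 1       1 1180    740 561.6     2.195 0.1892    251.4 200.5          448.7
#> 2       2 1180    240 572.3     3.038 0.1708    234.7 222.7          431.8
#> 3       3 1180    500 570.7     4.122 0.1820    255.2 204.1          442.1
```

Reading the output: the staircase holds each context's stop-failure rate
(`rr`) near its 20% design target (slightly below, because each session
climbs from the 128 ms initial delay); the integration-method `ssrt`
recovers the generating 200 ms stop latency; failed-stop RTs are faster
than go RTs, the race-model censoring signature; and the stop-irrelevant
deviants of contexts 2 and 3 are answered like go trials
(`irrelevant_accuracy` = 1 here, `p_go_omission = 0` by default).

A ready-made qualitative EEG pattern (stop > go frontocentral delta/theta,
attenuated theta when the same stimulus is stop-irrelevant, left-motor
high beta) is available as `default_effect_spec()`; see the vignette in
`vignettes/` for the full model description and the calibration of
injected effects.

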