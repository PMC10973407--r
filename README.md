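# mutlfoci

Single-cell mutation dynamics from fluorescent mismatch-repair foci.

In *E. coli*, fluorescently tagged MutL forms a diffraction-limited focus at
each replication error that the methyl-directed mismatch-repair (MMR)
machinery detects. In mother-machine time-lapse experiments the lifetime of
such a focus separates the two fates of an error: repaired errors give
short-lived foci (mean lifetime tens of seconds), while the ~1% of errors
whose repair fails give long-lived foci persisting about one doubling time —
nascent mutations, visible in real time. `mutlfoci` turns tables of tracked
focus records (lineage, onset frame, span in frames, frame interval) into:

- **repair kinetics** — the mean short-focus lifetime `tau`, estimated by
  maximum likelihood under interval censoring: with frames every `dt` and
  uniform onset phase, the span `K` (frames) of a detected
  exponential-lifetime focus is geometric with success probability
  `1 − exp(−dt/tau)`, so `tau = dt / (−log(1 − 1/mean(K)))`;
- **detection-corrected rates** — at 2-min frames most short foci fall
  between frames; a focus with exponential lifetime covers at least one
  frame with probability `p = (tau/dt)(1 − exp(−dt/tau))` (~0.32 for
  `tau` = 40 s, `dt` = 2 min). Total error-production rates use a
  span-weighted (Horvitz–Thompson) estimator: multi-frame foci are detected
  with probability 1 and count once, single-frame foci count
  `E[1/P(detect|L) | span = 1]` times;
- **a short/long lifetime cutoff** — the valley of a kernel-smoothed
  density on log observed lifetime between the single-frame mode and the
  doubling-time mode, the basis of the short/long classification
  (conventionally 14 min at 2-min frames);
- **mutation-rate estimates** — long-lived foci per generation with exact
  Poisson intervals, plus mutation-accumulation/sequencing arithmetic
  (`log2(dilution)` generations per growth cycle) for cross-validation;
- **tests of mutation dynamics** — if error production is Poisson and
  repair failure is an i.i.d. Bernoulli coin toss, long-focus onsets form a
  thinned Poisson process and inter-onset gaps (in frames) are geometric:
  `P(gap ≤ k·dt) = 1 − exp(−lambda·k·dt)`. `gof_poisson()` tests this with
  a finite-window, censoring-aware parametric bootstrap;
  `short_gap_enrichment()` quantifies the over-representation of gaps
  < 40 min that transient impaired-repair states produce; `burst_summary()`
  flags affected lineages and checks bursts are lineage-autonomous.

A ground-truth simulator (`sim_params()`, `simulate_lineages()`,
`apply_imaging()`) generates mother-cell lineages with Poisson error
production, Bernoulli repair failure (optionally modulated by a hidden
two-state telegraph process to create mutation bursts), exponential
short-focus lifetimes, discrete imaging at any frame interval and optional
photobleaching — so every analysis stage is validated against known truth.

## Worked example

Simulate 400 mother-cell lineages for 100 generations at the
experimentally observed focus rate (0.065 min⁻¹, 1% repair failure,
26.6-min doubling time), observe them at 2-min frames, and analyse:

```r
library(mutlfoci)

params <- sim_params(error_rate_per_min = 0.065, failure_prob = 0.01,
                     n_lineages = 400, window_generations = 100, seed = 7)
traces <- simulate_lineages(params)
foci   <- apply_imaging(traces, imaging_config(frame_interval_s = 120))
nft    <- attr(foci, "n_frames_total")
foci   <- classify_foci(foci, cutoff_min = 14)

span_weighted_total_rate(lifetime_distribution(foci),
                         exposure_min = 400 * 100 * 26.6)
#> total focus (span-weighted) rate estimate (n = 22182 events, exposure = 1.064e+06 min = 4e+04 generations)
#>   raw       : 0.02085 /min  (0.5545 /generation)
#>   corrected : 0.06432 /min  (1.711 /generation), p_detect = 0.324
#>   95% CI (corrected): 0.06347-0.06517 /min (1.688-1.733 /generation)

interior <- drop_edge_foci(foci, nft)
mutation_rate_from_long_foci(sum(interior$class == "long"), 400 * 100)
#> long-lived focus (mutation) rate estimate (n = 680 events, exposure = 4e+04 min = 4e+04 generations)
#>   raw       : 0.017 /min  (0.017 /generation)
#>   corrected : 0.017 /min  (0.017 /generation), p_detect = 1
#>   95% CI (corrected): 0.01575-0.01833 /min (0.01575-0.01833 /generation)

gaps <- interarrival_times(foci, "long", n_frames_total = nft,
                           n_lineages = 400)
gof_poisson(gaps, n_boot = 999, seed = 7)
#> Poisson-dynamics GOF (long foci): D = 0.3151, p = 0.31 (367 gaps, 999 bootstrap reps, rate 0.0006452 /min)
```

Reading the output: of the ~64,000 true errors, only ~22,000 foci are seen
at 2-min frames; the span-weighted correction recovers the true production
rate (0.065 min⁻¹ is inside the CI). The 680 long-lived foci give a
mutation rate of 0.017 per generation (here 1% of 1.7 errors per
generation; at the long-term experimental error rate of 0.14 per
generation the same estimator returns ~0.0014 per generation). With
constant repair efficiency the inter-arrival test accepts Poisson dynamics
(p = 0.31); rerun with `burst_params` in `sim_params()` to see it reject
and the <40-min gaps become over-represented.

`run_pipeline(pipeline_config(...))` chains all stages (simulate → CSV
tables → lifetimes → rates → dynamics) and writes per-stage CSV reports
plus a JSON manifest with the seed and a config fingerprint; reruns with an
identical config are numerically identical.

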