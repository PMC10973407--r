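---
title: "Models and methods: repair kinetics, detection-corrected rates, and mutation dynamics from MutL foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mutlfoci` analyses tracked fluorescent MutL focus records from
mother-machine experiments. This vignette states the generative model the
package assumes, derives its estimators, explains every tunable that
matters, and records the design choices made where the design was genuinely
open.

## The generative model

One lineage is the mother cell at the closed end of one microchannel,
followed for `window_generations` generations. The model has four layers:

1. **Error production.** Replication errors occur along each lineage as a
   homogeneous Poisson process with rate `error_rate_per_min`
   (`lambda`, events·min⁻¹·lineage⁻¹). Defaults: 0.14/26.6 ≈ 0.0053 min⁻¹,
   i.e. 0.14 errors per generation, the regime of long-term mother-cell
   records; short-interval full-population imaging observes ~0.065 min⁻¹
   and analyses at that scale simply pass a different `lambda`.
2. **Repair outcome.** Each error independently fails repair with
   probability `failure_prob` (`q`, default 0.01): a Bernoulli coin toss.
   Optionally a hidden two-state telegraph process (rates `rate_on`,
   `rate_off` per minute) switches the cell into an impaired-repair state
   where the failure probability is `q_high`. The telegraph acts on repair
   only, never on error production: bursts of mutations are modelled as
   transient losses of repair capacity, not surges of errors.
3. **Focus lifetime.** A repaired error shows a focus for an
   `Exp(tau_short_s)` lifetime (default mean 40 s). An unrepaired error
   shows a focus for about one doubling time:
   `L = doubling_time_min * (1 + eps)`, `eps ~ N(0, long_lifetime_cv)`,
   redrawn in the vanishingly rare case `1 + eps <= 0`. The spread
   `long_lifetime_cv` (default 0.2) is a free parameter — the observable
   constraint is only that long-focus lifetimes mode near the doubling
   time — and results that depend on it (notably classification leak near
   the cutoff) should be sensitivity-tested rather than asserted.
4. **Observation.** Frames are acquired every `frame_interval_s` seconds
   (7.5–30 s short-term, 120 s long-term), offset by a phase in
   `[0, dt)`. A focus alive on `[onset, onset + L)` is recorded iff at
   least one frame time falls in that interval; its observed span is the
   number of consecutive visible frames and its observed lifetime is
   `span * dt` (a single-frame focus reads as one frame interval).
   Optional photobleaching extinguishes a visible focus permanently after
   each exposure with probability `bleach_per_exposure`. Divisions are
   deterministic every `doubling_time_min` (default 26.6 min): growth-rate
   noise is orthogonal to every statistic computed here, and generations
   are therefore exactly `time / doubling_time`.

Reproducibility: each lineage draws from a counter-based substream derived
from `(seed, lineage_index)`, so lineage *i* is identical whether 5 or
5,000 lineages are simulated, and no simulation call disturbs the caller's
RNG state.

What the simulator deliberately omits: cell geometry and fluorescence
images (records begin at tracked focus tables), daughter-cell pedigrees
(mother-cell-only semantics), merging of spatially co-occurring foci (two
onsets in one frame stay separate records; temporal analyses collapse
same-frame onsets instead), and any mechanistic model of the
hemimethylation repair window. Passing tests therefore demonstrate the
correctness of the statistical pipeline on data satisfying these
assumptions, not the assumptions themselves on real microscopy.

## Repair kinetics under interval censoring

With uniform onset phase, the span `K` of a *detected* focus of
exponential lifetime (mean `tau`) is geometric on {1, 2, ...}:

    P(K >= k) ∝ exp(-(k-1) dt / tau),  P(K = k | detected) = e^{-(k-1)x}(1 - e^{-x}),  x = dt/tau.

The MLE is closed-form: `x = -log(1 - 1/mean(K))`, `tau = dt/x`, with a
delta-method Wald interval on `log(tau)`. A seemingly natural alternative —
writing each span-`k` focus as censored into `((k-1)dt, (k+1)dt)` and
maximising the product of interval probabilities — is not a valid
likelihood because those intervals overlap across `k`; its maximiser solves
`coth(x) = mean(K)` and overestimates `tau` by ~9% at `dt/tau = 0.19`, an
error far larger than the standard error at realistic sample sizes. The
geometric form is the exact distribution of the data the imaging layer
produces, and simulation shows nominal CI coverage (the acceptance suite
requires ≥90% over 50 replicates at n ≈ 5000).

Both `tau` and the raw mean of observed lifetimes (`mean(K) * dt`, which
overestimates the lifetime by up to one frame interval) are reported, since
either convention may be wanted when comparing to published summaries.
Degenerate input — every focus on a single frame, as happens when the frame
interval dwarfs the lifetime — yields `tau = NA`, a flag, and an exact
upper bound from `P(all K = 1) = p^n`.

## Detection probability and rate correction

A focus of lifetime `L` covers a frame with probability `min(L/dt, 1)`;
under exponential lifetimes the detection probability is

    p(tau, dt) = (tau/dt) (1 - exp(-dt/tau)),

~0.32 at `tau` = 40 s, `dt` = 2 min: at long-term cadence two thirds of
repaired errors are never seen, and raw focus rates across conditions with
different repair efficiency are incomparable without correction.

Two corrected estimators of the *total* error-production rate are provided:

- `corrected_total_rate()` applies the classical flat correction
  `(n_short/p + n_long)/exposure` to classified counts. It is simple and
  adequate when repair failure is rare, but when long-lived foci are
  common, the few of them whose lifetime draws fall below the
  classification cutoff are wrongly inflated by `1/p`, biasing the total
  upward by a few percent — resolvable at focus counts in the tens of
  thousands.
- `span_weighted_total_rate()` is the package's primary estimator: a
  Horvitz–Thompson weighting that requires no classification at all. A
  focus observed on ≥2 frames necessarily lived longer than one frame
  interval, so its detection probability is exactly 1 and it counts once;
  only single-frame foci can have been hard to detect, and they count
  `E[1/P(detect | L) | span = 1]` times (≈3.27 at 40 s/2 min; closed form
  in `single_frame_weight()`, exponential model entering only there). The
  estimator is unbiased for any mixture of short- and long-lived foci,
  which is what makes corrected totals agree across repair efficiencies
  from 1% to 100% failure.

Poisson intervals are exact (Garwood) throughout, scaled by the correction
inflation; with ~500 long-lived events the normal approximation would be
noticeably anticonservative in the tails. Per-generation rates are
per-minute rates times the doubling time, exactly; exposure accounting
(lineage-minutes and generations) is explicit, and foci whose spans touch
the first or last frame of the window are excluded from classified counts
(their class is ambiguous; unbiased classification beats inflated counts).

## The short/long cutoff

At 2-min frames the observed-lifetime distribution of a mixed-repair
population is bimodal: a single-frame mode (repaired errors) and a mode
near the doubling time (unrepaired errors). `determine_cutoff()` smooths
the distribution with a Gaussian KDE on log observed lifetime and returns
the density minimum between the two tallest modes.

Numerical choices, all open design decisions:

- The KDE is computed from the binned distribution (distinct lifetimes
  weighted by relative frequency), with a Silverman-type bandwidth
  `bw_mult * 0.9 * sd_w * m^(-1/5)` from the weighted sd and the number of
  distinct spans `m`. Depending only on the distribution's shape makes the
  cutoff exactly invariant under duplication of the dataset, which a
  bandwidth carrying the sample-size factor `n^(-1/5)` would violate.
- `bw_mult` defaults to 0.75, deflating the Silverman scale: that rule is
  derived for smooth unimodal samples, and at full strength it over-smooths
  a discrete, sharply bimodal histogram, dragging the valley into the
  shoulder of the dominant single-frame mode. The deflated value tracks the
  empirically empty stretch of bins while keeping the density strictly
  positive across the gap; the tallest-two-modes rule guards against
  under-smoothing artifacts in sparse bins.
- Bimodality is accepted only if the two modes differ ≥4-fold in lifetime
  (genuine short/long modes differ by an order of magnitude — one frame vs
  ~13 frames — while wiggles of a single decaying mode sit on adjacent
  bins) and the valley is below half the lower mode. Otherwise a failure
  state with diagnostics is returned; fewer than 50 foci is an error.
- Classification is strict: long-lived ⇔ observed lifetime
  `> cutoff`. With 2-min frames and the conventional 14-min threshold the
  long-lived set is span ≥ 8; `>=` would move the span-7 bin across. The
  convention at the boundary is not externally fixed; strict `>` is this
  package's documented choice.

The valley's exact position is deliberately unimportant: in the canonical
regime shifting the cutoff by ±2 min reclassifies under 5% of foci, and the
acceptance suite asserts exactly that, along with the valley falling
between the modes (6–20 min bracket around the conventional 14).

## Inter-arrival dynamics

If error production is Poisson at rate `lambda` and repair failure is an
i.i.d. Bernoulli mark with probability `q`, long-focus onsets are a thinned
Poisson process at `lambda q` — a compound Poisson process with Bernoulli
increments. On the frame grid, occupied frames are independent with
probability `1 - exp(-lambda dt)`, so gaps between successive occupied
frames are geometric and

    P(gap <= k dt) = 1 - exp(-lambda k dt),

the exponential CDF corrected for discrete observation
(`poisson_gap_cdf()`). Gaps are defined onset-frame to onset-frame within a
lineage; onsets sharing a frame collapse to one (the resolvability limit of
spot tracking at 2-min cadence); the gap from the last onset to the window
end is kept as right-censored and never enters empirical CDFs.

Finite windows bias closed gaps short: long gaps are preferentially
censored. `null_prediction_mc()` therefore simulates Poisson onsets through
the same windowing, frame-binning, collapse and censoring pipeline as the
data and returns the bias-corrected predicted CDF (it converges to the
analytic form as windows grow; the convergence and the direction of the
finite-window bias are both under test).

`gof_poisson()` tests the Poisson null. The statistic is the sup-norm
distance between the empirical closed-gap CDF and the analytic geometric
CDF at the pooled empirical rate (total onsets over total lineage-time,
counting lineages with zero onsets). Its null distribution comes from a
parametric bootstrap that re-simulates the full finite-window pipeline and
*re-estimates the rate in every replicate*: both the finite-window bias and
the noise from plugging in an estimated rate are thereby absorbed into the
null distribution, which is what makes the test calibrated (type-I error
0.05 ± 0.02 at nominal 0.05 in the acceptance suite) — evaluating the
observed statistic against a different reference than the replicates would
not be. The analytic reference is used rather than a Monte-Carlo CDF so
that each bootstrap replicate costs one simulation instead of a nested
Monte-Carlo run; since data and replicates share the reference exactly, the
p-value is unchanged in distribution. Defaults: 1999 bootstrap replicates;
all seeds logged in results; identical seeds give bit-identical results.
Fewer than 20 closed gaps is refused rather than tested.

Two complementary views of burstiness:

- `short_gap_enrichment()` compares the observed fraction of gaps below a
  threshold (default 40 min — roughly 1.5 generations, the timescale of
  transient impaired-repair states) with the Monte-Carlo null fraction, via
  a binomial test; the excess ratio is ~1 under constant repair and rises
  severalfold under telegraph-modulated failure at matched mean rate.
- `burst_summary()` flags lineages with ≥2 long-focus onsets within two
  generations and tests cross-lineage temporal coincidence by circularly
  shifting each lineage's onsets (a permutation preserving within-lineage
  structure). Lineage-autonomous bursts show no coincidence signal;
  synchronized external perturbations would.

The telegraph parameters used in validation (q 0.005→0.25, mean impaired
dwell 40 min, stationary mean failure 1%) give the pipeline >80% power at
~400–500 long-focus gaps while leaving all-foci onsets Poissonian — the
same dissociation expected in real data, where error production is
Poissonian but repair capacity fluctuates.

## The 2×2 unconditional test and other comparisons

Age-binned repair-failure fractions (bins of 10 generations of replicative
age) are compared first-vs-last with an unconditional exact test for two
binomials: the pooled-variance score statistic, with the p-value maximised
over the nuisance success probability on a 0.001 grid. The unconditional
(Barnard-type) test is preferred to conditioning on both margins because
at a handful of long-lived foci per bin the conditional test is needlessly
conservative; the score variant is used because the CSM variant is
combinatorially heavier, and the variant is recorded in the result. The
implementation is validated against an exhaustive enumeration oracle on
small tables. Welch's unequal-variance t-test (`compare_rate_estimates()`)
serves the per-group rate comparisons, and rate ratios between conditions
(`fold_change()`) use the conditional-binomial interval, exact given the
total count.

## Problem sizes and budgets

Test and acceptance simulations use 400 lineages × 100 generations for
long-term regimes (≈22,000 foci, ≈600 long-lived at 0.065 min⁻¹ — the
scale of the tracked dataset), ≈5,000 foci for lifetime estimation, 50
replicates for coverage checks, 200 seeds for test calibration, and 10⁶
draws for Monte-Carlo oracle comparisons. These sizes make every
stochastic assertion's tolerance (3 MC standard errors, ≥90% coverage,
0.05 ± 0.02 calibration) meaningful while keeping the full suite to a few
minutes.

## Known limitations

- The long-lived lifetime model (truncated normal around the doubling
  time) reproduces the observed mode, not a mechanism; classification leak
  near the cutoff scales with `long_lifetime_cv`.
- The detection model assumes a focus is seen whenever a frame falls
  within its lifetime; intensity thresholds, noise and segmentation errors
  in real trackers are not modelled (photobleaching is, crudely, as
  per-exposure extinction).
- The pooled-rate Poisson null treats lineages as exchangeable;
  between-lineage rate heterogeneity would register as non-Poissonian
  dynamics, which is the intended reading (heterogeneity of repair
  capacity) but cannot be distinguished from heterogeneity of error
  production by the gap test alone — the all-foci gap test provides that
  control.
- Hidden-state inference (estimating the telegraph rates themselves) is
  out of scope; the package detects non-Poissonianity and localises bursts
  but does not fit the switching process.
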