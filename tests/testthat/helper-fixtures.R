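# Shared fixture builders. All data are generated in code at test time.

# Independent enumeration oracle for the unconditional 2x2 test: explicit
# double loop over all tables, accumulating tail probability per nuisance
# value. Deliberately written without vectorized linear algebra so it shares
# no code path with barnard_test().
barnard_oracle <- function(tab, grid_step = 0.001) {
  x1 <- tab[1, 1]; n1 <- sum(tab[1, ])
  x2 <- tab[2, 1]; n2 <- sum(tab[2, ])
  z <- function(y1, y2) {
    pp <- (y1 + y2) / (n1 + n2)
    v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
    if (v == 0) 0 else (y1 / n1 - y2 / n2) / sqrt(v)
  }
  z_obs <- abs(z(x1, x2))
  p_max <- 0
  for (p in seq(grid_step, 1 - grid_step, by = grid_step)) {
    tot <- 0
    for (y1 in 0:n1) {
      for (y2 in 0:n2) {
        if (abs(z(y1, y2)) >= z_obs - 1e-12) {
          tot <- tot + dbinom(y1, n1, p) * dbinom(y2, n2, p)
        }
      }
    }
    if (tot > p_max) p_max <- tot
  }
  min(1, p_max)
}

# A hand-built ground-truth trace with fully specified events, for exact
# imaging arithmetic.
manual_trace <- function(onsets_min, lifetimes_min, window_min,
                         outcome = NULL, lineage_id = 1L,
                         doubling_min = 26.6) {
  if (is.null(outcome)) outcome <- rep("repaired", length(onsets_min))
  structure(
    list(
      lineage_id = lineage_id,
      window_min = window_min,
      doubling_time_min = doubling_min,
      division_times_min = seq(doubling_min, window_min, by = doubling_min),
      events = data.frame(
        onset_min = onsets_min,
        outcome = as.character(outcome),
        lifetime_min = lifetimes_min,
        q_state = integer(length(onsets_min))
      )
    ),
    class = "lineage_trace"
  )
}

# Mixed short/long foci observed at 2-min frames: the canonical bimodal
# regime (repair-failure probability boosted for class balance).
bimodal_foci <- function(seed = 703, n_lineages = 50,
                         window_generations = 30, failure_prob = 0.3) {
  p <- sim_params(error_rate_per_min = 0.065, failure_prob = failure_prob,
                  n_lineages = n_lineages,
                  window_generations = window_generations, seed = seed)
  apply_imaging(simulate_lineages(p), imaging_config(120))
}

# Short-lived-only foci at a fine frame interval (repair-kinetics regime).
short_foci <- function(seed = 401, frame_interval_s = 7.5,
                       n_lineages = 170, window_generations = 20,
                       tau_short_s = 40) {
  p <- sim_params(error_rate_per_min = 0.06, failure_prob = 0,
                  tau_short_s = tau_short_s, n_lineages = n_lineages,
                  window_generations = window_generations, seed = seed)
  apply_imaging(simulate_lineages(p), imaging_config(frame_interval_s))
}

# Telegraph burst parameters with 1% time-averaged failure probability and
# a mean impaired-state dwell of 40 min (~1.5 generations).
burst_params_1pct <- function() {
  list(q_high = 0.25, rate_on = 5.208e-4, rate_off = 0.025)
}

# Long-term classified foci table at the canonical long-run scale.
longrun_foci <- function(seed, n_lineages = 400, failure_prob = 0.01,
                         burst_params = NULL, error_rate_per_min = 0.065) {
  p <- sim_params(error_rate_per_min = error_rate_per_min,
                  failure_prob = failure_prob,
                  burst_params = burst_params,
                  n_lineages = n_lineages, window_generations = 100,
                  seed = seed)
  f <- apply_imaging(simulate_lineages(p), imaging_config(120))
  nft <- attr(f, "n_frames_total")
  f <- classify_foci(f, 14)
  attr(f, "n_frames_total") <- nft
  f
}
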