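#' @importFrom stats poisson.test binom.test t.test dbinom var
NULL

#' Probability that a short-lived focus is detected under discrete imaging
#'
#' A focus with exponential lifetime (mean `tau_s`) whose onset has uniform
#' phase relative to the frame grid covers at least one frame time with
#' probability `(tau/dt) * (1 - exp(-dt/tau))`. At fine frame intervals this
#' tends to 1; at 2-min intervals with a 40-s mean lifetime only ~32% of
#' short-lived foci are caught, which is why raw focus rates must be
#' detection-corrected before comparing conditions.
#'
#' @param tau_s Mean focus lifetime in seconds.
#' @param dt_s Frame interval in seconds.
#' @return Detection probability in (0, 1].
#' @examples
#' detection_probability(40, 120) # ~0.317
#' @export
detection_probability <- function(tau_s, dt_s) {
  stopifnot(is.numeric(tau_s), is.numeric(dt_s),
            all(is.finite(tau_s)), all(is.finite(dt_s)),
            all(tau_s > 0), all(dt_s > 0))
  r <- tau_s / dt_s
  r * (1 - exp(-1 / r))
}

# Exact (Garwood) Poisson CI for a count, returned as a rate per unit
# exposure.
garwood_rate_ci <- function(n_events, exposure, conf_level = 0.95) {
  ci <- stats::poisson.test(n_events, conf.level = conf_level)$conf.int
  as.numeric(ci) / exposure
}

new_rate_estimate <- function(kind, n_events, exposure_min, generations,
                              raw_rate_min, corrected_rate_min,
                              detection_probability, ci_rate_min,
                              conf_level) {
  structure(
    list(
      kind = kind,
      n_events = n_events,
      exposure_min = exposure_min,
      generations = generations,
      raw_rate_min = raw_rate_min,
      raw_rate_gen = raw_rate_min * (exposure_min / generations),
      corrected_rate_min = corrected_rate_min,
      corrected_rate_gen = corrected_rate_min * (exposure_min / generations),
      detection_probability = detection_probability,
      ci_rate_min = ci_rate_min,
      ci_rate_gen = ci_rate_min * (exposure_min / generations),
      conf_level = conf_level
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s rate estimate (n = %s events, exposure = %.4g min = %.4g generations)\n",
              x$kind, format(x$n_events), x$exposure_min, x$generations))
  cat(sprintf("  raw       : %.4g /min  (%.4g /generation)\n",
              x$raw_rate_min, x$raw_rate_gen))
  cat(sprintf("  corrected : %.4g /min  (%.4g /generation), p_detect = %.3g\n",
              x$corrected_rate_min, x$corrected_rate_gen,
              x$detection_probability))
  cat(sprintf("  %d%% CI (corrected): %.4g-%.4g /min (%.4g-%.4g /generation)\n",
              round(100 * x$conf_level),
              x$ci_rate_min[1], x$ci_rate_min[2],
              x$ci_rate_gen[1], x$ci_rate_gen[2]))
  invisible(x)
}

#' Detection-corrected total error-production rate
#'
#' Short-lived foci are undercounted at coarse frame intervals; long-lived
#' foci (lifetimes near a doubling time, far exceeding the frame interval)
#' are assumed fully detected. The corrected total rate is
#' `(n_short / p_short + n_long) / exposure`, reported per minute and per
#' generation. The Poisson CI is computed on the observed total count
#' (Garwood exact) and scaled by the correction factor.
#'
#' @param n_short,n_long Observed short- and long-lived focus counts.
#' @param exposure_min Total observed lineage-time in minutes.
#' @param p_short Detection probability for short-lived foci, from
#'   [detection_probability()].
#' @param doubling_min Doubling time in minutes used to convert exposure to
#'   generations. Default 26.6.
#' @param conf_level Confidence level. Default 0.95.
#' @return A `rate_estimate` object.
#' @examples
#' corrected_total_rate(100, 1, 5000, detection_probability(40, 120))
#' @export
corrected_total_rate <- function(n_short, n_long, exposure_min, p_short,
                                 doubling_min = 26.6, conf_level = 0.95) {
  stopifnot(n_short >= 0, n_long >= 0, exposure_min > 0,
            is.numeric(p_short), length(p_short) == 1L,
            p_short > 0, p_short <= 1, doubling_min > 0)
  n_obs <- n_short + n_long
  raw <- n_obs / exposure_min
  corrected <- (n_short / p_short + n_long) / exposure_min
  inflation <- if (n_obs > 0) corrected / raw else 1 / p_short
  ci <- garwood_rate_ci(n_obs, exposure_min, conf_level) * inflation
  new_rate_estimate(
    kind = "total focus", n_events = n_obs, exposure_min = exposure_min,
    generations = exposure_min / doubling_min,
    raw_rate_min = raw, corrected_rate_min = corrected,
    detection_probability = p_short, ci_rate_min = ci,
    conf_level = conf_level
  )
}

#' Detection weight for single-frame foci
#'
#' Horvitz-Thompson inverse-detection weight for a focus observed on exactly
#' one frame, under exponential lifetimes with mean `tau_s` and uniform
#' phase. A focus observed on two or more frames must have lived longer than
#' one frame interval and so was detected with probability 1; only
#' single-frame foci can have lifetimes short enough to be missed, and their
#' average inverse detection probability is this weight.
#'
#' @param tau_s Mean short-focus lifetime, seconds.
#' @param dt_s Frame interval, seconds.
#' @return Weight >= 1 to apply to single-frame focus counts.
#' @examples
#' single_frame_weight(40, 120) # ~3.27
#' @export
single_frame_weight <- function(tau_s, dt_s) {
  stopifnot(tau_s > 0, dt_s > 0)
  x <- dt_s / tau_s
  num <- (1 - exp(-x)) +
    exp(-x) * ((1 - exp(-x)) - (1 / x) * (1 - exp(-x) * (1 + x)))
  num / ((1 - exp(-x))^2 / x)
}

#' Span-weighted (Horvitz-Thompson) total focus rate
#'
#' Detection-corrected total focus production rate that weights each
#' detected focus by the inverse of its detection probability: foci spanning
#' two or more frames were detected with probability 1 and count once;
#' single-frame foci count [single_frame_weight()] times. Unlike the flat
#' `n_short / p_short` correction this needs no short/long classification,
#' so foci near the cutoff cannot be inflated by the wrong weight, and the
#' estimate is unbiased for any mixture of short- and long-lived foci (the
#' exponential-lifetime assumption only enters through the single-frame
#' weight).
#'
#' @param dist A [lifetime_distribution()] of all detected foci.
#' @param exposure_min Total observed lineage-time, minutes.
#' @param tau_s Mean short-focus lifetime for the single-frame weight,
#'   seconds. Default 40.
#' @param doubling_min Doubling time, minutes. Default 26.6.
#' @param conf_level Confidence level. Default 0.95.
#' @return A `rate_estimate` object.
#' @export
span_weighted_total_rate <- function(dist, exposure_min, tau_s = 40,
                                     doubling_min = 26.6,
                                     conf_level = 0.95) {
  stopifnot(inherits(dist, "lifetime_distribution"), exposure_min > 0)
  w1 <- single_frame_weight(tau_s, dist$frame_interval_s)
  n1 <- sum(dist$counts[dist$k == 1L])
  n_rest <- dist$n - n1
  corrected_n <- n1 * w1 + n_rest
  raw <- dist$n / exposure_min
  corrected <- corrected_n / exposure_min
  inflation <- if (dist$n > 0) corrected_n / dist$n else w1
  ci <- garwood_rate_ci(dist$n, exposure_min, conf_level) * inflation
  new_rate_estimate(
    kind = "total focus (span-weighted)", n_events = dist$n,
    exposure_min = exposure_min, generations = exposure_min / doubling_min,
    raw_rate_min = raw, corrected_rate_min = corrected,
    detection_probability = 1 / inflation, ci_rate_min = ci,
    conf_level = conf_level
  )
}

#' Mutation rate from long-lived foci
#'
#' Long-lived foci mark unrepaired replication errors, i.e. nascent
#' mutations, so their rate per generation estimates the mutation rate. The
#' CI is the exact (Garwood) Poisson interval.
#'
#' @param n_long Number of long-lived foci.
#' @param generations Total observed lineage-time in generations.
#' @param conf_level Confidence level. Default 0.95.
#' @return A `rate_estimate` object whose generation-unit fields carry the
#'   mutation-rate estimate; `exposure_min` is set to `generations` with a
#'   unit doubling time so per-minute fields equal per-generation fields.
#' @examples
#' mutation_rate_from_long_foci(56, 40000)
#' @export
mutation_rate_from_long_foci <- function(n_long, generations,
                                         conf_level = 0.95) {
  stopifnot(n_long >= 0, generations > 0)
  rate <- n_long / generations
  ci <- garwood_rate_ci(n_long, generations, conf_level)
  new_rate_estimate(
    kind = "long-lived focus (mutation)", n_events = n_long,
    exposure_min = generations, generations = generations,
    raw_rate_min = rate, corrected_rate_min = rate,
    detection_probability = 1, ci_rate_min = ci, conf_level = conf_level
  )
}

#' Generations per serial-dilution growth cycle
#'
#' A culture diluted `d`-fold must double `log2(d)` times to return to
#' saturation, so each cycle of a mutation-accumulation experiment
#' contributes `log2(d)` generations.
#'
#' @param dilution_factor Fold-dilution per cycle (> 1).
#' @return Generations per cycle.
#' @examples
#' generations_per_cycle(5e8) # ~28.9
#' @export
generations_per_cycle <- function(dilution_factor) {
  stopifnot(is.numeric(dilution_factor), all(dilution_factor > 1))
  log2(dilution_factor)
}

#' Mutation rate from a mutation-accumulation + sequencing experiment
#'
#' Converts mutation counts from sequenced mutation-accumulation lines into
#' a rate per genome per generation: total mutations divided by
#' (lines x generations-per-cycle x cycles).
#'
#' @param n_mutations Total mutations over all lines.
#' @param n_lines Number of independent lines.
#' @param dilution_factor Fold-dilution per cycle.
#' @param n_cycles Number of growth cycles.
#' @param conf_level Confidence level for the exact Poisson CI. Default 0.95.
#' @return List with `rate_per_generation`, `ci`, `generations_per_cycle`,
#'   `total_generations`, `n_mutations`.
#' @examples
#' ma_wgs_rate(58, 4, 5e8, 2)
#' @export
ma_wgs_rate <- function(n_mutations, n_lines, dilution_factor, n_cycles,
                        conf_level = 0.95) {
  stopifnot(n_mutations >= 0, n_lines >= 1, n_cycles >= 1,
            dilution_factor > 1)
  g <- generations_per_cycle(dilution_factor)
  total_gen <- n_lines * g * n_cycles
  list(
    rate_per_generation = n_mutations / total_gen,
    ci = garwood_rate_ci(n_mutations, total_gen, conf_level),
    generations_per_cycle = g,
    total_generations = total_gen,
    n_mutations = n_mutations
  )
}

#' Welch comparison of two sets of per-group rates
#'
#' Two-sided Welch (unequal-variance) t-test on per-experiment or per-cell-
#' group rate estimates, as used to compare the total focus rate in cells
#' with versus without a long-lived focus.
#'
#' @param a,b Numeric vectors of rates.
#' @return List with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @examples
#' compare_rate_estimates(c(0.06, 0.07, 0.065), c(0.058, 0.066, 0.071))
#' @export
compare_rate_estimates <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  if (stats::var(a) + stats::var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                df = NA_real_, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Fraction of errors whose repair fails
#'
#' Ratio of long-lived foci to the detection-corrected total focus count,
#' with a binomial CI (the corrected total is rounded to the nearest count
#' for the interval). The complement of this ratio is what is usually
#' reported as repair efficiency.
#'
#' @param n_long Long-lived focus count.
#' @param n_all_corrected Detection-corrected total focus count (>= n_long).
#' @param conf_level Confidence level. Default 0.95.
#' @return List with `fraction`, `ci`, `n_long`, `n_all_corrected`.
#' @examples
#' repair_failure_fraction(10, 1000)
#' @export
repair_failure_fraction <- function(n_long, n_all_corrected,
                                    conf_level = 0.95) {
  stopifnot(n_long >= 0, n_all_corrected >= n_long, n_all_corrected > 0)
  n_tot <- max(round(n_all_corrected), n_long)
  bt <- binom.test(n_long, n_tot, conf.level = conf_level)
  list(fraction = n_long / n_all_corrected,
       ci = as.numeric(bt$conf.int),
       n_long = n_long, n_all_corrected = n_all_corrected)
}

#' Unconditional exact test for a 2x2 table (score variant)
#'
#' Barnard-type unconditional exact test comparing two binomial proportions,
#' using the pooled-variance score statistic and maximising the tail
#' probability over the nuisance success probability on a fixed grid. Used
#' for the first-versus-last age-bin comparison of long-lived focus
#' fractions, where fixed-margin (conditional) tests are needlessly
#' conservative at small counts.
#'
#' @param tab 2x2 matrix or table: rows are the two groups, columns are
#'   success/failure counts (e.g. long-lived vs short-lived).
#' @param grid_step Nuisance-parameter grid resolution. Default 0.001.
#' @return List with `p_value`, `statistic` (observed score Z),
#'   `nuisance_at_max`, `method`.
#' @examples
#' barnard_test(matrix(c(3, 297, 4, 296), 2, byrow = TRUE))
#' @export
barnard_test <- function(tab, grid_step = 0.001) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  x1 <- tab[1, 1]; n1 <- sum(tab[1, ])
  x2 <- tab[2, 1]; n2 <- sum(tab[2, ])
  if (n1 == 0 || n2 == 0) stop("both rows need positive totals")
  score_z <- function(y1, y2) {
    p1 <- y1 / n1; p2 <- y2 / n2
    pp <- (y1 + y2) / (n1 + n2)
    v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
    z <- (p1 - p2) / sqrt(v)
    z[v == 0] <- 0
    z
  }
  y1 <- 0:n1; y2 <- 0:n2
  zmat <- outer(y1, y2, score_z)
  z_obs <- score_z(x1, x2)
  # two-sided: tables at least as extreme in |Z|
  extreme <- abs(zmat) >= abs(z_obs) - 1e-12
  pis <- seq(grid_step, 1 - grid_step, by = grid_step)
  p_of_pi <- vapply(pis, function(p) {
    b1 <- dbinom(y1, n1, p)
    b2 <- dbinom(y2, n2, p)
    as.numeric(b1 %*% extreme %*% b2)
  }, numeric(1))
  i_max <- which.max(p_of_pi)
  list(p_value = min(1, p_of_pi[i_max]),
       statistic = z_obs,
       nuisance_at_max = pis[i_max],
       method = "unconditional exact, pooled score statistic, two-sided")
}

#' Age-binned repair-failure analysis
#'
#' Bins classified foci by the replicative age (in generations) at which
#' they appear, reports the long-lived fraction per bin, and tests the
#' first bin against the last with the unconditional exact 2x2 test. In the
#' mother machine, a mother cell's replicative age grows by one per
#' division, so age in generations is onset time divided by the doubling
#' time.
#'
#' @param foci Classified focus records ([classify_foci()]) with columns
#'   `onset_frame`, `frame_interval_s`, `class`.
#' @param doubling_min Doubling time in minutes. Default 26.6.
#' @param bin_generations Age-bin width in generations. Default 10.
#' @param grid_step Passed to [barnard_test()].
#' @return List with `bins` (data.frame: `bin_start_gen`, `n_short`,
#'   `n_long`, `fraction_long`) and `endpoint_test` (first vs last bin,
#'   [barnard_test()] result).
#' @export
age_binned_analysis <- function(foci, doubling_min = 26.6,
                                bin_generations = 10, grid_step = 0.001) {
  stopifnot(is.data.frame(foci), "class" %in% names(foci),
            all(c("onset_frame", "frame_interval_s") %in% names(foci)),
            doubling_min > 0, bin_generations > 0)
  age_gen <- foci$onset_frame * foci$frame_interval_s / 60 / doubling_min
  bin <- floor(age_gen / bin_generations)
  tab <- table(bin, foci$class)
  bins <- data.frame(
    bin_start_gen = as.numeric(rownames(tab)) * bin_generations,
    n_short = as.integer(tab[, "short"]),
    n_long = as.integer(tab[, "long"])
  )
  bins$fraction_long <- bins$n_long / (bins$n_short + bins$n_long)
  if (nrow(bins) < 2L) stop("need at least two age bins")
  first <- bins[1, ]; last <- bins[nrow(bins), ]
  if (first$n_short + first$n_long == 0 || last$n_short + last$n_long == 0) {
    stop("empty endpoint age bin")
  }
  m <- matrix(c(first$n_long, first$n_short, last$n_long, last$n_short),
              2, 2, byrow = TRUE)
  list(bins = bins, endpoint_test = barnard_test(m, grid_step = grid_step))
}

#' Fold change between two Poisson rates
#'
#' Ratio of two event rates with an exposure-adjusted CI by the conditional
#' binomial method: given the total count, the first count is binomial with
#' success probability `rate_a * E_a / (rate_a * E_a + rate_b * E_b)`, so a
#' binomial CI on that probability maps to a CI on the rate ratio.
#'
#' @param n_a,n_b Event counts in the two conditions.
#' @param exposure_a,exposure_b Exposures (same units).
#' @param conf_level Confidence level. Default 0.95.
#' @return List with `ratio` (rate_a / rate_b; `Inf` when `n_b` is 0),
#'   `ci`, `rate_a`, `rate_b`. With `n_a = 0` the lower CI bound is 0; with
#'   `n_b = 0` the upper bound is `Inf`.
#' @examples
#' fold_change(20, 1000, 40, 1000)
#' @export
fold_change <- function(n_a, exposure_a, n_b, exposure_b,
                        conf_level = 0.95) {
  stopifnot(n_a >= 0, n_b >= 0, exposure_a > 0, exposure_b > 0,
            n_a + n_b > 0)
  rate_a <- n_a / exposure_a
  rate_b <- n_b / exposure_b
  bt <- binom.test(n_a, n_a + n_b, conf.level = conf_level)
  p_ci <- as.numeric(bt$conf.int)
  ratio_ci <- (p_ci / (1 - p_ci)) * (exposure_b / exposure_a)
  list(ratio = if (n_b > 0) rate_a / rate_b else Inf,
       ci = ratio_ci, rate_a = rate_a, rate_b = rate_b)
}

#' Drop foci whose spans touch the observation-window edges
#'
#' A focus visible on the first or last frame of the window has an
#' ambiguous class (its true span is right- or left-truncated), so rate
#' estimation excludes such records rather than inflating counts.
#'
#' @param foci Focus records with `onset_frame` and `n_frames`.
#' @param n_frames_total Number of frames in the window; taken from
#'   `attr(foci, "n_frames_total")` when `NULL`.
#' @return `foci` without edge-touching records.
#' @export
drop_edge_foci <- function(foci, n_frames_total = NULL) {
  stopifnot(is.data.frame(foci))
  if (is.null(n_frames_total)) n_frames_total <- attr(foci, "n_frames_total")
  stopifnot(!is.null(n_frames_total))
  if (nrow(foci) == 0L) return(foci)
  last <- foci$onset_frame + foci$n_frames - 1L
  foci[foci$onset_frame > 0L & last < n_frames_total - 1L, , drop = FALSE]
}
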