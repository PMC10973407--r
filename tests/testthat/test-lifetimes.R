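test_that("lifetime distribution is an exact span histogram", {
  foci <- data.frame(n_frames = c(1L, 1L, 4L), frame_interval_s = 120)
  d <- lifetime_distribution(foci)
  expect_equal(d$k, c(1L, 4L))
  expect_equal(d$counts, c(2L, 1L))
  expect_equal(d$n, 3L)
  expect_equal(as.data.frame(d)$lifetime_min, c(2, 8))
  # empty input
  d0 <- lifetime_distribution(data.frame(n_frames = integer(0),
                                         frame_interval_s = numeric(0)))
  expect_equal(d0$n, 0L)
  # mixed frame intervals are rejected
  expect_error(lifetime_distribution(
    data.frame(n_frames = c(1L, 2L), frame_interval_s = c(120, 30))),
    "mixed")
  expect_error(lifetime_distribution(
    data.frame(n_frames = 0L, frame_interval_s = 120)))
})

test_that("tau recovery: censored MLE covers a 40-s truth at 7.5-s frames", {
  f <- short_foci(seed = 401)
  est <- estimate_tau_censored(lifetime_distribution(f))
  expect_false(est$degenerate)
  expect_gt(est$ci_s[1], 30)
  expect_lt(est$ci_s[2], 50)
  expect_true(est$ci_s[1] <= 40 && 40 <= est$ci_s[2])
  # the raw mean of observed lifetimes overestimates tau at finite frames
  expect_gt(est$raw_mean_s, est$tau_s)
})

test_that("tau estimate is scale-equivariant in the frame interval", {
  d <- lifetime_distribution(data.frame(
    n_frames = rep(c(1L, 2L, 3L, 5L), c(50, 25, 12, 3)),
    frame_interval_s = 10))
  e1 <- estimate_tau_censored(d)
  d2 <- d; d2$frame_interval_s <- 30 # same spans, 3x coarser clock
  e2 <- estimate_tau_censored(d2)
  expect_equal(e2$tau_s, 3 * e1$tau_s)
  expect_equal(e2$ci_s, 3 * e1$ci_s)
})

test_that("tau estimates agree across re-discretizations of the same truth", {
  traces <- simulate_lineages(sim_params(error_rate_per_min = 0.06,
                                         failure_prob = 0, tau_short_s = 40,
                                         n_lineages = 170,
                                         window_generations = 20,
                                         seed = 409))
  e1 <- estimate_tau_censored(lifetime_distribution(
    apply_imaging(traces, imaging_config(7.5))))
  e2 <- estimate_tau_censored(lifetime_distribution(
    apply_imaging(traces, imaging_config(15))))
  expect_lt(abs(e1$tau_s - e2$tau_s),
            2 * sqrt(e1$se_s^2 + e2$se_s^2) + 1e-9)
})

test_that("all-single-frame data give a flagged degenerate estimate with an upper bound", {
  d <- lifetime_distribution(data.frame(n_frames = rep(1L, 200),
                                        frame_interval_s = 120))
  expect_warning(est <- estimate_tau_censored(d), "degenerate")
  expect_true(est$degenerate)
  expect_true(is.na(est$tau_s))
  expect_true(is.finite(est$ci_s[2]) && est$ci_s[2] > 0)
  # the bound shrinks with more observations
  d2 <- lifetime_distribution(data.frame(n_frames = rep(1L, 2000),
                                         frame_interval_s = 120))
  est2 <- suppressWarnings(estimate_tau_censored(d2))
  expect_lt(est2$ci_s[2], est$ci_s[2])
})

test_that("the censored MLE approaches the sample mean as frames become fine", {
  traces <- simulate_lineages(sim_params(error_rate_per_min = 0.06,
                                         failure_prob = 0, tau_short_s = 40,
                                         n_lineages = 120,
                                         window_generations = 20,
                                         seed = 411))
  gap <- vapply(c(30, 15, 7.5, 2), function(dt_s) {
    est <- estimate_tau_censored(lifetime_distribution(
      apply_imaging(traces, imaging_config(dt_s))))
    abs(est$raw_mean_s - est$tau_s)
  }, numeric(1))
  # discrepancy between MLE and raw mean is bounded by the frame interval
  expect_true(all(gap <= c(30, 15, 7.5, 2)))
  expect_true(all(diff(gap) < 0))
})

test_that("cutoff finds a valley between the 2-min and doubling-time modes", {
  f <- bimodal_foci(seed = 703)
  co <- determine_cutoff(lifetime_distribution(f))
  expect_true(co$success)
  expect_gt(co$cutoff_min, co$modes_min[1])
  expect_lt(co$cutoff_min, co$modes_min[2])
  expect_gt(co$cutoff_min, 6)
  expect_lt(co$cutoff_min, 20)
  # low mode at one frame, high mode near the doubling time
  expect_lt(abs(co$modes_min[1] - 2), 1)
  expect_lt(abs(co$modes_min[2] - 26.6), 5)
})

test_that("cutoff is exactly invariant under dataset duplication", {
  f <- bimodal_foci(seed = 705, n_lineages = 30)
  co1 <- determine_cutoff(lifetime_distribution(f))
  co2 <- determine_cutoff(lifetime_distribution(rbind(f, f)))
  expect_identical(co1$cutoff_min, co2$cutoff_min)
})

test_that("pure short-lived input yields a unimodal failure state", {
  p <- sim_params(error_rate_per_min = 0.065, failure_prob = 0,
                  n_lineages = 60, window_generations = 20, seed = 9)
  f <- apply_imaging(simulate_lineages(p), imaging_config(120))
  co <- determine_cutoff(lifetime_distribution(f))
  expect_false(co$success)
  expect_true(is.na(co$cutoff_min))
})

test_that("cutoff refuses tiny datasets", {
  f <- data.frame(n_frames = rep(c(1L, 13L), 10), frame_interval_s = 120)
  expect_error(determine_cutoff(lifetime_distribution(f)), "at least 50")
})

test_that("classification uses a strict inequality at the cutoff", {
  foci <- data.frame(n_frames = c(7L, 8L), frame_interval_s = 120)
  cl <- classify_foci(foci, cutoff_min = 14)
  expect_equal(as.character(cl$class), c("short", "long"))
  expect_equal(cl$lifetime_min, c(14, 16))
  # counts are conserved
  f <- bimodal_foci(seed = 707, n_lineages = 20)
  cl <- classify_foci(f, 14)
  expect_equal(sum(cl$class == "short") + sum(cl$class == "long"), nrow(f))
  expect_error(classify_foci(foci, cutoff_min = 1))
})

test_that("classified long-lived fraction tracks the failure probability", {
  f <- longrun_foci(seed = 611, n_lineages = 150)
  # observed long fraction of *corrected* totals ~ q = 0.01
  interior <- drop_edge_foci(f)
  n_long <- sum(interior$class == "long")
  n_short <- sum(interior$class == "short")
  frac <- n_long / (n_short / detection_probability(40, 120) + n_long)
  expect_lt(abs(frac - 0.01), 0.005)
})

test_that("cutoff shifts of +/- 2 min barely change classification", {
  f <- bimodal_foci(seed = 703)
  base <- classify_foci(f, 14)$class
  for (cut in c(12, 16)) {
    moved <- mean(classify_foci(f, cut)$class != base)
    expect_lt(moved, 0.05)
  }
})

test_that("bleaching comparison flags only genuinely divergent lifetimes", {
  traces <- simulate_lineages(sim_params(error_rate_per_min = 0.1,
                                         failure_prob = 0, tau_short_s = 40,
                                         n_lineages = 120,
                                         window_generations = 20,
                                         seed = 503))
  d75 <- lifetime_distribution(apply_imaging(traces, imaging_config(7.5)))
  d30 <- lifetime_distribution(apply_imaging(traces, imaging_config(30)))
  bl <- apply_imaging(traces, imaging_config(7.5, bleach_per_exposure = 0.2),
                      seed = 3)
  dbl <- lifetime_distribution(bl)
  rep_clean <- compare_bleaching(list(dt7.5 = d75, dt30 = d30))
  expect_false(any(rep_clean$significant))
  rep_bleach <- compare_bleaching(list(clean = d75, bleached = dbl))
  expect_true(all(rep_bleach$significant))
  # identical inputs have zero distance
  rep_same <- compare_bleaching(list(a = d75, b = d75))
  expect_equal(rep_same$statistic, 0)
  expect_false(any(rep_same$significant))
})
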