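test_that("detection probability has the right limits and rejects bad input", {
  expect_lt(abs(detection_probability(40, 120) - 0.3167376), 1e-6)
  expect_gt(detection_probability(4000, 1), 0.999)
  expect_gt(detection_probability(40, 0.01), 0.999)
  expect_true(all(diff(detection_probability(40, c(240, 120, 30, 7.5))) > 0))
  expect_error(detection_probability(0, 120))
  expect_error(detection_probability(40, -1))
})

test_that("detection probability matches a brute-force placement oracle", {
  set.seed(88)
  for (ratio in c(0.33, 3)) {
    dt <- 120; tau <- ratio * dt
    n <- 2e5
    hit <- mean(runif(n, 0, dt) < rexp(n, 1 / tau))
    p <- detection_probability(tau, dt)
    expect_lt(abs(hit - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("corrected total rate reduces to the raw rate when detection is complete", {
  r <- corrected_total_rate(100, 5, 1000, p_short = 1)
  expect_equal(r$corrected_rate_min, r$raw_rate_min)
  expect_equal(r$raw_rate_min, 0.105)
  # per-generation rate is exactly per-minute rate times the doubling time
  expect_equal(r$corrected_rate_gen, r$corrected_rate_min * 26.6)
  # no short foci: correction leaves the long-focus rate
  r0 <- corrected_total_rate(0, 7, 1000, p_short = 0.3)
  expect_equal(r0$corrected_rate_min, 7 / 1000)
  expect_error(corrected_total_rate(10, 1, 100, p_short = 0))
  expect_error(corrected_total_rate(10, 1, 100, p_short = 1.2))
})

test_that("corrected rate estimates are invariant to the frame interval", {
  # at 7.5-s frames detection is ~0.91, at 2-min frames ~0.32; corrected
  # totals from the same truth agree within a percent-scale tolerance
  traces <- simulate_lineages(sim_params(error_rate_per_min = 0.065,
                                         failure_prob = 0.01,
                                         n_lineages = 150,
                                         window_generations = 30,
                                         seed = 211))
  est <- lapply(c(7.5, 120), function(dt_s) {
    f <- apply_imaging(traces, imaging_config(dt_s))
    nft <- attr(f, "n_frames_total")
    f <- classify_foci(f, 14)
    f <- drop_edge_foci(f, nft)
    corrected_total_rate(sum(f$class == "short"), sum(f$class == "long"),
                         exposure_min = 150 * 30 * 26.6,
                         p_short = detection_probability(40, dt_s))
  })
  expect_lt(abs(est[[1]]$corrected_rate_min - est[[2]]$corrected_rate_min) /
              est[[1]]$corrected_rate_min, 0.05)
  # and both cover the simulated truth
  for (e in est) {
    expect_true(e$ci_rate_min[1] <= 0.065 && 0.065 <= e$ci_rate_min[2])
  }
})

test_that("span-weighted totals are classification-free and unbiased", {
  # weight limits: as dt -> 0 only foci with lifetime < dt stay on one
  # frame and their mean inverse detection probability tends to 3/2 (while
  # the single-frame fraction itself vanishes); at 2-min frames the weight
  # is ~3.3 (checked against a brute-force placement oracle)
  expect_lt(abs(single_frame_weight(40, 0.1) - 1.5), 0.01)
  expect_true(all(diff(single_frame_weight(40, c(1, 30, 120, 600))) > 0))
  set.seed(91)
  n <- 2e5; dt <- 120; tau <- 40
  L <- rexp(n, 1 / tau); u <- runif(n, 0, dt)
  det <- u < L
  span1 <- det & ceiling((L - u) / dt) == 1
  w_oracle <- (n - sum(det & !span1)) / sum(span1) # weight making sum w = n
  expect_lt(abs(single_frame_weight(tau, dt) - w_oracle),
            3 * w_oracle / sqrt(sum(span1)))
  # mixed short/long population: estimate covers the simulated truth and
  # never drops below the raw rate
  p <- sim_params(error_rate_per_min = 0.065, failure_prob = 0.3,
                  n_lineages = 150, window_generations = 30, seed = 219)
  f <- apply_imaging(simulate_lineages(p), imaging_config(120))
  r <- span_weighted_total_rate(lifetime_distribution(f),
                                exposure_min = 150 * 30 * 26.6)
  expect_true(r$ci_rate_min[1] <= 0.065 && 0.065 <= r$ci_rate_min[2])
  expect_gte(r$corrected_rate_min, r$raw_rate_min)
})

test_that("mutation rate from long foci uses the exact Poisson interval", {
  r0 <- mutation_rate_from_long_foci(0, 1000)
  expect_equal(r0$corrected_rate_gen, 0)
  expect_lt(abs(r0$ci_rate_gen[2] - 3.688879 / 1000), 1e-6)
  r1 <- mutation_rate_from_long_foci(56, 40000)
  r2 <- mutation_rate_from_long_foci(56, 80000)
  expect_equal(r1$corrected_rate_gen, 2 * r2$corrected_rate_gen)
})

test_that("MA+WGS arithmetic converts dilution factors to generations", {
  expect_equal(generations_per_cycle(2), 1)
  expect_lt(abs(generations_per_cycle(5e8) - 28.897), 0.001)
  r <- ma_wgs_rate(58, 4, 5e8, 2)
  expect_lt(abs(r$rate_per_generation - 58 / (4 * log2(5e8) * 2)), 1e-12)
  expect_lt(abs(r$rate_per_generation - 0.2509), 5e-4)
  expect_true(r$ci[1] < r$rate_per_generation &
                r$rate_per_generation < r$ci[2])
})

test_that("Welch comparison behaves at the null, under shifts, and under swaps", {
  a <- c(0.06, 0.07, 0.065, 0.061)
  expect_equal(compare_rate_estimates(a, a)$p_value, 1)
  w1 <- compare_rate_estimates(a, rev(a) + 0.01)
  w2 <- compare_rate_estimates(rev(a) + 0.01, a)
  expect_equal(w1$p_value, w2$p_value)
  expect_equal(w1$statistic, -w2$statistic)
  set.seed(12)
  low_p <- replicate(10, {
    compare_rate_estimates(rnorm(50), rnorm(50, 1))$p_value
  })
  expect_true(all(low_p < 0.01))
  # constant, equal samples: no variance, no difference
  expect_equal(compare_rate_estimates(rep(1, 3), rep(1, 3))$p_value, 1)
})

test_that("repair failure fraction recovers the simulated failure probability", {
  f <- longrun_foci(seed = 613, n_lineages = 150)
  interior <- drop_edge_foci(f)
  n_long <- sum(interior$class == "long")
  n_all <- sum(interior$class == "short") / detection_probability(40, 120) +
    n_long
  rf <- repair_failure_fraction(n_long, n_all)
  expect_true(rf$ci[1] <= 0.01 && 0.01 <= rf$ci[2])
  expect_equal(repair_failure_fraction(0, 500)$fraction, 0)
})

test_that("unconditional 2x2 test separates null-like from divergent tables", {
  p_null <- barnard_test(matrix(c(3, 297, 4, 296), 2, byrow = TRUE))
  expect_gt(p_null$p_value, 0.5)
  p_alt <- barnard_test(matrix(c(0, 300, 30, 270), 2, byrow = TRUE))
  expect_lt(p_alt$p_value, 0.001)
  p_same <- barnard_test(matrix(c(12, 34, 12, 34), 2, byrow = TRUE))
  expect_equal(p_same$p_value, 1)
  expect_error(barnard_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)))
})

test_that("unconditional 2x2 test equals the enumeration oracle on small tables", {
  tables <- list(
    matrix(c(3, 27, 8, 22), 2, byrow = TRUE),
    matrix(c(1, 14, 6, 9), 2, byrow = TRUE),
    matrix(c(0, 20, 5, 15), 2, byrow = TRUE),
    matrix(c(10, 20, 20, 40), 2, byrow = TRUE)
  )
  for (tab in tables) {
    expect_lt(abs(barnard_test(tab, grid_step = 0.01)$p_value -
                    barnard_oracle(tab, grid_step = 0.01)), 1e-10)
  }
})

test_that("age-binned analysis detects stability and change across age", {
  # stable failure fraction across age bins: large p
  f <- longrun_foci(seed = 617, n_lineages = 200)
  interior <- drop_edge_foci(f)
  res <- age_binned_analysis(interior, doubling_min = 26.6)
  expect_equal(nrow(res$bins), 10)
  expect_gt(res$endpoint_test$p_value, 0.05)
  expect_true(all(res$bins$n_short + res$bins$n_long > 0))
  # an age-dependent failure fraction is detected: build foci whose long
  # fraction jumps in the last bin
  synth <- data.frame(
    lineage_id = 1L,
    onset_frame = c(sample(0:132, 400, TRUE), sample(1197:1329, 400, TRUE)),
    n_frames = c(rep(c(1L, 14L), c(395, 5)), rep(c(1L, 14L), c(340, 60))),
    frame_interval_s = 120
  )
  synth <- classify_foci(synth, 14)
  res2 <- age_binned_analysis(synth, doubling_min = 26.6)
  expect_lt(res2$endpoint_test$p_value, 0.001)
})

test_that("fold change between Poisson rates has exposure-adjusted intervals", {
  eq <- fold_change(30, 1000, 30, 1000)
  expect_equal(eq$ratio, 1)
  expect_true(eq$ci[1] < 1 && 1 < eq$ci[2])
  # halved exposure doubles the ratio
  expect_equal(fold_change(30, 500, 30, 1000)$ratio, 2)
  z <- fold_change(0, 1000, 20, 1000)
  expect_equal(z$ratio, 0)
  expect_equal(z$ci[1], 0)
  expect_true(is.finite(z$ci[2]))
  zz <- fold_change(20, 1000, 0, 1000)
  expect_true(is.infinite(zz$ratio) && is.infinite(zz$ci[2]))
  # a simulated 2x difference is detected in most seeds
  set.seed(5)
  excl <- replicate(10, {
    n_a <- rpois(1, 100); n_b <- rpois(1, 200)
    ci <- fold_change(n_a, 1000, n_b, 1000)$ci
    ci[2] < 1 || ci[1] > 1
  })
  expect_gte(mean(excl), 0.8)
})

test_that("edge-touching foci are excluded from rate inputs", {
  f <- data.frame(lineage_id = 1L, onset_frame = c(0L, 5L, 95L, 50L),
                  n_frames = c(3L, 2L, 5L, 4L), frame_interval_s = 120)
  kept <- drop_edge_foci(f, n_frames_total = 100L)
  expect_equal(kept$onset_frame, c(5L, 50L))
})
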