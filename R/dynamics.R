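#' Inter-arrival times between focus onsets within lineages
#'
#' Computes gaps between successive focus onset frames within each lineage,
#' optionally restricted to long-lived foci. Onsets sharing a frame collapse
#' to a single onset (two spots in one frame are not temporally resolvable),
#' so every gap is at least one frame. The gap from the last onset to the
#' end of the window is recorded as right-censored; censored gaps never
#' enter empirical CDFs directly but are reproduced by the Monte-Carlo null.
#'
#' @param foci Focus records (`lineage_id`, `onset_frame`,
#'   `frame_interval_s`; plus `class` if filtering). Attribute
#'   `n_frames_total` (set by [apply_imaging()]) or the `n_frames_total`
#'   argument supplies the window length in frames.
#' @param class_filter `"all"` or `"long"` (requires a `class` column from
#'   [classify_foci()]).
#' @param n_frames_total Frames per lineage window; defaults to
#'   `attr(foci, "n_frames_total")`.
#' @param n_lineages Number of observed lineages contributing exposure
#'   (including lineages without any onset of the filtered class). Defaults
#'   to the number of distinct `lineage_id`s in `foci` before filtering;
#'   pass it explicitly when some lineages produced no foci at all.
#' @return Object of class `interarrival_set`: list with `gaps`
#'   (data.frame: `lineage_id`, `gap_frames`, `gap_min`, `censored`),
#'   `dt_min`, `n_onsets`, `total_window_min`, `rate_per_min` (pooled onset
#'   rate), `n_closed`.
#' @examples
#' foci <- data.frame(lineage_id = 1, onset_frame = c(3, 10, 10, 25),
#'                    n_frames = 1, frame_interval_s = 120)
#' interarrival_times(foci, n_frames_total = 100)$gaps
#' @export
interarrival_times <- function(foci, class_filter = c("all", "long"),
                               n_frames_total = NULL, n_lineages = NULL) {
  class_filter <- match.arg(class_filter)
  stopifnot(is.data.frame(foci),
            all(c("lineage_id", "onset_frame", "frame_interval_s")
                %in% names(foci)))
  if (is.null(n_frames_total)) n_frames_total <- attr(foci, "n_frames_total")
  stopifnot(!is.null(n_frames_total), n_frames_total >= 1)
  if (is.null(n_lineages)) n_lineages <- length(unique(foci$lineage_id))
  dt_min <- unique(foci$frame_interval_s) / 60
  if (length(dt_min) > 1L) stop("mixed frame intervals")
  if (length(dt_min) == 0L) dt_min <- NA_real_
  if (class_filter == "long") {
    stopifnot("class" %in% names(foci))
    foci <- foci[foci$class == "long", , drop = FALSE]
  }
  ids <- unique(foci$lineage_id)
  gap_list <- lapply(ids, function(id) {
    fr <- sort(unique(foci$onset_frame[foci$lineage_id == id]))
    closed <- if (length(fr) >= 2L) diff(fr) else integer(0)
    tail_gap <- (n_frames_total - 1L) - fr[length(fr)]
    data.frame(
      lineage_id = id,
      gap_frames = c(closed, tail_gap),
      censored = c(rep(FALSE, length(closed)), TRUE)
    )
  })
  gaps <- if (length(gap_list)) do.call(rbind, gap_list) else
    data.frame(lineage_id = integer(0), gap_frames = integer(0),
               censored = logical(0))
  gaps$gap_min <- gaps$gap_frames * dt_min
  n_onsets <- sum(!duplicated(foci[c("lineage_id", "onset_frame")]))
  total_window_min <- n_frames_total * dt_min * max(n_lineages, 1L)
  structure(
    list(
      gaps = gaps[order(gaps$lineage_id), c("lineage_id", "gap_frames",
                                            "gap_min", "censored")],
      dt_min = dt_min,
      n_frames_total = n_frames_total,
      n_lineages = n_lineages,
      n_onsets = n_onsets,
      total_window_min = total_window_min,
      rate_per_min = n_onsets / total_window_min,
      n_closed = sum(!gaps$censored),
      class_filter = class_filter
    ),
    class = "interarrival_set"
  )
}

#' @export
print.interarrival_set <- function(x, ...) {
  cat(sprintf(
    "Inter-arrival set (%s foci): %d closed gaps, %d censored tails, %d lineages\n",
    x$class_filter, x$n_closed, sum(x$gaps$censored), x$n_lineages))
  cat(sprintf("  pooled onset rate: %.4g /min over %.4g lineage-min\n",
              x$rate_per_min, x$total_window_min))
  invisible(x)
}

#' Analytic gap CDF for Poisson onsets observed on a frame grid
#'
#' Under homogeneous Poisson onsets at rate `lambda`, frames are occupied
#' independently with probability `1 - exp(-lambda * dt)`, so the gap (in
#' frames) between successive occupied frames is geometric and the CDF at a
#' gap of `k` frames is `1 - exp(-lambda * k * dt)` — the exponential CDF
#' corrected for discrete observation, evaluated on the frame grid.
#'
#' @param lambda_per_min Onset rate per minute.
#' @param dt_min Frame interval in minutes.
#' @param k_frames Gap length(s) in frames (integer >= 1).
#' @return CDF value(s) in (0, 1).
#' @examples
#' poisson_gap_cdf(0.05, 2, 5) # 1 - exp(-0.5)
#' @export
poisson_gap_cdf <- function(lambda_per_min, dt_min, k_frames) {
  stopifnot(lambda_per_min > 0, dt_min > 0,
            all(k_frames >= 1), all(k_frames == round(k_frames)))
  1 - exp(-lambda_per_min * k_frames * dt_min)
}

# Simulate Poisson onsets through the windowing/frame-collapse pipeline for
# a batch of windows (one entry of window_frames per lineage-replicate) and
# return closed gap lengths in frames.
sim_null_gaps <- function(rate_per_min, window_frames, dt_min,
                          detect_p = 1) {
  window_min <- window_frames * dt_min
  counts <- rpois(length(window_frames), rate_per_min * window_min)
  id <- rep.int(seq_along(window_frames), counts)
  t <- runif(sum(counts)) * rep.int(window_min, counts)
  wmax <- rep.int(as.integer(window_frames) - 1L, counts)
  if (detect_p < 1) {
    keep <- runif(length(t)) < detect_p
    id <- id[keep]; t <- t[keep]; wmax <- wmax[keep]
  }
  frame <- pmin(floor(t / dt_min), wmax)
  ord <- order(id, frame)
  id <- id[ord]; frame <- frame[ord]
  dup <- c(FALSE, id[-1] == id[-length(id)] & frame[-1] == frame[-length(frame)])
  id <- id[!dup]; frame <- frame[!dup]
  if (length(id) < 2L) {
    return(list(gaps = integer(0), n_onsets = length(id)))
  }
  same <- id[-1] == id[-length(id)]
  list(gaps = (frame[-1] - frame[-length(frame)])[same],
       n_onsets = length(id))
}

#' Monte-Carlo null prediction for the gap CDF
#'
#' Simulates homogeneous Poisson onsets at the given rate through the same
#' finite-window, frame-binning, same-frame-collapse pipeline as the data,
#' and returns the predicted CDF of closed gaps on the frame grid. This is
#' the bias-corrected analytic prediction: it converges to
#' [poisson_gap_cdf()] as windows grow, but at finite windows long gaps are
#' preferentially censored, shifting the closed-gap CDF toward shorter gaps.
#'
#' @param rate_per_min Onset rate per minute (typically the pooled empirical
#'   rate of an [interarrival_times()] set).
#' @param window_frames Integer vector of window lengths (frames), one per
#'   lineage.
#' @param dt_min Frame interval in minutes.
#' @param n_reps Number of Monte-Carlo replicates of the whole lineage set.
#'   Default 200.
#' @param seed Integer seed.
#' @param detect_p Per-onset detection (thinning) probability. Default 1.
#' @return Object of class `null_gap_cdf`: list with `k` (1..max gap
#'   simulated), `cdf`, `n_gaps`, `rate_per_min`, `dt_min`, `n_reps`,
#'   `seed`, and `cdf_at(k)` lookup via [predict_gap_cdf()].
#' @export
null_prediction_mc <- function(rate_per_min, window_frames, dt_min,
                               n_reps = 200, seed = 1, detect_p = 1) {
  stopifnot(rate_per_min > 0, dt_min > 0, all(window_frames >= 1),
            n_reps >= 1)
  gaps <- with_local_seed(seed, {
    all_windows <- rep(as.integer(window_frames), n_reps)
    sim_null_gaps(rate_per_min, all_windows, dt_min, detect_p)$gaps
  })
  if (length(gaps) == 0L) stop("null simulation produced no closed gaps; ",
                               "increase n_reps or the rate")
  k_max <- max(gaps)
  cdf <- cumsum(tabulate(gaps, nbins = k_max)) / length(gaps)
  structure(
    list(k = seq_len(k_max), cdf = cdf, n_gaps = length(gaps),
         rate_per_min = rate_per_min, dt_min = dt_min, n_reps = n_reps,
         seed = seed, detect_p = detect_p),
    class = "null_gap_cdf"
  )
}

#' Evaluate a Monte-Carlo null gap CDF at gap lengths
#'
#' @param null A [null_prediction_mc()] object.
#' @param k_frames Gap length(s) in frames.
#' @return CDF values (1 beyond the largest simulated gap).
#' @export
predict_gap_cdf <- function(null, k_frames) {
  stopifnot(inherits(null, "null_gap_cdf"), all(k_frames >= 0))
  c(0, null$cdf)[pmin(k_frames, length(null$cdf)) + 1]
}

# sup-norm distance between the empirical CDF of closed gaps and the
# analytic geometric CDF at the given rate, over the frame grid
gap_ks_statistic <- function(gap_frames, rate_per_min, dt_min) {
  k_max <- max(gap_frames)
  ecdf_k <- cumsum(tabulate(gap_frames, nbins = k_max)) / length(gap_frames)
  theo <- poisson_gap_cdf(rate_per_min, dt_min, seq_len(k_max))
  max(abs(ecdf_k - theo))
}

#' Goodness of fit of focus onsets to Poisson dynamics
#'
#' Tests whether onset inter-arrival times are consistent with a homogeneous
#' Poisson process, the expectation when error production is Poissonian and
#' repair failure has constant probability (a compound Poisson process with
#' Bernoulli increments is again Poisson). The statistic is the sup-norm
#' distance between the empirical closed-gap CDF and the discrete-
#' observation-corrected exponential CDF at the pooled empirical rate. Its
#' null distribution is obtained by parametric bootstrap: onsets are
#' re-simulated through the same finite windows, frame binning, same-frame
#' collapse and tail censoring as the data, and the rate is re-estimated in
#' every replicate, so both finite-window bias and rate-estimation noise are
#' accounted for.
#'
#' @param gaps An [interarrival_times()] set.
#' @param n_boot Bootstrap replicates. Default 1999.
#' @param seed Integer seed (results are reproducible given the seed).
#' @param min_gaps Minimum closed gaps required. Default 20.
#' @return Object of class `gof_result`: list with `statistic`, `p_value`,
#'   `n_boot`, `rate_per_min`, `n_gaps`, `seed`.
#' @export
gof_poisson <- function(gaps, n_boot = 1999, seed = 1, min_gaps = 20) {
  stopifnot(inherits(gaps, "interarrival_set"), n_boot >= 1)
  closed <- gaps$gaps$gap_frames[!gaps$gaps$censored]
  if (length(closed) < min_gaps) {
    stop("need at least ", min_gaps, " closed gaps to test Poisson ",
         "dynamics; got ", length(closed))
  }
  if (gaps$n_onsets == 0 || gaps$rate_per_min <= 0) {
    stop("no onsets: rate cannot be estimated")
  }
  d_obs <- gap_ks_statistic(closed, gaps$rate_per_min, gaps$dt_min)
  windows <- rep(as.integer(gaps$n_frames_total), gaps$n_lineages)
  total_window_min <- gaps$total_window_min
  d_boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        sim <- sim_null_gaps(gaps$rate_per_min, windows, gaps$dt_min)
        if (length(sim$gaps) >= 2L) break
      }
      rate_b <- sim$n_onsets / total_window_min
      gap_ks_statistic(sim$gaps, rate_b, gaps$dt_min)
    }, numeric(1))
  })
  p <- (1 + sum(d_boot >= d_obs)) / (n_boot + 1)
  structure(
    list(statistic = d_obs, p_value = p, n_boot = n_boot,
         rate_per_min = gaps$rate_per_min, n_gaps = length(closed),
         seed = seed, class_filter = gaps$class_filter),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "Poisson-dynamics GOF (%s foci): D = %.4g, p = %.4g (%d gaps, %d bootstrap reps, rate %.4g /min)\n",
    x$class_filter, x$statistic, x$p_value, x$n_gaps, x$n_boot,
    x$rate_per_min))
  invisible(x)
}

#' Over-representation of short inter-arrival times
#'
#' Compares the observed fraction of closed gaps shorter than a threshold
#' with the fraction expected under Poisson onsets at the pooled empirical
#' rate (from the Monte-Carlo null, so finite-window bias is shared), via a
#' binomial test. An excess ratio above 1 indicates temporal clustering of
#' onsets — for long-lived foci, mutation bursts.
#'
#' @param gaps An [interarrival_times()] set.
#' @param threshold_min Gap threshold in minutes; must exceed the frame
#'   interval. Default 40.
#' @param n_reps Monte-Carlo replicates for the null. Default 200.
#' @param seed Integer seed.
#' @return List with `excess_ratio`, `p_value`, `observed_fraction`,
#'   `null_fraction`, `n_short`, `n_gaps`, `threshold_min`.
#' @export
short_gap_enrichment <- function(gaps, threshold_min = 40, n_reps = 200,
                                 seed = 1) {
  stopifnot(inherits(gaps, "interarrival_set"))
  if (threshold_min <= gaps$dt_min) {
    stop("threshold_min must exceed the frame interval (no shorter gap ",
         "is observable)")
  }
  closed <- gaps$gaps$gap_min[!gaps$gaps$censored]
  if (length(closed) == 0L) stop("no closed gaps")
  null <- null_prediction_mc(gaps$rate_per_min,
                             rep(as.integer(gaps$n_frames_total),
                                 gaps$n_lineages),
                             gaps$dt_min, n_reps = n_reps, seed = seed)
  k_thr <- ceiling(threshold_min / gaps$dt_min) - 1  # gaps strictly below
  p_null <- predict_gap_cdf(null, k_thr)
  n_short <- sum(closed < threshold_min)
  p_null <- min(max(p_null, 1e-12), 1 - 1e-12)
  bt <- binom.test(n_short, length(closed), p = p_null)
  list(
    excess_ratio = (n_short / length(closed)) / p_null,
    p_value = bt$p.value,
    observed_fraction = n_short / length(closed),
    null_fraction = p_null,
    n_short = n_short,
    n_gaps = length(closed),
    threshold_min = threshold_min
  )
}

# count pairs of onsets in *different* lineages within w minutes of each
# other
cross_lineage_pairs <- function(t_min, lineage, w) {
  n <- length(t_min)
  if (n < 2L) return(0L)
  dt_ok <- abs(outer(t_min, t_min, "-")) <= w
  diff_lin <- outer(lineage, lineage, "!=")
  (sum(dt_ok & diff_lin)) / 2
}

#' Per-lineage burst report for long-lived foci
#'
#' Flags lineages in which two or more long-lived focus onsets fall within a
#' short window (default two generations) — the signature of a transient
#' impaired-repair state — and tests whether onsets coincide in time
#' *across* lineages more than chance allows (which would indicate a shared
#' external cause rather than lineage-autonomous states) by a permutation
#' test that circularly shifts each lineage's onset times.
#'
#' @param foci Classified focus records with `lineage_id`, `onset_frame`,
#'   `frame_interval_s`, `class`.
#' @param doubling_min Doubling time in minutes. Default 26.6.
#' @param burst_window_gen Window (generations) within which >= 2 long-lived
#'   onsets flag a burst. Default 2.
#' @param coincidence_window_min Window for the cross-lineage coincidence
#'   statistic, minutes. Default one doubling time.
#' @param n_perm Permutations. Default 999.
#' @param seed Integer seed.
#' @param n_frames_total Frames per window; defaults to the attribute set by
#'   [apply_imaging()].
#' @return List with `bursts` (data.frame: `lineage_id`, `n_long`,
#'   `min_gap_min`, `burst`), `n_flagged`, and `coincidence` (list:
#'   `statistic`, `p_value`, `n_perm`).
#' @export
burst_summary <- function(foci, doubling_min = 26.6, burst_window_gen = 2,
                          coincidence_window_min = doubling_min,
                          n_perm = 999, seed = 1, n_frames_total = NULL) {
  stopifnot(is.data.frame(foci), "class" %in% names(foci))
  if (is.null(n_frames_total)) n_frames_total <- attr(foci, "n_frames_total")
  stopifnot(!is.null(n_frames_total))
  long <- foci[foci$class == "long", , drop = FALSE]
  dt_min <- unique(foci$frame_interval_s) / 60
  stopifnot(length(dt_min) <= 1L)
  window_min <- n_frames_total * dt_min
  t_min <- long$onset_frame * dt_min
  ids <- unique(long$lineage_id)
  burst_w <- burst_window_gen * doubling_min
  bursts <- do.call(rbind, lapply(ids, function(id) {
    tt <- sort(t_min[long$lineage_id == id])
    mg <- if (length(tt) >= 2L) min(diff(tt)) else NA_real_
    data.frame(lineage_id = id, n_long = length(tt), min_gap_min = mg,
               burst = !is.na(mg) && mg <= burst_w)
  }))
  if (is.null(bursts)) {
    bursts <- data.frame(lineage_id = integer(0), n_long = integer(0),
                         min_gap_min = numeric(0), burst = logical(0))
  }
  stat_obs <- cross_lineage_pairs(t_min, long$lineage_id,
                                  coincidence_window_min)
  perm_stats <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shifts <- runif(length(ids), 0, window_min)
      names(shifts) <- as.character(ids)
      t_perm <- (t_min + shifts[as.character(long$lineage_id)]) %% window_min
      cross_lineage_pairs(t_perm, long$lineage_id, coincidence_window_min)
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= stat_obs)) / (n_perm + 1)
  list(
    bursts = bursts,
    n_flagged = sum(bursts$burst),
    coincidence = list(statistic = stat_obs, p_value = p, n_perm = n_perm)
  )
}
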