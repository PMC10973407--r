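#' @importFrom stats rpois runif rexp rnorm rgeom
NULL

# Evaluate code under a temporary RNG state so simulation substreams do not
# disturb the caller's RNG.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Sample the telegraph (two-state) repair-capacity process on [0, window] and
# return the state (0 baseline / 1 impaired) at each query time.
telegraph_state_at <- function(times, window_min, rate_on, rate_off) {
  p_on <- rate_on / (rate_on + rate_off)
  state <- as.integer(runif(1) < p_on)
  switch_times <- numeric(0)
  t <- 0
  s <- state
  repeat {
    rate <- if (s == 1L) rate_off else rate_on
    t <- t + rexp(1, rate)
    if (t >= window_min) break
    switch_times <- c(switch_times, t)
    s <- 1L - s
  }
  if (length(times) == 0L) return(integer(0))
  n_before <- findInterval(times, switch_times)
  as.integer((state + n_before) %% 2L)
}

#' Simulate one mother-cell lineage
#'
#' Generates the ground truth for a single mother cell observed in a
#' mother-machine microchannel: replication-error onsets as a homogeneous
#' Poisson process, an independent Bernoulli repair outcome per error (with
#' the failure probability optionally modulated by a hidden two-state
#' telegraph process), an exponential lifetime for repaired (short-lived)
#' foci, and a lifetime of about one doubling time for unrepaired
#' (long-lived) foci. Divisions are deterministic at the doubling time.
#'
#' @param params A [sim_params()] object.
#' @param lineage_index 1-based lineage index; determines the RNG substream
#'   so that lineage `i` is reproducible regardless of how many lineages are
#'   simulated.
#'
#' @return An object of class `lineage_trace`: a list with `lineage_id`,
#'   `window_min`, `division_times_min`, and `events`, a data.frame with
#'   columns `onset_min`, `outcome` (`"repaired"`/`"unrepaired"`),
#'   `lifetime_min` and `q_state` (0 baseline, 1 impaired).
#' @examples
#' tr <- simulate_lineage(sim_params(window_generations = 20, seed = 7), 1)
#' nrow(tr$events)
#' @export
simulate_lineage <- function(params, lineage_index) {
  stopifnot(inherits(params, "sim_params"),
            is.numeric(lineage_index), lineage_index >= 1)
  window_min <- params$window_generations * params$doubling_time_min
  tau_min <- params$tau_short_s / 60
  with_local_seed(substream_seed(params$seed, lineage_index), {
    n_events <- rpois(1, params$error_rate_per_min * window_min)
    onset <- sort(runif(n_events, 0, window_min))
    if (!is.null(params$burst_params)) {
      bp <- params$burst_params
      q_state <- telegraph_state_at(onset, window_min, bp$rate_on, bp$rate_off)
      q_eff <- ifelse(q_state == 1L, bp$q_high, params$failure_prob)
    } else {
      q_state <- integer(n_events)
      q_eff <- rep(params$failure_prob, n_events)
    }
    unrepaired <- runif(n_events) < q_eff
    lifetime <- numeric(n_events)
    n_short <- sum(!unrepaired)
    lifetime[!unrepaired] <- rexp(n_short, rate = 1 / tau_min)
    n_long <- sum(unrepaired)
    if (n_long > 0) {
      eps <- rnorm(n_long, 0, params$long_lifetime_cv)
      # resample the rare draws that would give a nonpositive lifetime
      while (any(bad <- (1 + eps) <= 0)) {
        eps[bad] <- rnorm(sum(bad), 0, params$long_lifetime_cv)
      }
      lifetime[unrepaired] <- params$doubling_time_min * (1 + eps)
    }
    structure(
      list(
        lineage_id = as.integer(lineage_index),
        window_min = window_min,
        doubling_time_min = params$doubling_time_min,
        division_times_min = seq(params$doubling_time_min, window_min,
                                 by = params$doubling_time_min),
        events = data.frame(
          onset_min = onset,
          outcome = ifelse(unrepaired, "unrepaired", "repaired"),
          lifetime_min = lifetime,
          q_state = q_state
        )
      ),
      class = "lineage_trace"
    )
  })
}

#' Simulate a batch of independent lineages
#'
#' @param params A [sim_params()] object; `params$n_lineages` lineages are
#'   generated on independent RNG substreams.
#' @return An object of class `lineage_set`: a list of [simulate_lineage()]
#'   traces with the parameters attached as attribute `params`.
#' @examples
#' traces <- simulate_lineages(sim_params(n_lineages = 3,
#'                                        window_generations = 10, seed = 2))
#' length(traces)
#' @export
simulate_lineages <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  traces <- lapply(seq_len(params$n_lineages),
                   function(i) simulate_lineage(params, i))
  structure(traces, class = "lineage_set", params = params)
}

#' @export
print.lineage_trace <- function(x, ...) {
  cat(sprintf("Lineage %d: window %.4g min, %d error events (%d unrepaired)\n",
              x$lineage_id, x$window_min, nrow(x$events),
              sum(x$events$outcome == "unrepaired")))
  invisible(x)
}

#' Observe a lineage trace through discrete time-lapse imaging
#'
#' Projects the continuous-time ground truth onto the frame grid: a focus
#' alive during `[onset, onset + lifetime)` is detected iff at least one
#' frame time falls in that interval (and it has not photobleached). The
#' observed span is the number of consecutive frames on which the focus is
#' visible, and the observed lifetime is `span * frame interval` — a focus
#' seen on a single frame has observed lifetime equal to the frame interval.
#'
#' @param trace A [simulate_lineage()] trace, or a [simulate_lineages()] set.
#' @param imaging An [imaging_config()]; if its `window_min` is `NULL` the
#'   trace's own window is used. The bleaching model is permanent
#'   per-exposure extinction with probability `bleach_per_exposure`.
#' @param seed Optional integer seed for the bleaching draws (ignored when
#'   `bleach_per_exposure` is 0).
#'
#' @return A data.frame of observed focus records with columns `lineage_id`,
#'   `onset_frame` (0-based), `n_frames` (>= 1), `frame_interval_s`, and the
#'   ground-truth columns `true_onset_min`, `true_lifetime_min`, `outcome`,
#'   `q_state`. The attribute `n_frames_total` gives the number of frames in
#'   the imaged window; `window_min` the window length.
#' @examples
#' tr <- simulate_lineage(sim_params(window_generations = 20, seed = 7), 1)
#' foci <- apply_imaging(tr, imaging_config(frame_interval_s = 120))
#' head(foci)
#' @export
apply_imaging <- function(trace, imaging, seed = NULL) {
  stopifnot(inherits(imaging, "imaging_config"))
  if (inherits(trace, "lineage_set")) {
    params <- attr(trace, "params")
    out <- lapply(seq_along(trace), function(i) {
      apply_imaging(trace[[i]], imaging,
                    seed = if (is.null(seed)) NULL
                           else substream_seed(seed, i))
    })
    res <- do.call(rbind, out)
    if (is.null(res)) res <- empty_foci_frame(imaging$frame_interval_s)
    attr(res, "n_frames_total") <- attr(out[[1]], "n_frames_total")
    attr(res, "window_min") <- attr(out[[1]], "window_min")
    attr(res, "frame_interval_s") <- imaging$frame_interval_s
    rownames(res) <- NULL
    return(res)
  }
  stopifnot(inherits(trace, "lineage_trace"))
  dt_min <- imaging$frame_interval_s / 60
  phase_min <- imaging$phase_offset_s / 60
  window_min <- min(trace$window_min,
                    if (is.null(imaging$window_min)) Inf else
                      imaging$window_min)
  j_max <- floor((window_min - phase_min) / dt_min + 1e-9)
  ev <- trace$events
  if (nrow(ev) == 0L) {
    res <- empty_foci_frame(imaging$frame_interval_s)
  } else {
    o <- ev$onset_min
    L <- ev$lifetime_min
    # first frame index with frame time >= onset; last with frame time
    # strictly before onset + L (half-open lifetime interval)
    j0 <- pmax(0L, as.integer(ceiling((o - phase_min) / dt_min - 1e-9)))
    jl <- pmin(j_max, as.integer(ceiling((o + L - phase_min) / dt_min - 1e-9)) - 1L)
    span <- jl - j0 + 1L
    keep <- span >= 1L & (phase_min + j0 * dt_min) >= o
    if (imaging$bleach_per_exposure > 0) {
      draw <- function() {
        n <- sum(keep)
        surv <- rgeom(n, imaging$bleach_per_exposure) + 1L
        pmin(span[keep], surv)
      }
      span_obs <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
    } else {
      span_obs <- span[keep]
    }
    res <- if (!any(keep)) empty_foci_frame(imaging$frame_interval_s) else
      data.frame(
      lineage_id = rep(trace$lineage_id, sum(keep)),
      onset_frame = j0[keep],
      n_frames = as.integer(span_obs),
      frame_interval_s = imaging$frame_interval_s,
      true_onset_min = o[keep],
      true_lifetime_min = L[keep],
      outcome = ev$outcome[keep],
      q_state = ev$q_state[keep]
    )
  }
  attr(res, "n_frames_total") <- j_max + 1L
  attr(res, "window_min") <- window_min
  attr(res, "frame_interval_s") <- imaging$frame_interval_s
  res
}

empty_foci_frame <- function(frame_interval_s) {
  data.frame(
    lineage_id = integer(0), onset_frame = integer(0),
    n_frames = integer(0), frame_interval_s = numeric(0),
    true_onset_min = numeric(0), true_lifetime_min = numeric(0),
    outcome = character(0), q_state = integer(0)
  )
}

#' Lineage metadata table for a simulated batch
#'
#' @param traces A [simulate_lineages()] set.
#' @param experiment_id Experiment label for the table.
#' @return data.frame with columns `experiment_id`, `lineage_id`,
#'   `n_generations`, `window_min`, `doubling_time_min`.
#' @export
lineage_table <- function(traces, experiment_id = "sim") {
  stopifnot(inherits(traces, "lineage_set"))
  params <- attr(traces, "params")
  data.frame(
    experiment_id = experiment_id,
    lineage_id = vapply(traces, function(t) t$lineage_id, integer(1)),
    n_generations = params$window_generations,
    window_min = vapply(traces, function(t) t$window_min, numeric(1)),
    doubling_time_min = params$doubling_time_min
  )
}
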