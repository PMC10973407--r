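#' Simulation parameters for mother-machine lineage simulation
#'
#' Bundles the ground-truth parameters of the generative model: replication
#' errors arise along each mother-cell lineage as a homogeneous Poisson
#' process, each error independently fails repair with a (possibly
#' state-modulated) Bernoulli probability, repaired errors give short-lived
#' foci with exponential lifetimes, and unrepaired errors give long-lived
#' foci persisting about one doubling time.
#'
#' @param error_rate_per_min Poisson rate of replication errors per lineage,
#'   in events per minute. Default 0.14/26.6 (about 0.14 errors per
#'   generation at a 26.6-min doubling time).
#' @param failure_prob Probability that repair of a detected error fails
#'   (the error becomes a nascent mutation). Default 0.01.
#' @param tau_short_s Mean lifetime, in seconds, of the exponential lifetime
#'   of short-lived (successfully repaired) foci. Default 40.
#' @param doubling_time_min Cell doubling time in minutes; also the mean
#'   lifetime of long-lived (unrepaired) foci. Default 26.6.
#' @param long_lifetime_cv Coefficient of variation of the long-lived focus
#'   lifetime about the doubling time. Default 0.2.
#' @param burst_params Optional list with elements `q_high` (failure
#'   probability in the impaired-repair state), `rate_on` and `rate_off`
#'   (per-minute telegraph switching rates into and out of that state).
#'   `NULL` (default) disables the hidden state, giving a time-homogeneous
#'   Bernoulli failure.
#' @param n_lineages Number of independent mother-cell lineages.
#' @param window_generations Observation window per lineage, in generations
#'   (window length in minutes is `window_generations * doubling_time_min`).
#' @param seed Integer base seed; lineage `i` uses an independent substream
#'   derived from `(seed, i)` so its trace does not depend on `n_lineages`.
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(n_lineages = 5, window_generations = 10, seed = 1)
#' @export
sim_params <- function(error_rate_per_min = 0.14 / 26.6,
                       failure_prob = 0.01,
                       tau_short_s = 40,
                       doubling_time_min = 26.6,
                       long_lifetime_cv = 0.2,
                       burst_params = NULL,
                       n_lineages = 100L,
                       window_generations = 100,
                       seed = 1L) {
  stopifnot(
    is.numeric(error_rate_per_min), length(error_rate_per_min) == 1L,
    is.finite(error_rate_per_min), error_rate_per_min > 0,
    is.numeric(failure_prob), length(failure_prob) == 1L,
    is.finite(failure_prob), failure_prob >= 0, failure_prob <= 1,
    is.numeric(tau_short_s), is.finite(tau_short_s), tau_short_s > 0,
    is.numeric(doubling_time_min), is.finite(doubling_time_min),
    doubling_time_min > 0,
    is.numeric(long_lifetime_cv), is.finite(long_lifetime_cv),
    long_lifetime_cv >= 0,
    is.numeric(n_lineages), n_lineages >= 1,
    is.numeric(window_generations), window_generations > 0,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  if (!is.null(burst_params)) {
    req <- c("q_high", "rate_on", "rate_off")
    if (!all(req %in% names(burst_params))) {
      stop("burst_params must contain q_high, rate_on and rate_off")
    }
    stopifnot(
      burst_params$q_high >= failure_prob, burst_params$q_high <= 1,
      burst_params$rate_on > 0, burst_params$rate_off > 0
    )
  }
  structure(
    list(
      error_rate_per_min = error_rate_per_min,
      failure_prob = failure_prob,
      tau_short_s = tau_short_s,
      doubling_time_min = doubling_time_min,
      long_lifetime_cv = long_lifetime_cv,
      burst_params = burst_params,
      n_lineages = as.integer(n_lineages),
      window_generations = window_generations,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Imaging configuration for discrete time-lapse observation
#'
#' Describes how a continuous-time lineage trace is observed: frames are
#' acquired every `frame_interval_s` seconds, starting `phase_offset_s`
#' seconds after time zero, for `window_min` minutes. A focus is visible on
#' a frame if the frame time falls within its lifetime interval; optionally
#' each exposure photobleaches a visible focus permanently with probability
#' `bleach_per_exposure`.
#'
#' @param frame_interval_s Frame interval in seconds (e.g. 7.5, 15, 30, 120).
#' @param window_min Duration of the imaged window in minutes; `NULL` means
#'   "use the full simulated window" when applied to a trace.
#' @param phase_offset_s Offset of the frame grid relative to time zero, in
#'   seconds, in `[0, frame_interval_s)`. Default 0.
#' @param bleach_per_exposure Probability that a visible focus permanently
#'   drops below detection at each exposure; 0 disables bleaching.
#'
#' @return An object of class `imaging_config`.
#' @examples
#' imaging_config(frame_interval_s = 120)
#' @export
imaging_config <- function(frame_interval_s,
                           window_min = NULL,
                           phase_offset_s = 0,
                           bleach_per_exposure = 0) {
  stopifnot(
    is.numeric(frame_interval_s), length(frame_interval_s) == 1L,
    is.finite(frame_interval_s), frame_interval_s > 0,
    is.numeric(phase_offset_s), phase_offset_s >= 0,
    phase_offset_s < frame_interval_s,
    is.numeric(bleach_per_exposure), bleach_per_exposure >= 0,
    bleach_per_exposure < 1
  )
  if (!is.null(window_min)) {
    stopifnot(is.numeric(window_min), is.finite(window_min), window_min > 0)
  }
  structure(
    list(
      frame_interval_s = frame_interval_s,
      window_min = window_min,
      phase_offset_s = phase_offset_s,
      bleach_per_exposure = bleach_per_exposure
    ),
    class = "imaging_config"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Lineage simulation parameters\n")
  cat(sprintf("  error rate      : %.5g /min (%.3g /generation)\n",
              x$error_rate_per_min,
              x$error_rate_per_min * x$doubling_time_min))
  cat(sprintf("  failure prob    : %.4g\n", x$failure_prob))
  cat(sprintf("  tau (short)     : %.3g s\n", x$tau_short_s))
  cat(sprintf("  doubling time   : %.3g min\n", x$doubling_time_min))
  cat(sprintf("  lineages/window : %d x %.4g generations\n",
              x$n_lineages, x$window_generations))
  if (!is.null(x$burst_params)) {
    cat(sprintf("  telegraph state : q_high=%.3g, on=%.3g/min, off=%.3g/min\n",
                x$burst_params$q_high, x$burst_params$rate_on,
                x$burst_params$rate_off))
  }
  invisible(x)
}

#' @export
print.imaging_config <- function(x, ...) {
  cat(sprintf(
    "Imaging: dt = %.4g s, phase = %.4g s, bleach/exposure = %.3g%s\n",
    x$frame_interval_s, x$phase_offset_s, x$bleach_per_exposure,
    if (is.null(x$window_min)) "" else sprintf(", window = %.4g min",
                                               x$window_min)
  ))
  invisible(x)
}

# Deterministic 32-bit substream seed for lineage i, independent of the
# number of lineages simulated.
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483647)
}
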