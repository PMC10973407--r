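#' @importFrom utils read.csv write.csv packageVersion
NULL

foci_required_cols <- c("experiment_id", "lineage_id", "onset_frame",
                        "n_frames", "frame_interval_s")
lineage_required_cols <- c("experiment_id", "lineage_id", "n_generations",
                           "window_min", "doubling_time_min")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Read a foci table
#'
#' Reads and validates a CSV of observed focus records. Required columns:
#' `experiment_id`, `lineage_id`, `onset_frame` (0-based integer),
#' `n_frames` (integer >= 1), `frame_interval_s`. Ground-truth columns from
#' the simulator (`true_onset_min`, `true_lifetime_min`, `outcome`,
#' `q_state`) are carried through when present. Malformed rows are reported
#' with their line numbers.
#'
#' @param path CSV path.
#' @return Validated data.frame of focus records.
#' @export
read_foci_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, foci_required_cols, path)
  bad <- which(!is.finite(df$n_frames) | df$n_frames < 1 |
                 df$n_frames != round(df$n_frames))
  if (length(bad)) {
    stop("invalid n_frames (must be integer >= 1) at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bad <- which(!is.finite(df$onset_frame) | df$onset_frame < 0 |
                 df$onset_frame != round(df$onset_frame))
  if (length(bad)) {
    stop("invalid onset_frame (must be integer >= 0) at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bad <- which(!is.finite(df$frame_interval_s) | df$frame_interval_s <= 0)
  if (length(bad)) {
    stop("invalid frame_interval_s at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  df$onset_frame <- as.integer(df$onset_frame)
  df$n_frames <- as.integer(df$n_frames)
  df
}

#' Read a lineage metadata table
#'
#' Required columns: `experiment_id`, `lineage_id`, `n_generations`,
#' `window_min`, `doubling_time_min`.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_lineage_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, lineage_required_cols, path)
  bad <- which(!is.finite(df$window_min) | df$window_min <= 0 |
                 !is.finite(df$doubling_time_min) | df$doubling_time_min <= 0)
  if (length(bad)) {
    stop("invalid window_min/doubling_time_min at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  df
}

#' Write a foci table
#'
#' @param foci Focus records; an `experiment_id` column is added when absent.
#' @param path Output CSV path.
#' @param experiment_id Label used when the column is absent.
#' @return `path`, invisibly.
#' @export
write_foci_table <- function(foci, path, experiment_id = "sim") {
  stopifnot(is.data.frame(foci))
  if (!"experiment_id" %in% names(foci)) {
    foci <- cbind(experiment_id = rep(experiment_id, nrow(foci)), foci)
  }
  front <- intersect(foci_required_cols, names(foci))
  foci <- foci[, c(front, setdiff(names(foci), front)), drop = FALSE]
  write.csv(foci, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a lineage metadata table
#'
#' @param lineages Lineage table ([lineage_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(lineages, path) {
  stopifnot(is.data.frame(lineages),
            all(lineage_required_cols %in% names(lineages)))
  write.csv(lineages, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulated observations and lineage metadata as CSV tables
#'
#' @param records Focus records from [apply_imaging()].
#' @param traces The [simulate_lineages()] set the records came from.
#' @param dir Output directory (created if needed).
#' @param experiment_id Experiment label.
#' @return Named character vector with paths `foci` and `lineages`.
#' @export
emit_tables <- function(records, traces, dir, experiment_id = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  foci_path <- file.path(dir, "foci.csv")
  lin_path <- file.path(dir, "lineages.csv")
  write_foci_table(records, foci_path, experiment_id)
  write_lineage_table(lineage_table(traces, experiment_id), lin_path)
  c(foci = foci_path, lineages = lin_path)
}

# tiny FNV-1a string hash, used to stamp reports with a config fingerprint
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Defaults mirror the canonical long-term imaging analysis: 2-min frames,
#' 14-min short/long cutoff, 40-s mean short-focus lifetime for the
#' detection correction, and a 26.6-min doubling time.
#'
#' @param sim [sim_params()] for the simulated input.
#' @param frame_interval_s Frame interval, seconds. Default 120.
#' @param cutoff_min Classification cutoff, minutes; used as fallback when
#'   the data-driven cutoff fails. Default 14.
#' @param tau_s Mean short-focus lifetime for detection correction,
#'   seconds. Default 40.
#' @param gap_threshold_min Short-gap enrichment threshold. Default 40.
#' @param n_boot Bootstrap replicates for the dynamics test. Default 1999.
#' @param mc_reps Monte-Carlo replicates for null gap CDFs. Default 200.
#' @param seed Integer seed controlling every stochastic stage.
#' @param out_dir Output directory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_params(seed = seed),
                            frame_interval_s = 120,
                            cutoff_min = 14,
                            tau_s = 40,
                            gap_threshold_min = 40,
                            n_boot = 1999,
                            mc_reps = 200,
                            seed = 1L,
                            out_dir = tempfile("mutlfoci_run_")) {
  stopifnot(inherits(sim, "sim_params"), cutoff_min > 0, tau_s > 0,
            n_boot >= 1, mc_reps >= 1)
  structure(
    list(sim = sim, frame_interval_s = frame_interval_s,
         cutoff_min = cutoff_min, tau_s = tau_s,
         gap_threshold_min = gap_threshold_min, n_boot = n_boot,
         mc_reps = mc_reps, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full simulate-analyse pipeline
#'
#' Chains the stages end to end: simulate lineages, observe them through
#' discrete imaging, write and re-read the CSV tables, build the lifetime
#' distribution, determine (or fall back to) the short/long cutoff, classify
#' foci, estimate detection-corrected rates and the mutation rate, and test
#' the onset dynamics of all and of long-lived foci. All randomness derives
#' from `config$seed`, so reruns with an equal config reproduce every
#' numeric output.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results (`tables`, `dist`,
#'   `cutoff`, `foci`, `rates`, `dynamics`, `manifest_path`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  pipeline_log("simulate", "%d lineages x %.4g generations",
               config$sim$n_lineages, config$sim$window_generations)
  traces <- simulate_lineages(config$sim)
  imaging <- imaging_config(config$frame_interval_s)
  foci_raw <- apply_imaging(traces, imaging,
                            seed = substream_seed(config$seed, 999983))
  n_frames_total <- attr(foci_raw, "n_frames_total")
  paths <- emit_tables(foci_raw, traces, config$out_dir)
  tick("simulate")

  foci <- read_foci_table(paths[["foci"]])
  lineages <- read_lineage_table(paths[["lineages"]])
  tick("io")

  dist <- lifetime_distribution(foci)
  cutoff <- tryCatch(determine_cutoff(dist), error = function(e) NULL)
  cutoff_min <- if (!is.null(cutoff) && isTRUE(cutoff$success)) {
    cutoff$cutoff_min
  } else {
    pipeline_log("lifetimes", "no data-driven cutoff; using %.4g min",
                 config$cutoff_min)
    config$cutoff_min
  }
  foci <- classify_foci(foci, cutoff_min = cutoff_min)
  attr(foci, "n_frames_total") <- n_frames_total
  write.csv(as.data.frame(dist),
            file.path(config$out_dir, "lifetime_distribution.csv"),
            row.names = FALSE)
  write_foci_table(foci, file.path(config$out_dir, "foci_classified.csv"))
  pipeline_log("lifetimes", "%d foci, cutoff %.4g min", nrow(foci),
               cutoff_min)
  tick("lifetimes")

  interior <- drop_edge_foci(foci, n_frames_total)
  n_short <- sum(interior$class == "short")
  n_long <- sum(interior$class == "long")
  exposure_min <- sum(lineages$window_min)
  doubling_min <- lineages$doubling_time_min[1]
  p_short <- detection_probability(config$tau_s, config$frame_interval_s)
  total_rate <- span_weighted_total_rate(dist, exposure_min,
                                         tau_s = config$tau_s,
                                         doubling_min = doubling_min)
  mut_rate <- mutation_rate_from_long_foci(n_long,
                                           exposure_min / doubling_min)
  failure <- repair_failure_fraction(
    n_long, total_rate$corrected_rate_min * exposure_min)
  age <- tryCatch(
    age_binned_analysis(interior, doubling_min = doubling_min),
    error = function(e) NULL)
  rates_report <- data.frame(
    condition = "sim",
    n_short = n_short, n_long = n_long,
    exposure_min = exposure_min,
    exposure_generations = exposure_min / doubling_min,
    p_detect = p_short,
    raw_rate_min = total_rate$raw_rate_min,
    corrected_rate_min = total_rate$corrected_rate_min,
    corrected_rate_gen = total_rate$corrected_rate_gen,
    corrected_rate_gen_lo = total_rate$ci_rate_gen[1],
    corrected_rate_gen_hi = total_rate$ci_rate_gen[2],
    mutation_rate_gen = mut_rate$corrected_rate_gen,
    mutation_rate_gen_lo = mut_rate$ci_rate_gen[1],
    mutation_rate_gen_hi = mut_rate$ci_rate_gen[2],
    failure_fraction = failure$fraction
  )
  write.csv(rates_report, file.path(config$out_dir, "rates_report.csv"),
            row.names = FALSE)
  pipeline_log("rates", "corrected %.4g /gen, mutation %.4g /gen",
               total_rate$corrected_rate_gen, mut_rate$corrected_rate_gen)
  tick("rates")

  n_lineages <- nrow(lineages)
  gaps_all <- interarrival_times(foci, "all", n_frames_total, n_lineages)
  gaps_long <- interarrival_times(foci, "long", n_frames_total, n_lineages)
  gaps_out <- gaps_long$gaps
  gaps_out$censored <- as.integer(gaps_out$censored)
  write.csv(gaps_out[c("lineage_id", "gap_min", "censored")],
            file.path(config$out_dir, "gaps_long.csv"), row.names = FALSE)
  gof <- function(g, tag) {
    tryCatch(
      gof_poisson(g, n_boot = config$n_boot,
                  seed = substream_seed(config$seed, 424243)),
      error = function(e) {
        pipeline_log("dynamics", "%s GOF skipped: %s", tag,
                     conditionMessage(e))
        NULL
      })
  }
  gof_all <- gof(gaps_all, "all-foci")
  gof_long <- gof(gaps_long, "long-foci")
  enrich <- tryCatch(
    short_gap_enrichment(gaps_long,
                         threshold_min = config$gap_threshold_min,
                         n_reps = config$mc_reps,
                         seed = substream_seed(config$seed, 555557)),
    error = function(e) NULL)
  bursts <- burst_summary(foci, doubling_min = doubling_min,
                          n_perm = 499,
                          seed = substream_seed(config$seed, 777773),
                          n_frames_total = n_frames_total)
  dyn_report <- list(
    all = if (!is.null(gof_all)) gof_all[c("statistic", "p_value",
                                           "n_gaps", "rate_per_min")],
    long = if (!is.null(gof_long)) gof_long[c("statistic", "p_value",
                                              "n_gaps", "rate_per_min")],
    short_gap_enrichment = enrich,
    n_burst_lineages = bursts$n_flagged,
    coincidence_p = bursts$coincidence$p_value
  )
  tick("dynamics")

  manifest <- list(
    package = "mutlfoci",
    version = as.character(packageVersion("mutlfoci")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = fnv1a(paste(
      utils::capture.output(utils::str(
        config[setdiff(names(config), "out_dir")])), collapse = "\n")),
    dynamics = dyn_report,
    timings_s = timings
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  pipeline_log("done", "reports in %s", config$out_dir)

  invisible(list(
    tables = paths, dist = dist, cutoff = cutoff, cutoff_min = cutoff_min,
    foci = foci, lineages = lineages,
    rates = list(total = total_rate, mutation = mut_rate,
                 failure = failure, age = age, report = rates_report),
    dynamics = list(gaps_all = gaps_all, gaps_long = gaps_long,
                    gof_all = gof_all, gof_long = gof_long,
                    enrichment = enrich, bursts = bursts),
    manifest_path = manifest_path
  ))
}
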