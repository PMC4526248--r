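#' Normalize and validate a run configuration
#'
#' Fills defaults for every protocol, simulator and detector setting and
#' rejects inconsistent values with one aggregated error. A configuration
#' is a plain named list (e.g. read from YAML or JSON with
#' [read_run_config()]); cohort parameters live under `$cohort` and are
#' passed to [cohort_config()].
#'
#' @param config Named list of overrides (default empty: all defaults).
#' @return A normalized list of class `run_config`.
#' @export
#' @examples
#' cfg <- validate_config(list(seed = 42))
#' cfg$ramp_s
validate_config <- function(config = list()) {
  defaults <- list(
    shifts = tempo_shifts(),
    laps_per_sequence = 4,
    lap_distance_m = 200,
    n_sequences = 12,
    ramp_s = 5,
    reference_window_s = 20,
    discard_head_s = 5,
    discard_tail_s = 20,
    sample_rate_hz = 100,
    accel_noise_sd = 0.5,
    steps_from = "detected",
    cohort = list(),
    seed = 1L
  )
  unknown <- setdiff(names(config), names(defaults))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])

  errors <- character(0)
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || cfg$seed < 0) {
    errors <- c(errors, "seed must be a single non-negative integer")
  }
  for (key in c("lap_distance_m", "ramp_s", "reference_window_s",
                "sample_rate_hz", "discard_head_s", "discard_tail_s")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 0) {
      errors <- c(errors, paste0(key, " must be a non-negative number"))
    }
  }
  if (cfg$laps_per_sequence != 4) {
    errors <- c(errors, "the protocol is defined for 4 laps per sequence")
  }
  if (!cfg$steps_from %in% c("true", "detected")) {
    errors <- c(errors, 'steps_from must be "true" or "detected"')
  }
  cohort <- tryCatch(
    do.call(cohort_config, utils::modifyList(cfg$cohort,
                                             list(seed = as.integer(cfg$seed)))),
    error = function(e) {
      errors <<- c(errors, paste0("cohort: ", conditionMessage(e)))
      NULL
    })
  if (length(errors) > 0) {
    abort(paste0("invalid configuration:\n",
                 paste0("- ", errors, collapse = "\n")),
          class = "runsync_config_error")
  }
  if (cfg$ramp_s > cfg$discard_head_s) {
    warn("ramp_s exceeds discard_head_s: the tempo ramp leaks into the analyzed window")
  }
  cfg$cohort <- cohort
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(as.list(raw))
}

#' Run the full statistical battery on a scored cohort
#'
#' Reproduces the analysis plan: normality check of the cadence-adaptation
#' values, repeated-measures ANOVA with linear trend contrast of adaptation
#' over the shift conditions, Friedman test of entrainment over conditions,
#' the entrainment-basin analysis (paired Wilcoxon vs the 0 % control,
#' Bonferroni-corrected), Mann-Whitney comparisons of per-participant mean
#' entrainment by gender and by musical training, and the Spearman
#' correlation between entrainment and perceived exertion.
#'
#' @param metrics Tidy metric table from [score_cohort()].
#' @param profiles Runner profile tibble (for gender / training grouping);
#'   optional, group tests are skipped when absent.
#' @return A list of class `entrainment_report`.
#' @export
analyze_cohort <- function(metrics, profiles = NULL) {
  shifts <- sort(unique(metrics$shift_pct))
  pids <- sort(unique(metrics$participant_id))
  to_matrix <- function(colname) {
    wide <- vapply(shifts, function(sh) {
      d <- metrics[metrics$shift_pct == sh, ]
      d[[colname]][match(pids, d$participant_id)]
    }, numeric(length(pids)))
    matrix(wide, nrow = length(pids), ncol = length(shifts),
           dimnames = list(pids, shifts))
  }
  adapt <- to_matrix("adaptation_pct")
  entr <- to_matrix("entrainment_pct")

  # condition-wise tests need >= 2 conditions (and the basin its control);
  # degenerate reductions (tiny runs) simply omit inapplicable tests
  report <- list(ks_adaptation = tryCatch(ks_normality(as.vector(adapt)),
                                          error = function(e) NULL))
  if (length(shifts) >= 2 && length(pids) >= 2) {
    report$anova_adaptation <- rm_anova_linear(adapt, scores = shifts)
    report$friedman_entrainment <- friedman_rank_test(entr)
    if (0 %in% shifts) report$basin <- basin_analysis(metrics)
  }
  report$spearman_rpe <- tryCatch(
    spearman_rho(metrics$entrainment_pct, metrics$rpe),
    error = function(e) NULL)

  if (!is.null(profiles)) {
    per_pid <- metrics |>
      group_by(.data$participant_id) |>
      summarise(mean_entrainment = mean(.data$entrainment_pct),
                mean_adaptation = mean(.data$adaptation_pct),
                .groups = "drop") |>
      left_join(profiles, by = "participant_id")
    grp_test <- function(a, b) {
      if (length(a) == 0 || length(b) == 0) return(NULL)
      mann_whitney_u(a, b)
    }
    report$mann_whitney_gender <- grp_test(
      per_pid$mean_entrainment[per_pid$gender == "female"],
      per_pid$mean_entrainment[per_pid$gender == "male"])
    report$mann_whitney_training <- grp_test(
      per_pid$mean_entrainment[per_pid$musical_training],
      per_pid$mean_entrainment[!per_pid$musical_training])
    report$per_participant <- per_pid
  }
  structure(report, class = "entrainment_report")
}

#' @export
print.entrainment_report <- function(x, ...) {
  cat("== entrainment report ==\n")
  for (nm in setdiff(names(x), "per_participant")) {
    if (!is.null(x[[nm]])) print(x[[nm]])
  }
  invisible(x)
}

# 32-bit FNV-1a over a string, for manifest config hashes
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- (as.double(h) %% 2^32) * 16777619 %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full experiment pipeline
#'
#' simulate -> detect -> score -> analyze, writing all artifacts to a run
#' directory: the per-sequence metric table (`metrics.csv`), per-condition
#' summaries (`condition_summary.csv`), the statistical report
#' (`report.json`), the schedules (`schedules.json`), a manifest with the
#' config hash, and a log with one timing line per stage. Re-running with
#' the same configuration reproduces identical CSV/JSON outputs.
#'
#' @param config A `run_config` (or a list, validated on entry).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `run_dir`, `sim`, `metrics`, `report`.
#' @export
run_experiment <- function(config = list(), out_dir = tempfile("runsync-"),
                           quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      line <- sprintf("stage %s: FAILED (%s)", name, conditionMessage(e))
      writeLines(c(log_lines, line), log_path)
      abort(line, class = "runsync_pipeline_error", parent = e)
    })
    n_rec <- if (is.data.frame(res)) nrow(res) else
      if (is.list(res) && !is.null(res$sessions)) nrow(res$sessions) else
      length(res)
    line <- sprintf("stage %-9s %5d records  %7.2f s", name, n_rec,
                    proc.time()[["elapsed"]] - t0)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
    res
  }

  sim <- stage("simulate", simulate_cohort(
    config$cohort, traces = config$steps_from == "detected",
    lap_distance_m = config$lap_distance_m, ramp_s = config$ramp_s,
    reference_window_s = config$reference_window_s,
    accel_noise_sd = config$accel_noise_sd, shifts = config$shifts))
  metrics <- stage("score", score_cohort(sim, steps_from = config$steps_from))
  report <- stage("analyze", analyze_cohort(metrics, sim$profiles))

  stage("export", {
    write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"))
    if (!is.null(report$basin)) {
      readr::write_csv(tidy(report$basin),
                       file.path(out_dir, "condition_summary.csv"))
    }
    write_schedules_json(sim$schedules, file.path(out_dir, "schedules.json"))
    write_report_json(report, file.path(out_dir, "report.json"))
    manifest <- list(
      package = "runsync",
      version = as.character(utils::packageVersion("runsync")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config_hash = fnv1a_hash({
        plain <- unclass(config)
        plain$cohort <- unclass(plain$cohort)
        jsonlite::toJSON(plain[order(names(plain))], auto_unbox = TRUE,
                         digits = NA)
      }),
      files = c("metrics.csv", "condition_summary.csv", "schedules.json",
                "report.json", "log.txt")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest$files
  })
  writeLines(log_lines, log_path)
  invisible(list(run_dir = out_dir, sim = sim, metrics = metrics,
                 report = report))
}

#' Serialize an entrainment report to JSON
#'
#' @param report An `entrainment_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  to_list <- function(x) {
    if (inherits(x, "sync_test")) as.list(tidy(x))
    else if (inherits(x, "rm_anova")) list(omnibus = as.list(tidy(x$omnibus)),
                                           contrast = as.list(tidy(x$contrast)))
    else if (inherits(x, "basin_result")) {
      list(summary = x$summary, comparisons = x$comparisons,
           bonferroni_alpha = x$bonferroni_alpha)
    } else x
  }
  out <- purrr::map(report[setdiff(names(report), "per_participant")], to_list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
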