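# End-to-end orchestration: simulate -> extract -> compare -> report, with a
# small command-line front end. All run artifacts are plain files in one
# output directory; every seed and setting is recorded so any number in the
# report can be reproduced.

DEFAULT_ANALYSES <- data.frame(
  component  = c("a", "a", "a_fixed", "b", "b", "mop", "op", "phnr", "phnr"),
  measure    = c("amplitude", "it", "amplitude", "amplitude", "it",
                 "amplitude", "it", "amplitude", "it"),
  stringsAsFactors = FALSE)

#' Run configuration for an end-to-end analysis
#'
#' @param out_dir Output directory (created if missing).
#' @param sim A [sim_config()] to simulate recordings, or `NULL` to read
#'   them from `recordings_path`.
#' @param recordings_path CSV of recordings (used when `sim` is `NULL`).
#' @param windows A [window_config()].
#' @param analyses data.frame with columns `component`, `measure`; defaults
#'   to the full roster (PhNR analyses run on LA only, others on both
#'   adaptation states present).
#' @param n_boot,alpha,seed Statistical settings (bootstrap resamples,
#'   nominal level, seed).
#' @param per_luminance Whether to run per-luminance follow-up models.
#' @param write_recordings Whether to write simulated recordings to CSV.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, sim = NULL, recordings_path = NULL,
                       windows = window_config(),
                       analyses = DEFAULT_ANALYSES,
                       n_boot = 2000, alpha = 0.05, seed = 1,
                       per_luminance = TRUE, write_recordings = TRUE) {
  if (is.null(sim) && is.null(recordings_path)) {
    abort_invalid("either sim or recordings_path is required")
  }
  structure(list(out_dir = out_dir, sim = sim,
                 recordings_path = recordings_path, windows = windows,
                 analyses = analyses, n_boot = n_boot, alpha = alpha,
                 seed = seed, per_luminance = per_luminance,
                 write_recordings = write_recordings),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulates (or reads) recordings, measures every component, compares the
#' groups component-by-component (overall model plus optional per-luminance
#' follow-ups), and writes the measurement table, per-comparison JSON, a
#' summary CSV and a log capturing versions, seeds and settings into
#' `config$out_dir`. Rerunning with the same configuration reproduces all
#' numeric outputs exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summary` (data.frame), `comparisons`,
#'   `table` and `out_dir`.
#' @export
run_end_to_end <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$sim)) {
    cohort <- synth_cohort(config$sim)
    recordings <- cohort$recordings
    if (isTRUE(config$write_recordings)) {
      write_recording_set(recordings, file.path(config$out_dir,
                                                "recordings.csv"))
      utils::write.csv(cohort$truth,
                       file.path(config$out_dir, "truth.csv"),
                       row.names = FALSE)
    }
  } else {
    recordings <- read_recording_set(config$recordings_path)
  }
  table <- extract_all(recordings, config$windows)
  write_measurement_table(table, file.path(config$out_dir,
                                           "measurements.csv"))
  adaptations <- unique(table$adaptation)
  comparisons <- list()
  summary_rows <- list()
  for (i in seq_len(nrow(config$analyses))) {
    comp <- config$analyses$component[i]
    meas <- config$analyses$measure[i]
    for (adaptation in adaptations) {
      if (comp == "phnr" && adaptation != "LA") next
      cmp <- tryCatch(
        compare_groups_overall(table, comp, adaptation, meas,
                               n_boot = config$n_boot,
                               seed = config$seed + 97L * i),
        error = function(e) e)
      if (inherits(cmp, "error")) next
      per_lum <- NULL
      if (isTRUE(config$per_luminance)) {
        per_lum <- compare_groups_per_luminance(
          table, comp, adaptation, meas, alpha = config$alpha,
          n_boot = max(1000, config$n_boot), seed = config$seed + 997L * i)
      }
      key <- paste(adaptation, comp, meas, sep = "_")
      comparisons[[key]] <- list(overall = cmp, per_luminance = per_lum)
      jsonlite::write_json(
        list(component = comp, adaptation = adaptation, measure = meas,
             estimate = cmp$estimate, ci95 = cmp$ci95,
             p_value = cmp$p_value, n_boot = cmp$n_boot, seed = cmp$seed,
             per_luminance = per_lum),
        file.path(config$out_dir, paste0("comparison_", key, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      summary_rows[[key]] <- data.frame(
        adaptation = adaptation, component = comp, measure = meas,
        estimate = cmp$estimate, ci_lo = cmp$ci95[1], ci_hi = cmp$ci95[2],
        p_value = cmp$p_value,
        significant = cmp$p_value < config$alpha,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  log <- list(
    package = "ergkit",
    package_version = as.character(utils::packageVersion("ergkit")),
    r_version = R.version.string,
    seed = config$seed, n_boot = config$n_boot, alpha = config$alpha,
    simulated = !is.null(config$sim),
    sim_seed = if (!is.null(config$sim)) config$sim$seed else NULL,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary, comparisons = comparisons,
                 table = table, out_dir = config$out_dir))
}

#' Render a per-luminance summary report
#'
#' For each requested component measure, tabulates group medians with
#' bootstrap 95% CIs per flash luminance, and marks per-luminance
#' significance at two tiers (nominal `*`, Bonferroni `+`) when comparison
#' results are supplied. Implicit times flagged unreliable are excluded from
#' the medians; light-adapted implicit times below the reliability luminance
#' are reported as missing.
#'
#' @param table A [measurement_table()].
#' @param comparisons Optional list as produced by [run_end_to_end()]
#'   (elements named `adaptation_component_measure` with a `per_luminance`
#'   data.frame).
#' @param analyses data.frame with columns `component`, `measure`.
#' @param n_boot,seed Bootstrap settings for the median CIs.
#' @param path Optional CSV output path.
#' @return data.frame with one row per
#'   (adaptation, component, measure, luminance, group).
#' @export
render_summary <- function(table, comparisons = NULL,
                           analyses = DEFAULT_ANALYSES,
                           n_boot = 1000, seed = 1, path = NULL) {
  rows <- list()
  for (i in seq_len(nrow(analyses))) {
    comp <- analyses$component[i]
    meas <- analyses$measure[i]
    for (adaptation in unique(table$adaptation)) {
      if (comp == "phnr" && adaptation != "LA") next
      sub <- tryCatch(
        analysis_rows(table, comp, meas, adaptation, luminance_min = if (adaptation == "LA" && meas == "it") NULL else 0),
        error = function(e) NULL)
      if (is.null(sub) || !nrow(sub)) next
      col <- names(sub)[4]
      key <- paste(adaptation, comp, meas, sep = "_")
      per_lum <- if (!is.null(comparisons) && key %in% names(comparisons)) {
        comparisons[[key]]$per_luminance
      } else NULL
      for (lum in sort(unique(sub$luminance))) {
        for (grp in c("WT", "MODEL")) {
          v <- sub[[col]][sub$luminance == lum & sub$group == grp]
          v <- v[!is.na(v)]
          if (length(v) < 2) next
          ci <- bootstrap_median_ci(v, n_boot = max(200, n_boot),
                                    seed = seed + round(1e3 * log10(lum) + i))
          marker <- ""
          if (!is.null(per_lum)) {
            hit <- per_lum[abs(per_lum$luminance - lum) < 1e-9, ]
            if (nrow(hit) == 1 && isTRUE(hit$significant_bonferroni)) {
              marker <- "+"
            } else if (nrow(hit) == 1 && isTRUE(hit$significant_nominal)) {
              marker <- "*"
            }
          }
          rows[[length(rows) + 1L]] <- data.frame(
            adaptation = adaptation, component = comp, measure = meas,
            luminance = lum, group = grp, n = length(v),
            median = stats::median(v), ci_lo = ci[1], ci_hi = ci[2],
            significance = marker, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
  }
  out
}

# ---- command-line front end ------------------------------------------------

parse_cli_args <- function(args) {
  if (!length(args)) return(list(verb = NULL, opts = list()))
  verb <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      abort_invalid(sprintf("unexpected argument: %s", a))
    }
    key <- sub("^--", "", a)
    if (key %in% c("verbose")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      if (i + 1 > length(args)) {
        abort_invalid(sprintf("missing value for --%s", key))
      }
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  list(verb = verb, opts = opts)
}

cli_sim_config <- function(opts) {
  seed <- as.integer(opts$seed %||% 1)
  effects <- if (!is.null(opts$effects)) {
    if (identical(opts$effects, "null")) NULL else paper_effects(opts$effects)
  } else {
    paper_effects()
  }
  sim_config(seed = seed, effects = effects,
             n_wt = as.integer(opts$n_wt %||% 13),
             n_model = as.integer(opts$n_model %||% 22))
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write a synthetic cohort to CSV), `extract` (measure a
#' recordings CSV into a measurement table), `compare` (one overall group
#' comparison from a measurement table), `report` (per-luminance summary
#' CSV) and `run-all` (simulate + extract + compare + report into an output
#' directory). Common options: `--seed`, `--out`; see the README for worked
#' examples. Exit codes: 0 ok, 1 stage error, 2 configuration error.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
ergkit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(parse_cli_args(args), error = function(e) e)
  if (inherits(parsed, "error") || is.null(parsed$verb) ||
      !parsed$verb %in% c("simulate", "extract", "compare", "report",
                          "run-all")) {
    message("usage: ergkit <simulate|extract|compare|report|run-all> [--options]")
    return(invisible(2L))
  }
  opts <- parsed$opts
  status <- tryCatch({
    switch(parsed$verb,
      "simulate" = {
        cfg <- cli_sim_config(opts)
        cohort <- synth_cohort(cfg)
        write_recording_set(cohort$recordings, opts$out %||% "recordings.csv")
        if (!is.null(opts$truth)) {
          utils::write.csv(cohort$truth, opts$truth, row.names = FALSE)
        }
        0L
      },
      "extract" = {
        recs <- read_recording_set(opts[["in"]] %||%
                                     abort_invalid("--in is required"))
        table <- extract_all(recs)
        write_measurement_table(table, opts$out %||% "measurements.csv")
        0L
      },
      "compare" = {
        table <- read_measurement_table(opts[["in"]] %||%
                                          abort_invalid("--in is required"))
        cmp <- compare_groups_overall(
          table,
          component = opts$component %||% "b",
          adaptation = opts$adaptation %||% "DA",
          measure = opts$measure %||% "amplitude",
          n_boot = as.integer(opts$n_boot %||% 2000),
          seed = as.integer(opts$seed %||% 1))
        out <- opts$out %||% "comparison.json"
        jsonlite::write_json(
          list(component = cmp$component, adaptation = cmp$adaptation,
               measure = cmp$measure, estimate = cmp$estimate,
               ci95 = cmp$ci95, p_value = cmp$p_value,
               n_boot = cmp$n_boot, seed = cmp$seed),
          out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        0L
      },
      "report" = {
        table <- read_measurement_table(opts[["in"]] %||%
                                          abort_invalid("--in is required"))
        render_summary(table, seed = as.integer(opts$seed %||% 1),
                       path = opts$out %||% "summary.csv")
        0L
      },
      "run-all" = {
        cfg <- run_config(
          out_dir = opts$out %||% "ergkit_run",
          sim = cli_sim_config(opts),
          n_boot = as.integer(opts$n_boot %||% 2000),
          seed = as.integer(opts$seed %||% 1))
        run_end_to_end(cfg)
        0L
      })
  },
  ergkit_invalid_argument = function(e) {
    message("configuration error: ", conditionMessage(e)); 2L
  },
  error = function(e) {
    message("stage error: ", conditionMessage(e)); 1L
  })
  invisible(status)
}
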