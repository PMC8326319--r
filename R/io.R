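# Data interchange: native trial-table CSVs (one per session plus a
# participants manifest), a mapping-driven adapter for externally deposited
# exports, schema validation, and the end-to-end pipeline drivers.

#' Write a cohort to disk as trial-table CSVs
#'
#' One CSV per session (`trials_<participant>_<condition>.csv`) plus a
#' `manifest.csv` with group, session order and the true generating
#' parameters (kept for parameter-recovery checks).
#'
#' @param cohort A [simulate_cohort()] result (or a list with `trials` and
#'   `manifest` tibbles).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$manifest, file.path(dir, "manifest.csv"))
  sessions <- split_sessions(cohort$trials)
  for (s in sessions) {
    fn <- sprintf("trials_%s_%s.csv", s$participant[1], s$condition[1])
    readr::write_csv(s, file.path(dir, fn))
  }
  invisible(dir)
}

validate_trials <- function(trials) {
  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- character()
  note <- function(rows, what) {
    if (length(rows) > 0) {
      shown <- paste(head(rows, 10), collapse = ", ")
      if (length(rows) > 10) shown <- paste0(shown, ", ...")
      problems <<- c(problems, sprintf("%s (rows %s)", what, shown))
    }
  }
  for (col in c("feedback_S", "feedback_O1", "feedback_O2")) {
    v <- trials[[col]]
    note(bad(v < .SCALE_MIN | v > .SCALE_MAX | v != round(v)),
         sprintf("`%s` outside integer range 1-15", col))
  }
  note(bad(!trials$context %in% c(-1, 1)),
       "`context` not coded +1 (cooperation) / -1 (competition)")
  note(bad(!trials$phase %in% c("starter", "main")), "unknown `phase`")
  note(bad(!trials$relevant_other %in% c("O1", "O2")),
       "unknown `relevant_other`")
  for (col in intersect(c("marker_S", "marker_O"), names(trials))) {
    v <- trials[[col]]
    note(bad(!is.na(v) & !on_marker_grid(v)),
         sprintf("`%s` off the X.5 marker grid", col))
  }
  if ("choice" %in% names(trials)) {
    note(bad(!is.na(trials$choice) & !trials$choice %in% c("engage", "avoid")),
         "unknown `choice`")
  }
  if (length(problems) > 0) {
    abort(paste0("Trial-table validation failed:\n- ",
                 paste(problems, collapse = "\n- ")),
          class = "somtrack_validation_error")
  }
  invisible(trials)
}

check_paired_schedules <- function(trials) {
  if (!all(c("participant", "condition") %in% names(trials))) {
    return(invisible(TRUE))
  }
  for (p in unique(trials$participant)) {
    tp <- trials[trials$participant == p, ]
    conds <- unique(tp$condition)
    if (length(conds) != 2) next
    a <- dplyr::arrange(tp[tp$condition == conds[1], ], .data$trial_index)
    b <- dplyr::arrange(tp[tp$condition == conds[2], ], .data$trial_index)
    k <- min(nrow(a), nrow(b))  # aborted sessions may be ragged
    same <- isTRUE(all.equal(a$feedback_S[1:k], b$feedback_S[1:k])) &&
      isTRUE(all.equal(a$feedback_O1[1:k], b$feedback_O1[1:k])) &&
      isTRUE(all.equal(a$feedback_O2[1:k], b$feedback_O2[1:k]))
    if (!same) {
      warn(sprintf(
        "Participant %s: the two sessions do not share one feedback schedule.",
        p))
      return(invisible(FALSE))
    }
  }
  invisible(TRUE)
}

apply_mapping <- function(trials, mapping) {
  if (is.character(mapping)) mapping <- jsonlite::read_json(mapping)
  cols <- mapping$columns
  if (is.null(cols)) {
    abort("An `osf` mapping must supply a `columns` entry (native = source).",
          class = "somtrack_usage_error")
  }
  for (native in names(cols)) {
    src <- cols[[native]]
    if (!src %in% names(trials)) {
      abort(sprintf("Mapped source column `%s` absent from the data.", src),
            class = "somtrack_validation_error")
    }
    trials[[native]] <- trials[[src]]
  }
  if (!is.null(mapping$context_map)) {
    cm <- mapping$context_map
    trials$context <- unlist(cm[as.character(trials$context)], use.names = FALSE)
  }
  if (!is.null(mapping$rating_positive)) {
    for (col in c("rating_S", "rating_O")) {
      trials[[col]] <- as.integer(trials[[col]] == mapping$rating_positive)
    }
  }
  trials
}

#' Load a behavioral dataset from disk
#'
#' Reads session trial-table CSVs (and `manifest.csv` when present) written
#' by [write_cohort()], or -- with `dialect = "osf"` and a user-supplied
#' column mapping -- an external deposit export, recoded into the native
#' schema. All rows pass schema validation (feedback within the integer 1-15
#' scale, markers on the X.5 grid, context coded +1/-1) with row-level
#' diagnostics on failure, and each participant's two sessions are checked
#' for a shared feedback schedule.
#'
#' @param dir Directory of CSV files.
#' @param dialect `"native"` or `"osf"`. The `osf` dialect requires
#'   `mapping` because the deposit's exact layout is not fixed.
#' @param mapping For `dialect = "osf"`: a list (or path to a JSON file)
#'   with `columns` (named: native = source), and optionally `context_map`
#'   (source value -> +1/-1) and `rating_positive` (source value coding a
#'   positive rating).
#' @return A list with `trials` (all sessions stacked) and `manifest`
#'   (or `NULL`).
#' @export
load_dataset <- function(dir, dialect = c("native", "osf"), mapping = NULL) {
  dialect <- match.arg(dialect)
  files <- list.files(dir, pattern = "^trials_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) {
    abort(sprintf("No trial-table CSVs (trials_*.csv) found in `%s`.", dir),
          class = "somtrack_usage_error")
  }
  trials <- dplyr::bind_rows(lapply(files, readr::read_csv,
                                    show_col_types = FALSE))
  if (dialect == "osf") {
    if (is.null(mapping)) {
      abort("dialect = \"osf\" requires a column `mapping`.",
            class = "somtrack_usage_error")
    }
    trials <- apply_mapping(trials, mapping)
  }
  missing <- setdiff(required_record_cols, names(trials))
  if (length(missing) > 0) {
    abort(paste0("Loaded data lacks columns: ", paste(missing, collapse = ", ")),
          class = "somtrack_validation_error")
  }
  validate_trials(trials)
  check_paired_schedules(trials)
  manifest_path <- file.path(dir, "manifest.csv")
  manifest <- if (file.exists(manifest_path)) {
    readr::read_csv(manifest_path, show_col_types = FALSE)
  } else NULL
  list(trials = trials, manifest = manifest)
}

#' Run the full analysis on a loaded trial table
#'
#' Fits one parameter set per group by maximum likelihood, computes the
#' per-session SOM effect sizes, and runs the baseline tests (no-cTBS
#' sessions pooled) and the stimulation comparison. This is the published
#' analysis applied end to end to any dataset in the native schema (use
#' [load_dataset()] with a mapping for external exports).
#'
#' @param trials A validated trial table covering all sessions.
#' @return A list of class `som_report` with `fits` (per group), `effects`,
#'   `baseline` and `ctbs` tibbles.
#' @export
reproduce_analysis <- function(trials) {
  groups <- unique(trials$group)
  fits <- lapply(stats::setNames(groups, groups), function(g) {
    fit_group(dplyr::filter(trials, .data$group == !!g))
  })
  effects <- som_effects(trials, fits)
  baseline <- baseline_som_tests(effects)
  ctbs <- tryCatch(ctbs_interaction_test(effects),
                   error = function(e) NULL)
  structure(list(fits = fits, effects = effects,
                 baseline = baseline, ctbs = ctbs),
            class = "som_report")
}

#' @export
print.som_report <- function(x, ...) {
  cat("SOM analysis report\n\nGroup fits:\n")
  for (g in names(x$fits)) {
    cat(sprintf("  %s: alpha = %.3f, beta = %.3f\n",
                g, x$fits[[g]]$alpha, x$fits[[g]]$beta))
  }
  cat("\nBaseline tests (variance-weighted effects, no-cTBS sessions):\n")
  print(x$baseline)
  if (!is.null(x$ctbs)) {
    cat("\nStimulation comparison (raw betas):\n")
    print(x$ctbs)
  }
  invisible(x)
}

#' Simulate-fit-GLM-stats pipeline from one configuration
#'
#' Runs the whole pipeline deterministically from a configuration list:
#' simulate a cohort, fit each group, estimate per-session SOM effects, and
#' run the baseline and stimulation tests. Re-running with the same
#' configuration reproduces the report exactly.
#'
#' @param config A list of [simulate_cohort()] arguments (must include
#'   `seed`), or a path to a JSON file holding one.
#' @param out_dir Optional directory; when given, the cohort CSVs, the
#'   effects table and a JSON report are written there.
#' @return The [reproduce_analysis()] report, with the cohort attached as
#'   attribute `"cohort"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) {
    abort("`config` must include a `seed`.", class = "somtrack_usage_error")
  }
  cohort <- do.call(simulate_cohort, config)
  report <- reproduce_analysis(cohort$trials)
  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir)
    readr::write_csv(report$effects, file.path(out_dir, "effects.csv"))
    jsonlite::write_json(
      list(
        config = config,
        fits = lapply(report$fits, glance),
        baseline = report$baseline,
        ctbs = report$ctbs
      ),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  attr(report, "cohort") <- cohort
  report
}
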