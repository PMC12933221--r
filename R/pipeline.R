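#' Pipeline state
#'
#' Mutable state carried across polling cycles: the set of processed file
#' paths, the current retention-time correction, and the measurement
#' history.
#'
#' @param history A `qc_history`.
#' @param rt_state An [rt_correction_state()].
#' @param processed Character vector of processed file paths.
#' @return A list of class `pipeline_state`.
#' @export
pipeline_state <- function(history = new_history(),
                           rt_state = rt_correction_state(),
                           processed = character()) {
  structure(list(history = history, rt_state = rt_state,
                 processed = unique(processed)),
            class = "pipeline_state")
}

#' Process one run through the full QC chain
#'
#' Measurement of every compound (with the current RT correction), univariate
#' verdict against the rolling history, multivariate evaluation when enough
#' normal-operating-conditions history exists, MS2 confirmation for targets
#' with a library entry, recording into the store, and the history update.
#' Blanks additionally refresh the RT correction (kept unchanged when no
#' internal standard is detected in the blank).
#'
#' @param run A [qc_run()].
#' @param state A [pipeline_state()].
#' @param cfg A [qc_config()].
#' @param specs A [compound_list()].
#' @param store Optional `qc_store` to record into.
#' @param library_dir Optional MS2 library directory.
#' @param run_id Run identifier; defaults to the run's file name.
#' @return List with `state` (updated), `verdict`, `mspc`, `ms2`,
#'   `measurements`.
#' @export
process_run <- function(run, state, cfg = qc_config(),
                        specs = default_internal_standards(), store = NULL,
                        library_dir = NULL, run_id = NULL) {
  run_id <- run_id %||% basename(run$path)
  polarity <- run_polarity(run)
  if (is.na(polarity)) polarity <- specs$polarity[1]
  measurements <- measure_run(run, specs, state$rt_state, cfg)

  if (run$sample_type == "blank") {
    shift <- blank_rt_shift(measurements, specs, source_blank = run$path,
                            computed_at = run$acquired_at)
    if (shift$n_standards_used >= 1) state$rt_state <- shift
  }

  verdict <- evaluate_run(measurements, state$history, cfg,
                          at = run$acquired_at, run_id = run_id,
                          sample_type = run$sample_type, specs = specs,
                          polarity = polarity)

  mspc <- NULL
  if (run$sample_type == "sample") {
    models <- mspc_models(state$history, run$acquired_at, cfg, specs, polarity)
    mspc <- evaluate_mspc(measurements, models, cfg, run_id, specs, polarity)
  }

  ms2 <- NULL
  if (!is.null(library_dir) && dir.exists(library_dir)) {
    targets <- specs[specs$role == "target", , drop = FALSE]
    if (nrow(targets) > 0) {
      ms2 <- purrr::list_rbind(purrr::map(seq_len(nrow(targets)), function(i) {
        tgt <- targets[i, ]
        m <- measurements[measurements$compound_id == tgt$identifier, , drop = FALSE]
        apex <- if (nrow(m) == 1 && isTRUE(m$detected)) m$apex_rt else NA_real_
        if (is.na(apex)) {
          return(tibble::tibble(compound_id = tgt$identifier, cosine = NA_real_,
                                n_matching_fragments = NA_integer_,
                                n_acquired_fragments = NA_integer_,
                                status = "not_detected"))
        }
        ms2_match(run, tgt, apex, library_dir, cfg)
      }))
    }
  }

  if (!is.null(store)) record_run(store, verdict, measurements, mspc, ms2, run)
  state$history <- update_history(state$history, verdict, measurements, specs,
                                  mspc_result = mspc)
  list(state = state, verdict = verdict, mspc = mspc, ms2 = ms2,
       measurements = measurements)
}

#' Process a sequence of in-memory runs
#'
#' Convenience wrapper over [process_run()] for simulated batches: runs are
#' processed in acquisition order against an evolving state.
#'
#' @param runs List of [qc_run()] objects.
#' @param state A [pipeline_state()].
#' @inheritParams process_run
#' @return List with `state`, `verdicts` (list), `mspc` (list), `summary`
#'   (tibble of verdict glances joined with multivariate outcomes).
#' @export
process_runs <- function(runs, state = pipeline_state(), cfg = qc_config(),
                         specs = default_internal_standards(), store = NULL,
                         library_dir = NULL) {
  ord <- order(vapply(runs, function(r) as.numeric(r$acquired_at), numeric(1)),
               vapply(runs, function(r) r$path %||% "", character(1)))
  runs <- runs[ord]
  verdicts <- list(); mspcs <- list()
  for (r in runs) {
    out <- process_run(r, state, cfg, specs, store, library_dir)
    state <- out$state
    verdicts[[length(verdicts) + 1]] <- out$verdict
    mspcs[[length(mspcs) + 1]] <- out$mspc
  }
  summary <- purrr::list_rbind(purrr::map(verdicts, glance))
  mspc_sum <- purrr::list_rbind(purrr::map(mspcs, function(m) {
    if (is.null(m)) return(NULL)
    glance(m)
  }))
  if (!is.null(mspc_sum) && nrow(mspc_sum) > 0) {
    summary <- dplyr::left_join(summary,
                                dplyr::select(mspc_sum, "run_id",
                                              "out_of_control", "flagged_blocks"),
                                by = "run_id")
  } else {
    summary$out_of_control <- NA
    summary$flagged_blocks <- NA_character_
  }
  list(state = state, verdicts = verdicts, mspc = mspcs, summary = summary)
}

#' Process all ready files in a folder once
#'
#' Discovers unprocessed mzML/mzXML files (subfolders included), keeps those
#' untouched for the quiet period, loads and processes them in acquisition
#' order. Files that fail to load are skipped — they stay unprocessed and are
#' retried on the next cycle.
#'
#' @param root Folder to scan.
#' @param state A [pipeline_state()].
#' @inheritParams process_run
#' @param now Reference time for the readiness check.
#' @return As [process_runs()], plus `skipped` (paths deferred this cycle).
#' @export
process_folder <- function(root, state = pipeline_state(), cfg = qc_config(),
                           specs = default_internal_standards(), store = NULL,
                           library_dir = NULL, now = Sys.time()) {
  candidates <- discover_unprocessed(root, state$processed)
  ready <- candidates[vapply(candidates, is_file_ready, logical(1),
                             now = now, quiet_period = cfg$quiet_period)]
  runs <- list(); loaded_paths <- character(); skipped <- character()
  for (path in ready) {
    run <- tryCatch(load_run(path, cfg$sample_type_tokens),
                    error = function(e) {
                      warn(paste0("skipping '", path, "': ", conditionMessage(e)))
                      NULL
                    })
    if (is.null(run)) skipped <- c(skipped, path)
    else {
      runs[[length(runs) + 1]] <- run
      loaded_paths <- c(loaded_paths, path)
    }
  }
  out <- process_runs(runs, state, cfg, specs, store, library_dir)
  out$state$processed <- unique(c(out$state$processed, loaded_paths))
  out$skipped <- c(setdiff(candidates, ready), skipped)
  out
}

#' Watch a folder, processing new files every cycle
#'
#' Repeats [process_folder()] with persistent state every `interval` seconds
#' until interrupted (or for `max_cycles` cycles, which keeps the loop
#' testable). Empty cycles are no-ops.
#'
#' @inheritParams process_folder
#' @param interval Seconds between cycles.
#' @param max_cycles Stop after this many cycles (default `Inf`).
#' @param on_cycle Optional callback `function(cycle_result, cycle_index)`.
#' @return The final [pipeline_state()], invisibly.
#' @export
watch_folder <- function(root, state = pipeline_state(), cfg = qc_config(),
                         specs = default_internal_standards(), store = NULL,
                         library_dir = NULL, interval = 60, max_cycles = Inf,
                         on_cycle = NULL) {
  cycle <- 0
  while (cycle < max_cycles) {
    cycle <- cycle + 1
    out <- process_folder(root, state, cfg, specs, store, library_dir)
    state <- out$state
    if (!is.null(on_cycle)) on_cycle(out, cycle)
    if (cycle < max_cycles) Sys.sleep(interval)
  }
  invisible(state)
}

#' Retrospective reanalysis of an internal-standard table
#'
#' Replays a per-measurement table (exported by
#' [export_internal_standard_table()] or imported from an external file via
#' [import_internal_standard_table()]) in acquisition order: each run is
#' evaluated univariately against the history accumulated so far, the
#' multivariate models are refitted from the QC-passing window, and the run
#' is projected onto them. Returns per-category counts and the two agreement
#' rates between the univariate and multivariate decisions (computed over
#' runs where multivariate models existed).
#'
#' @param table Tibble with the canonical internal-standard table columns,
#'   or a file path.
#' @param cfg A [qc_config()].
#' @param specs A [compound_list()].
#' @param polarity Polarity of the runs in the table.
#' @return List with `summary` (per-run tibble), `counts`
#'   ([count_verdicts()] row), and `agreement` (tibble with
#'   `univariate_flagged_also_mspc_pct` and `mspc_flagged_also_univariate_pct`).
#' @export
reanalyse_table <- function(table, cfg = qc_config(),
                            specs = default_internal_standards(),
                            polarity = "positive") {
  if (is.character(table)) table <- import_internal_standard_table(table)
  needed <- c("run_id", "acquired_at", "compound_id", "detected", "height",
              "apex_rt_s", "mass_error_ppm")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("reanalysis table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"sample_type" %in% names(table)) table$sample_type <- "sample"

  run_meta <- dplyr::distinct(table, .data$run_id, .data$acquired_at,
                              .data$sample_type)
  run_meta <- dplyr::arrange(run_meta, .data$acquired_at, .data$run_id)

  state <- pipeline_state()
  rows <- list()
  for (i in seq_len(nrow(run_meta))) {
    rid <- run_meta$run_id[i]; at <- run_meta$acquired_at[i]
    st <- run_meta$sample_type[i]
    rows_i <- table[table$run_id == rid, , drop = FALSE]
    measurements <- tibble::tibble(
      compound_id = rows_i$compound_id,
      detected = rows_i$detected & !is.na(rows_i$height),
      height = rows_i$height, apex_rt = rows_i$apex_rt_s,
      baseline = NA_real_, noise = NA_real_, sn = NA_real_,
      points_above = NA_integer_, mean_mz = NA_real_,
      mass_error = rows_i$mass_error_ppm, reason = NA_character_
    )
    verdict <- evaluate_run(measurements, state$history, cfg, at = at,
                            run_id = rid, sample_type = st, specs = specs,
                            polarity = polarity)
    mspc <- NULL
    if (st == "sample") {
      models <- mspc_models(state$history, at, cfg, specs, polarity)
      mspc <- evaluate_mspc(measurements, models, cfg, rid, specs, polarity)
    }
    state$history <- update_history(state$history, verdict, measurements, specs,
                                    mspc_result = mspc)
    g <- glance(verdict)
    g$out_of_control <- if (is.null(mspc)) NA else mspc$out_of_control
    g$flagged_blocks <- if (is.null(mspc)) NA_character_
                        else paste(mspc$flagged_blocks, collapse = ";")
    rows[[i]] <- g
  }
  summary <- purrr::list_rbind(rows)

  with_mspc <- summary[!is.na(summary$out_of_control), , drop = FALSE]
  univ_flagged <- with_mspc[!with_mspc$pass, , drop = FALSE]
  mspc_flagged <- with_mspc[with_mspc$out_of_control, , drop = FALSE]
  agreement <- tibble::tibble(
    n_evaluated = nrow(with_mspc),
    univariate_flagged_also_mspc_pct =
      if (nrow(univ_flagged) == 0) NA_real_
      else 100 * mean(univ_flagged$out_of_control),
    mspc_flagged_also_univariate_pct =
      if (nrow(mspc_flagged) == 0) NA_real_
      else 100 * mean(!mspc_flagged$pass)
  )
  list(summary = summary, counts = count_verdicts(summary),
       agreement = agreement)
}
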