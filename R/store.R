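#' Open (or create) a results store
#'
#' The store is a small set of relational tables — `runs`, `is_results`,
#' `verdicts`, `mspc`, `ms2` — kept in memory and persisted as CSV files in
#' one directory, so a desk-scale deployment needs no database server while
#' the schema stays portable to one. Re-opening a directory reloads all
#' tables; re-recording a run replaces its rows atomically.
#'
#' @param dir Directory for the CSV tables; `NULL` keeps the store
#'   in-memory only.
#' @return An environment of class `qc_store`.
#' @export
store_open <- function(dir = NULL) {
  store <- new.env(parent = emptyenv())
  store$dir <- dir
  store$tables <- empty_store_tables()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (tb in names(store$tables)) {
      path <- file.path(dir, paste0(tb, ".csv"))
      if (file.exists(path)) {
        loaded <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
        template <- store$tables[[tb]]
        for (cn in names(template)) {
          if (!cn %in% names(loaded)) loaded[[cn]] <- template[[cn]][0][NA]
        }
        store$tables[[tb]] <- tibble::as_tibble(loaded)[, names(template)]
      }
    }
  }
  class(store) <- "qc_store"
  store
}

empty_store_tables <- function() {
  list(
    runs = tibble::tibble(run_id = character(), path = character(),
                          acquired_at = as.POSIXct(character()),
                          sample_type = character(), polarity = character(),
                          batch_id = character()),
    is_results = tibble::tibble(run_id = character(), compound_id = character(),
                                detected = logical(), height = numeric(),
                                apex_rt_s = numeric(),
                                normalised_intensity = numeric(),
                                rt_deviation_s = numeric(),
                                mass_error_ppm = numeric(),
                                reasons = character()),
    verdicts = tibble::tibble(run_id = character(), pass = logical(),
                              category = character(), reasons = character(),
                              skipped_checks = character()),
    mspc = tibble::tibble(run_id = character(), block = character(),
                          t2 = numeric(), t2_limit = numeric(),
                          t2_reject = logical(), spe = numeric(),
                          spe_limit = numeric(), spe_reject = logical(),
                          flagged = logical(), out_of_control = logical()),
    ms2 = tibble::tibble(run_id = character(), compound_id = character(),
                         cosine = numeric(), n_matching_fragments = integer(),
                         status = character())
  )
}

#' @export
print.qc_store <- function(x, ...) {
  cat("<qc_store> ", if (is.null(x$dir)) "(in-memory)" else x$dir, "\n", sep = "")
  for (tb in names(x$tables)) {
    cat("  ", tb, ": ", nrow(x$tables[[tb]]), " rows\n", sep = "")
  }
  invisible(x)
}

store_flush <- function(store) {
  if (is.null(store$dir)) return(invisible(store))
  for (tb in names(store$tables)) {
    readr::write_csv(store$tables[[tb]], file.path(store$dir, paste0(tb, ".csv")),
                     progress = FALSE)
  }
  invisible(store)
}

replace_rows <- function(tbl, new_rows, run_id) {
  dplyr::bind_rows(tbl[tbl$run_id != run_id, , drop = FALSE], new_rows)
}

#' Record one processed run
#'
#' All tables are updated together: run metadata, per-standard results
#' (values alongside the verdict's normalised metrics and reasons), the
#' univariate verdict, the multivariate statistics with their control limits
#' (so trend analysis can track the D- and Q-statistics against their
#' thresholds), and any MS2 match results. Recording the same run again
#' replaces its rows — row counts do not grow.
#'
#' @param store A [store_open()] store.
#' @param verdict A `qc_verdict`.
#' @param measurements The [measure_run()] table behind the verdict.
#' @param mspc_result Optional `mspc_result`.
#' @param ms2_results Optional tibble of [ms2_match()] rows.
#' @param run Optional [qc_run()] supplying path/polarity/batch metadata.
#' @return The run id, invisibly.
#' @export
record_run <- function(store, verdict, measurements, mspc_result = NULL,
                       ms2_results = NULL, run = NULL) {
  run_id <- verdict$run_id
  if (is.na(run_id)) abort("verdict must carry a run_id")
  if (run_id %in% store$tables$runs$run_id) {
    inform(paste0("run '", run_id, "' re-recorded; previous rows replaced"))
  }
  store$tables$runs <- replace_rows(store$tables$runs, tibble::tibble(
    run_id = run_id,
    path = if (!is.null(run)) run$path else NA_character_,
    acquired_at = verdict$at,
    sample_type = verdict$sample_type,
    polarity = if (!is.null(run)) run_polarity(run) else NA_character_,
    batch_id = if (!is.null(run)) run$batch_id else NA_character_
  ), run_id)

  std <- verdict$standards
  m <- dplyr::left_join(std,
                        dplyr::select(measurements, "compound_id", "apex_rt"),
                        by = "compound_id")
  store$tables$is_results <- replace_rows(store$tables$is_results, tibble::tibble(
    run_id = run_id, compound_id = m$compound_id, detected = m$detected,
    height = m$height, apex_rt_s = m$apex_rt,
    normalised_intensity = m$normalised_intensity,
    rt_deviation_s = m$rt_deviation, mass_error_ppm = m$mass_error,
    reasons = m$reasons
  ), run_id)

  store$tables$verdicts <- replace_rows(store$tables$verdicts, tibble::tibble(
    run_id = run_id, pass = verdict$pass, category = verdict$category,
    reasons = paste(verdict$reasons, collapse = ";"),
    skipped_checks = paste(verdict$skipped_checks, collapse = ";")
  ), run_id)

  if (!is.null(mspc_result) && nrow(mspc_result$blocks) > 0) {
    store$tables$mspc <- replace_rows(
      store$tables$mspc,
      dplyr::mutate(mspc_result$blocks, run_id = run_id, .before = 1,
                    out_of_control = mspc_result$out_of_control),
      run_id)
  } else {
    store$tables$mspc <- replace_rows(store$tables$mspc,
                                      store$tables$mspc[0, ], run_id)
  }

  if (!is.null(ms2_results) && nrow(ms2_results) > 0) {
    store$tables$ms2 <- replace_rows(store$tables$ms2, tibble::tibble(
      run_id = run_id, compound_id = ms2_results$compound_id,
      cosine = ms2_results$cosine,
      n_matching_fragments = as.integer(ms2_results$n_matching_fragments),
      status = ms2_results$status
    ), run_id)
  }
  store_flush(store)
  invisible(run_id)
}

#' Export the per-measurement internal-standard table
#'
#' One row per (run, internal standard) joining run metadata with the stored
#' raw and normalised metrics — the long-format table used for retrospective
#' reanalysis and external plotting. Importing this file back and
#' re-evaluating reproduces the stored verdicts.
#'
#' @param store A `qc_store`.
#' @param path Optional CSV output path.
#' @param from,to Optional timestamp range filter on acquisition time.
#' @return The table (tibble); written to `path` when given.
#' @export
export_internal_standard_table <- function(store, path = NULL,
                                           from = NULL, to = NULL) {
  runs <- store$tables$runs
  if (!is.null(from)) runs <- runs[runs$acquired_at >= from, , drop = FALSE]
  if (!is.null(to)) runs <- runs[runs$acquired_at <= to, , drop = FALSE]
  out <- dplyr::inner_join(runs, store$tables$is_results, by = "run_id")
  out <- dplyr::left_join(out,
                          dplyr::select(store$tables$verdicts, "run_id",
                                        run_pass = "pass",
                                        run_category = "category"),
                          by = "run_id")
  out <- dplyr::arrange(out, .data$acquired_at, .data$run_id, .data$compound_id)
  if (!is.null(path)) readr::write_csv(out, path, progress = FALSE)
  out
}

# Header-synonym map for externally produced internal-standard tables.
is_table_synonyms <- list(
  run_id = c("run_id", "run", "measurement_id", "sample_id", "file", "filename"),
  acquired_at = c("acquired_at", "timestamp", "time", "acquisition_time", "date"),
  sample_type = c("sample_type", "type"),
  compound_id = c("compound_id", "compound", "internal_standard", "istd", "name"),
  detected = c("detected", "found"),
  height = c("height", "peak_height", "intensity"),
  apex_rt_s = c("apex_rt_s", "apex_rt", "rt", "retention_time", "retention_time_s"),
  mass_error_ppm = c("mass_error_ppm", "mass_error", "ppm_error")
)

#' Import an internal-standard table for reanalysis
#'
#' Header-driven and tolerant of column synonyms (e.g. `timestamp` for
#' `acquired_at`, `peak_height` for `height`), so tables exported by this
#' package and externally produced per-measurement tables both load. The
#' minimum usable set is a run identifier, a timestamp, a compound identifier
#' and the three raw metrics; `detected` defaults to "height present".
#'
#' @param path Delimited text file.
#' @return Tibble with the canonical columns of the exported table.
#' @export
import_internal_standard_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  lower <- gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", tolower(names(raw))))
  pick <- function(key) {
    hit <- which(lower %in% is_table_synonyms[[key]])
    if (length(hit) == 0) NULL else raw[[hit[1]]]
  }
  need <- c("run_id", "acquired_at", "compound_id", "height",
            "apex_rt_s", "mass_error_ppm")
  vals <- lapply(setNames(nm = names(is_table_synonyms)), pick)
  missing_cols <- need[vapply(vals[need], is.null, logical(1))]
  if (length(missing_cols) > 0) {
    abort(paste0("internal-standard table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  at <- vals$acquired_at
  if (!inherits(at, "POSIXct")) at <- as.POSIXct(at, tz = "UTC")
  tibble::tibble(
    run_id = as.character(vals$run_id),
    acquired_at = at,
    sample_type = if (is.null(vals$sample_type)) "sample"
                  else as.character(vals$sample_type),
    compound_id = as.character(vals$compound_id),
    detected = if (is.null(vals$detected)) !is.na(as.numeric(vals$height))
               else as.logical(vals$detected),
    height = as.numeric(vals$height),
    apex_rt_s = as.numeric(vals$apex_rt_s),
    mass_error_ppm = as.numeric(vals$mass_error_ppm)
  )
}

#' Render an alert report for a flagged run
#'
#' Replaces the original e-mail dispatch: a plain-text report naming every
#' breached metric with its value and limit (univariate), the multivariate
#' D/Q statistics against their thresholds (labelled advisory when only the
#' multivariate tests fired — the actual values behind a warning should
#' always be inspected before acting), plus a JSON side-car with the 60-day
#' history series per standard for plotting. Nothing is written for a clean
#' run.
#'
#' @param store A `qc_store`.
#' @param run_id Run to report on.
#' @param outbox Directory for the report files.
#' @param cfg A [qc_config()] (for the limit values quoted in the report).
#' @return Path of the text report, or `NULL` when the run is clean.
#' @export
render_alert <- function(store, run_id, outbox, cfg = qc_config()) {
  v <- store$tables$verdicts[store$tables$verdicts$run_id == run_id, , drop = FALSE]
  if (nrow(v) == 0) abort(paste0("no verdict recorded for run '", run_id, "'"))
  mspc <- store$tables$mspc[store$tables$mspc$run_id == run_id, , drop = FALSE]
  mspc_flagged <- nrow(mspc) > 0 && isTRUE(any(mspc$flagged))
  if (v$pass && !mspc_flagged) return(invisible(NULL))
  if (!dir.exists(outbox)) dir.create(outbox, recursive = TRUE)

  is_rows <- store$tables$is_results[store$tables$is_results$run_id == run_id, ,
                                     drop = FALSE]
  run_row <- store$tables$runs[store$tables$runs$run_id == run_id, , drop = FALSE]
  lim <- cfg$intensity_limits
  lines <- c(
    paste0("QC ALERT  run ", run_id, "  (", format(run_row$acquired_at), ")"),
    paste0("univariate: ", if (v$pass) "pass" else paste0("FAIL [", v$category, "]")),
    ""
  )
  if (!v$pass) {
    for (i in seq_len(nrow(is_rows))) {
      r <- is_rows[i, ]
      if (is.na(r$reasons)) next
      lines <- c(lines, paste0(
        "  ", r$compound_id, ": ", r$reasons,
        if (!is.na(r$normalised_intensity))
          sprintf(" | norm. intensity %.3f (limits %.1f-%.1f)",
                  r$normalised_intensity, lim[1], lim[2]) else "",
        if (!is.na(r$rt_deviation_s))
          sprintf(" | RT dev %+.1f s (limit +/-%g s)",
                  r$rt_deviation_s, cfg$rt_deviation_limit) else "",
        if (!is.na(r$mass_error_ppm))
          sprintf(" | mass error %+.2f ppm (limit +/-%g ppm)",
                  r$mass_error_ppm, cfg$mass_error_limit) else ""
      ))
    }
  }
  if (nrow(mspc) > 0) {
    lines <- c(lines, "",
               if (v$pass && mspc_flagged)
                 "multivariate anomaly (ADVISORY: no univariate limit breached; inspect the values below)"
               else "multivariate statistics:")
    for (i in seq_len(nrow(mspc))) {
      b <- mspc[i, ]
      lines <- c(lines, sprintf(
        "  %-15s T2 %8.2f / limit %8.2f %s | SPE %8.2f / limit %8.2f %s%s",
        b$block, b$t2, b$t2_limit, ifelse(b$t2_reject, "REJECT", "ok    "),
        b$spe, b$spe_limit, ifelse(b$spe_reject, "REJECT", "ok    "),
        ifelse(b$flagged, "  << flagged", "")))
    }
  }
  txt_path <- file.path(outbox, paste0("alert_", gsub("[^A-Za-z0-9_.-]", "_", run_id), ".txt"))
  writeLines(lines, txt_path)

  at <- run_row$acquired_at
  hist_rows <- dplyr::inner_join(
    store$tables$is_results,
    dplyr::select(store$tables$runs, "run_id", "acquired_at"),
    by = "run_id")
  hist_rows <- hist_rows[hist_rows$acquired_at >= at - cfg$rolling_window * 86400 &
                           hist_rows$acquired_at <= at, , drop = FALSE]
  series <- split(
    hist_rows[, c("run_id", "acquired_at", "height", "apex_rt_s",
                  "normalised_intensity", "rt_deviation_s", "mass_error_ppm")],
    hist_rows$compound_id)
  jsonlite::write_json(
    list(run_id = run_id, generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         history = lapply(series, function(d) {
           d$acquired_at <- format(d$acquired_at, "%Y-%m-%dT%H:%M:%S")
           d
         })),
    sub("\\.txt$", ".json", txt_path), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(txt_path)
}
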