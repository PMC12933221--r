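#' Create an empty measurement history
#'
#' The history store holds one row per (run, internal standard) with the
#' measured height, apex RT and mass error, the run's sample type and — once
#' known — its univariate QC outcome. Rolling medians and the
#' normal-operating-conditions (NOC) set are both queried from it.
#'
#' @return A tibble of class `qc_history` with zero rows.
#' @export
new_history <- function() {
  h <- tibble::tibble(
    run_id = character(), at = as.POSIXct(character()),
    sample_type = character(), pass = logical(),
    out_of_control = logical(),
    compound_id = character(), detected = logical(),
    height = numeric(), apex_rt = numeric(), mass_error = numeric()
  )
  class(h) <- c("qc_history", class(h))
  h
}

as_history <- function(tbl) {
  h <- tibble::as_tibble(tbl)
  missing_cols <- setdiff(names(new_history()), names(h))
  if (length(missing_cols) > 0) {
    abort(paste0("history missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  class(h) <- unique(c("qc_history", class(h)))
  h
}

# Open at both ends: a record exactly `window_days` old is already outside,
# and the run under evaluation (timestamp `at`) is never its own history.
history_window <- function(history, at, window_days) {
  lo <- at - window_days * 86400
  history[history$at > lo & history$at < at, , drop = FALSE]
}

#' Rolling median of a stored metric
#'
#' Median of the stored values for one compound in the window
#' `(at - window days, at)`, open at both ends: a record exactly
#' `window` days old is excluded and the run under evaluation is never
#' included. Heights are pooled from sample runs only (blanks and
#' standards carry different matrix/levels); retention times use all run
#' types. Returns `NA` when fewer than `min_records` detections are
#' available, in which case the corresponding check is skipped.
#'
#' @param history A `qc_history` tibble.
#' @param compound Compound identifier.
#' @param at Evaluation timestamp (`POSIXct`).
#' @param field `"height"` or `"rt"`.
#' @param window Window length in days (default 60).
#' @param min_records Minimum detections required (default 5).
#' @return Median value, or `NA_real_`.
#' @export
rolling_median <- function(history, compound, at, field = c("height", "rt"),
                           window = 60, min_records = 5) {
  field <- match.arg(field)
  h <- history_window(history, at, window)
  h <- h[h$compound_id == compound & h$detected, , drop = FALSE]
  if (field == "height") {
    h <- h[h$sample_type == "sample", , drop = FALSE]
    v <- h$height
  } else {
    v <- h$apex_rt
  }
  v <- v[!is.na(v)]
  if (length(v) < min_records) return(NA_real_)
  median(v)
}

#' Append a run's measurements to the history
#'
#' Detected internal-standard records are appended with the run's timestamp,
#' sample type and univariate outcome. Failing runs are stored too — the
#' rolling medians are robust to a minority of faulty runs — but are excluded
#' from the NOC downstream. Undetected standards are appended as
#' `detected = FALSE` rows so NOC eligibility (minimum detected standards per
#' run) can be evaluated later.
#'
#' Runs declared out of control by the multivariate tests are recorded as
#' such and also barred from the NOC: a model retrained on its own alarms
#' would absorb a persistent fault within a few injections.
#'
#' @param history A `qc_history` tibble.
#' @param verdict A `qc_verdict` from [evaluate_run()].
#' @param measurements The [measure_run()] table behind the verdict.
#' @param specs A [compound_list()]; only internal standards are stored.
#' @param mspc_result Optional `mspc_result` for the same run.
#' @return The updated `qc_history`.
#' @export
update_history <- function(history, verdict, measurements,
                           specs = default_internal_standards(),
                           mspc_result = NULL) {
  is_ids <- internal_standards_only(specs)$identifier
  m <- measurements[measurements$compound_id %in% is_ids, , drop = FALSE]
  if (nrow(m) == 0) return(history)
  add <- tibble::tibble(
    run_id = verdict$run_id, at = verdict$at,
    sample_type = verdict$sample_type, pass = verdict$pass,
    out_of_control = if (is.null(mspc_result)) NA
                     else isTRUE(mspc_result$out_of_control),
    compound_id = m$compound_id, detected = m$detected,
    height = m$height, apex_rt = m$apex_rt, mass_error = m$mass_error
  )
  as_history(dplyr::bind_rows(history, add))
}
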