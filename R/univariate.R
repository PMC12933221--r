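#' Univariate QC verdict for one run
#'
#' Each internal standard is checked against three rolling limits, all
#' inclusive (a value exactly at a limit passes):
#'
#' * normalised intensity — height divided by its 60-day rolling median —
#'   inside `intensity_limits` (default 0.5 to 2.0);
#' * retention-time deviation from the 60-day median RT within
#'   `rt_deviation_limit` (default +/-10 s);
#' * mass error within `mass_error_limit` (default +/-10 ppm).
#'
#' An undetected internal standard is a failure in its own right
#' (`missing_is`). The run category follows the reporting convention:
#' `missing_is` whenever any standard is undetected; otherwise `multiple`
#' when at least two different limit types are breached; otherwise the single
#' breached limit; otherwise `pass`. Checks without sufficient history
#' (fewer than `min_history` prior detections) are skipped and recorded in
#' `skipped_checks`.
#'
#' @param measurements [measure_run()] output for the run.
#' @param history A `qc_history` tibble (must not contain this run).
#' @param cfg A [qc_config()].
#' @param at Evaluation timestamp.
#' @param run_id Run identifier.
#' @param sample_type Run sample type.
#' @param specs A [compound_list()]; internal standards matching
#'   `polarity` are evaluated.
#' @param polarity Run polarity (default `"positive"`).
#' @return A `qc_verdict`: list with `run_id`, `at`, `sample_type`, `pass`,
#'   `reasons`, `category`, `skipped_checks` and a per-standard tibble
#'   `standards`.
#' @export
evaluate_run <- function(measurements, history, cfg = qc_config(),
                         at = Sys.time(), run_id = NA_character_,
                         sample_type = "sample",
                         specs = default_internal_standards(),
                         polarity = "positive") {
  is_specs <- internal_standards_only(specs, polarity)
  lim <- cfg$intensity_limits
  skipped <- character()

  rows <- purrr::map(seq_len(nrow(is_specs)), function(i) {
    id <- is_specs$identifier[i]
    m <- measurements[measurements$compound_id == id, , drop = FALSE]
    detected <- nrow(m) == 1 && isTRUE(m$detected)
    out <- tibble::tibble(
      compound_id = id, detected = detected,
      height = NA_real_, normalised_intensity = NA_real_,
      rt_deviation = NA_real_, mass_error = NA_real_,
      reasons = NA_character_
    )
    if (!detected) {
      out$reasons <- "missing_is"
      return(out)
    }
    reasons <- character()
    out$height <- m$height
    out$mass_error <- m$mass_error

    med_h <- rolling_median(history, id, at, "height",
                            cfg$rolling_window, cfg$min_history)
    if (is.na(med_h) || med_h <= 0) {
      skipped <<- union(skipped, "height")
    } else {
      out$normalised_intensity <- m$height / med_h
      if (out$normalised_intensity < lim[1] || out$normalised_intensity > lim[2]) {
        reasons <- c(reasons, "height")
      }
    }

    med_rt <- rolling_median(history, id, at, "rt",
                             cfg$rolling_window, cfg$min_history)
    if (is.na(med_rt)) {
      skipped <<- union(skipped, "retention_time")
    } else {
      out$rt_deviation <- m$apex_rt - med_rt
      if (abs(out$rt_deviation) > cfg$rt_deviation_limit) {
        reasons <- c(reasons, "retention_time")
      }
    }

    if (is.na(m$mass_error)) {
      skipped <<- union(skipped, "mass_error")
    } else if (abs(m$mass_error) > cfg$mass_error_limit) {
      reasons <- c(reasons, "mass_error")
    }

    out$reasons <- if (length(reasons)) paste(reasons, collapse = ";") else NA_character_
    out
  })
  standards <- purrr::list_rbind(rows)

  all_reasons <- unique(unlist(strsplit(
    standards$reasons[!is.na(standards$reasons)], ";", fixed = TRUE)))
  limit_reasons <- setdiff(all_reasons, "missing_is")
  category <- if ("missing_is" %in% all_reasons) {
    "missing_is"
  } else if (length(limit_reasons) >= 2) {
    "multiple"
  } else if (length(limit_reasons) == 1) {
    limit_reasons
  } else {
    "pass"
  }

  structure(
    list(run_id = run_id, at = at, sample_type = sample_type,
         pass = length(all_reasons) == 0, reasons = all_reasons,
         category = category, skipped_checks = skipped,
         standards = standards),
    class = "qc_verdict"
  )
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat("<qc_verdict> run ", x$run_id %||% "?", ": ",
      if (x$pass) "PASS" else paste0("FAIL (", x$category, ")"), "\n", sep = "")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  if (length(x$skipped_checks)) {
    cat("  skipped (insufficient history):",
        paste(x$skipped_checks, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname evaluate_run
#' @param x A `qc_verdict`.
#' @param ... Unused.
#' @export
tidy.qc_verdict <- function(x, ...) {
  dplyr::mutate(x$standards, run_id = x$run_id, .before = 1)
}

#' @rdname evaluate_run
#' @export
glance.qc_verdict <- function(x, ...) {
  tibble::tibble(
    run_id = x$run_id, at = x$at, sample_type = x$sample_type,
    pass = x$pass, category = x$category,
    n_standards = nrow(x$standards),
    n_detected = sum(x$standards$detected),
    reasons = paste(x$reasons, collapse = ";")
  )
}

#' Tabulate verdict categories
#'
#' Summarises a set of verdicts the way longitudinal reviews count them:
#' total runs, runs violating at least one limit, runs with a missing
#' internal standard, and — among the remaining flagged runs — counts per
#' single category and `multiple`. By construction
#' `flagged_excl_missing = height + retention_time + mass_error + multiple`.
#'
#' @param verdicts List of `qc_verdict` objects, or a tibble of
#'   [glance()]d verdicts.
#' @return One-row tibble of counts.
#' @export
count_verdicts <- function(verdicts) {
  g <- if (inherits(verdicts, "data.frame")) {
    tibble::as_tibble(verdicts)
  } else {
    purrr::list_rbind(purrr::map(verdicts, glance))
  }
  tibble::tibble(
    total = nrow(g),
    flagged = sum(!g$pass),
    missing_is = sum(g$category == "missing_is"),
    flagged_excl_missing = sum(!g$pass & g$category != "missing_is"),
    height = sum(g$category == "height"),
    retention_time = sum(g$category == "retention_time"),
    mass_error = sum(g$category == "mass_error"),
    multiple = sum(g$category == "multiple")
  )
}
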