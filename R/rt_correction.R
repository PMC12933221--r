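#' Retention-time correction state
#'
#' Long-term retention-time drift (column ageing, column replacement) is
#' absorbed by a single additive shift: the median deviation of all detected
#' internal standards in the most recent blank, applied uniformly to every
#' stored expected RT. The shift is always recomputed against the original
#' stored RTs — the latest blank wins, shifts never accumulate.
#'
#' @param shift Signed shift in seconds.
#' @param source_blank Path of the blank that produced the shift.
#' @param computed_at Timestamp of the blank.
#' @param n_standards_used Number of detected internal standards behind the
#'   median.
#' @return A list of class `rt_correction_state`.
#' @export
rt_correction_state <- function(shift = 0, source_blank = NA_character_,
                                computed_at = NA, n_standards_used = 0L) {
  if (shift != 0 && n_standards_used < 1) {
    abort("a non-zero shift requires n_standards_used >= 1")
  }
  structure(list(shift = shift, source_blank = source_blank,
                 computed_at = computed_at,
                 n_standards_used = as.integer(n_standards_used)),
            class = "rt_correction_state")
}

#' Retention-time shift from a blank
#'
#' The shift is the median over detected internal standards of
#' `apex_rt - expected_rt` (even counts take the mean of the two middle
#' values). Undetected standards are excluded; if none is detected the state
#' carries shift 0 and `n_standards_used = 0`, and the caller keeps its
#' previous correction. Internal standards in blanks are searched with a
#' tripled RT tolerance upstream, so drift beyond the sample tolerance is
#' still measurable here.
#'
#' @param blank_measurements [measure_run()] output for a blank run.
#' @param specs The [compound_list()] supplying stored expected RTs.
#' @param source_blank,computed_at Provenance carried into the state.
#' @return An [rt_correction_state()].
#' @export
#' @examples
#' specs <- default_internal_standards()
#' m <- tibble::tibble(compound_id = specs$identifier[1:3], detected = TRUE,
#'                     apex_rt = specs$expected_rt[1:3] + c(4, 5, 6))
#' blank_rt_shift(m, specs)$shift # 5
blank_rt_shift <- function(blank_measurements, specs,
                           source_blank = NA_character_, computed_at = NA) {
  is_specs <- internal_standards_only(specs)
  m <- dplyr::inner_join(
    dplyr::filter(blank_measurements, .data$detected),
    dplyr::select(tibble::as_tibble(is_specs), compound_id = "identifier",
                  "expected_rt"),
    by = "compound_id"
  )
  if (nrow(m) == 0) {
    return(rt_correction_state(0, source_blank, computed_at, 0L))
  }
  rt_correction_state(
    shift = median(m$apex_rt - m$expected_rt),
    source_blank = source_blank, computed_at = computed_at,
    n_standards_used = nrow(m)
  )
}

#' Apply the current RT correction to a compound list
#'
#' Every compound's expected RT — internal standards and targets alike — is
#' shifted by the same amount; stored RTs remain untouched.
#'
#' @param specs A [compound_list()].
#' @param state An [rt_correction_state()].
#' @return Tibble `identifier`, `expected_rt`, `corrected_rt`.
#' @export
apply_rt_correction <- function(specs, state = rt_correction_state()) {
  tibble::tibble(
    identifier = specs$identifier,
    expected_rt = specs$expected_rt,
    corrected_rt = specs$expected_rt + state$shift
  )
}
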