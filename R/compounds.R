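#' Compound list: internal standards and targets
#'
#' A compound list drives every downstream step: each row gives the exact
#' (monoisotopic, adduct-corrected) m/z used for ion extraction, the expected
#' retention time, the ionisation polarity and the role of the compound.
#' Internal standards (`role = "internal_standard"`) are isotopically labelled
#' compounds co-injected with every sample; their peak metrics proxy
#' instrument performance. Targets (`role = "target"`) are screened
#' qualitatively and may carry an MS2 library entry.
#'
#' @param identifier Unique compound key (also the MS2 library file stem).
#' @param name Display name.
#' @param mz Theoretical m/z in Da (> 0).
#' @param rt Expected retention time, in seconds.
#' @param polarity `"positive"` or `"negative"`.
#' @param role `"internal_standard"` or `"target"`.
#' @param ms2_key Optional MS2 library identifier; defaults to `identifier`
#'   for targets.
#'
#' @return A tibble with class `compound_list`, one row per compound.
#' @export
#' @examples
#' compound_list(
#'   identifier = c("lid_d10", "ben_d4"),
#'   name = c("Lidocaine-d10", "Benzothiazole-d4"),
#'   mz = c(245.2433, 124.0807),
#'   rt = c(318.6, 333.6),
#'   polarity = "positive",
#'   role = "internal_standard"
#' )
compound_list <- function(identifier, name = identifier, mz, rt,
                          polarity = "positive", role = "internal_standard",
                          ms2_key = NA_character_) {
  specs <- tibble::tibble(
    identifier = as.character(identifier),
    name = as.character(name),
    theoretical_mz = as.numeric(mz),
    expected_rt = as.numeric(rt),
    polarity = as.character(polarity),
    role = as.character(role),
    ms2_key = as.character(ms2_key)
  )
  validate_compound_list(specs)
}

validate_compound_list <- function(specs) {
  dup <- specs$identifier[duplicated(specs$identifier)]
  if (length(dup) > 0) {
    abort(paste0("duplicate compound identifier(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(!is.finite(specs$theoretical_mz)) || any(specs$theoretical_mz <= 0)) {
    bad <- specs$identifier[!is.finite(specs$theoretical_mz) | specs$theoretical_mz <= 0]
    abort(paste0("non-positive m/z for: ", paste(bad, collapse = ", ")))
  }
  if (any(specs$expected_rt < 0)) {
    abort("expected_rt must be >= 0 seconds")
  }
  if (!all(specs$polarity %in% c("positive", "negative"))) {
    abort("polarity must be 'positive' or 'negative'")
  }
  if (!all(specs$role %in% c("internal_standard", "target"))) {
    abort("role must be 'internal_standard' or 'target'")
  }
  class(specs) <- c("compound_list", class(tibble::tibble()))
  specs
}

#' Read a compound list from delimited text
#'
#' Expected columns: `identifier`, `name`, `mz`, `rt`, `polarity`, `role`
#' (and optionally `ms2_key`). Retention times are normalised to seconds:
#' with `rt_unit = "auto"` the unit is taken from an `rt_unit` column if
#' present, otherwise values are assumed to be minutes when every RT is
#' below 60 (chromatographic methods shorter than a minute do not occur
#' in this context) and seconds otherwise.
#'
#' @param path CSV file path.
#' @param rt_unit `"auto"`, `"seconds"` or `"minutes"`.
#' @return A [compound_list()] tibble with RT in seconds.
#' @export
load_compound_list <- function(path, rt_unit = c("auto", "seconds", "minutes")) {
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) abort(paste0("compound list not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("identifier", "name", "mz", "rt", "polarity", "role")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("compound list missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(compound_list(identifier = character(), mz = numeric(), rt = numeric()))
  }
  rt <- as.numeric(raw$rt)
  unit <- rt_unit
  if (unit == "auto") {
    if ("rt_unit" %in% names(raw)) {
      unit <- if (all(raw$rt_unit %in% c("min", "minutes"))) "minutes" else "seconds"
    } else {
      unit <- if (all(rt < 60, na.rm = TRUE)) "minutes" else "seconds"
    }
  }
  if (unit == "minutes") rt <- rt * 60
  compound_list(
    identifier = raw$identifier, name = raw$name, mz = raw$mz, rt = rt,
    polarity = raw$polarity, role = raw$role,
    ms2_key = if ("ms2_key" %in% names(raw)) raw$ms2_key else NA_character_
  )
}

#' Write a compound list to CSV (seconds, explicit unit column)
#' @param specs A [compound_list()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_list <- function(specs, path) {
  out <- tibble::tibble(
    identifier = specs$identifier, name = specs$name,
    mz = specs$theoretical_mz, rt = specs$expected_rt,
    rt_unit = "seconds", polarity = specs$polarity, role = specs$role,
    ms2_key = specs$ms2_key
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' The bundled ESI+ internal-standard panel
#'
#' Eight deuterated internal standards routinely co-injected in positive-mode
#' river-water screening, with exact m/z and expected retention times.
#' The m/z 124.0807 standard is listed as Benzothiazole-d4; the name
#' Benzotriazole-d4 also circulates for the same m/z/RT entry, so treat the
#' identifier (not the display name) as authoritative.
#'
#' @return A [compound_list()] of 8 internal standards, RT in seconds.
#' @export
#' @examples
#' default_internal_standards()
default_internal_standards <- function() {
  compound_list(
    identifier = c("benzothiazole_d4", "lidocaine_d10", "chloridazon_d5",
                   "irbesartan_d4", "darunavir_d9", "propazine_d6",
                   "azoxystrobin_d4", "diazinon_d10"),
    name = c("Benzothiazole-d4", "Lidocaine-d10", "Chloridazon-d5",
             "Irbesartan-d4", "Darunavir-d9", "Propazine-d6",
             "Azoxystrobin-d4", "Diazinon-d10"),
    mz = c(124.0807, 245.2433, 227.0743, 433.2648, 557.2990, 236.1544,
           408.1492, 315.1711),
    rt = 60 * c(5.56, 5.31, 6.50, 8.87, 10.41, 11.00, 11.80, 14.10),
    polarity = "positive",
    role = "internal_standard"
  )
}

internal_standards_only <- function(specs, polarity = NULL) {
  out <- specs[specs$role == "internal_standard", , drop = FALSE]
  if (!is.null(polarity)) out <- out[out$polarity == polarity, , drop = FALSE]
  out
}
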