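#' QC method configuration
#'
#' All tunable limits and window widths of the pipeline, with defaults
#' matching long-term practice on a QTOF + reversed-phase method:
#'
#' * `eic_ppm` (20): half-width of the ion-extraction window, ppm. Wider than
#'   the mass-error limit so that out-of-limit mass errors are still measured.
#' * `mass_error_limit` (10 ppm), `rt_deviation_limit` (10 s),
#'   `intensity_limits` (0.5, 2.0): the univariate control limits, inclusive.
#' * `sn_threshold` (5) and `min_points_above` (5): peak acceptance, S/N > 5
#'   and at least 5 EIC points above baseline + 2 x noise.
#' * `rolling_window` (60 days): history window for medians and for the
#'   normal-operating-conditions (NOC) set.
#' * `apex_search_half` (13.5 s): apex search half-window (27 s extraction
#'   window); `peak_half_window` (9 s): quantification window around the apex.
#' * `noise_window_len` (15 s), `noise_pre_offset` (30 s),
#'   `noise_post_offset` (15 s): the two noise windows, one starting 30 s
#'   before the apex, one 15 s after.
#' * `blank_rt_multiplier` (3): RT tolerance multiplier for internal
#'   standards in blanks (drift beyond the sample tolerance must still be
#'   measurable there).
#' * `alpha_initial` (0.05), `n_tests` (6), `n_pcs` (3): multivariate control;
#'   Bonferroni-corrected alpha = alpha_initial / n_tests.
#' * `min_is_per_polarity` (8): minimum detected internal standards for a run
#'   to enter the NOC.
#' * `min_history` (5): minimum records before a rolling median is trusted.
#' * `min_noc` (20): minimum NOC rows before multivariate control is applied.
#' * `mspc_rule` ("and"): flag when both T2 and SPE reject in a block
#'   ("and"), or when either does ("or").
#' * `mspc_correction` ("bonferroni"): multiple-testing correction across the
#'   six tests; "none" uses alpha_initial per test.
#' * `ms2_bin_width` (0.5 Da), `ms2_fragment_tol` (0.01 Da): MS2 matching.
#' * `quiet_period` (120 s): no-modification window before a file is
#'   considered complete.
#'
#' @param ... Named overrides of the defaults above.
#' @return A named list with class `qc_config`.
#' @export
#' @examples
#' cfg <- qc_config(n_pcs = 2)
#' cfg$n_pcs
qc_config <- function(...) {
  cfg <- list(
    eic_ppm = 20,
    mass_error_limit = 10,
    rt_deviation_limit = 10,
    intensity_limits = c(0.5, 2.0),
    sn_threshold = 5,
    min_points_above = 5L,
    rolling_window = 60,
    apex_search_half = 13.5,
    peak_half_window = 9,
    noise_window_len = 15,
    noise_pre_offset = 30,
    noise_post_offset = 15,
    blank_rt_multiplier = 3,
    alpha_initial = 0.05,
    n_tests = 6L,
    n_pcs = 3L,
    min_is_per_polarity = 8L,
    min_history = 5L,
    min_noc = 20L,
    mspc_rule = "and",
    mspc_correction = "bonferroni",
    ms2_bin_width = 0.5,
    ms2_fragment_tol = 0.01,
    quiet_period = 120,
    sample_type_tokens = list(blank = "blank", standard = "standard")
  )
  over <- list(...)
  if (length(over) > 0 && is.null(names(over))) abort("overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_qc_config(cfg)
}

validate_qc_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) abort(paste0("invalid config value for '", key, "': ", msg))
  }
  lim <- cfg$intensity_limits
  chk(length(lim) == 2 && lim[1] > 0 && lim[1] < 1 && lim[2] > 1,
      "intensity_limits", "need 0 < low < 1 < high")
  chk(cfg$alpha_initial > 0 && cfg$alpha_initial < 1, "alpha_initial",
      "need 0 < alpha < 1")
  chk(cfg$n_pcs >= 1, "n_pcs", "need >= 1")
  chk(cfg$n_tests >= 1, "n_tests", "need >= 1")
  chk(cfg$eic_ppm > 0, "eic_ppm", "need > 0")
  chk(cfg$mass_error_limit > 0, "mass_error_limit", "need > 0")
  chk(cfg$rt_deviation_limit > 0, "rt_deviation_limit", "need > 0")
  chk(cfg$ms2_bin_width > 0, "ms2_bin_width", "need > 0")
  chk(cfg$ms2_fragment_tol > 0, "ms2_fragment_tol", "need > 0")
  chk(cfg$mspc_rule %in% c("and", "or"), "mspc_rule", "need 'and' or 'or'")
  chk(cfg$mspc_correction %in% c("bonferroni", "none"), "mspc_correction",
      "need 'bonferroni' or 'none'")
  for (key in c("sn_threshold", "min_points_above", "rolling_window",
                "apex_search_half", "peak_half_window", "noise_window_len",
                "noise_pre_offset", "noise_post_offset", "blank_rt_multiplier",
                "min_is_per_polarity", "min_history", "min_noc", "quiet_period")) {
    chk(is.numeric(cfg[[key]]) && length(cfg[[key]]) == 1 && cfg[[key]] > 0,
        key, "need a single positive number")
  }
  structure(cfg, class = "qc_config")
}

#' Read a QC configuration from a YAML file
#'
#' Absent keys take the [qc_config()] defaults; present keys are validated.
#' An empty file yields the full default configuration.
#'
#' @param path YAML file.
#' @return A `qc_config` object.
#' @export
load_qc_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(vals$intensity_limits)) {
    vals$intensity_limits <- as.numeric(unlist(vals$intensity_limits))
  }
  do.call(qc_config, vals)
}

#' Write a QC configuration to YAML
#'
#' `write_qc_config()` followed by [load_qc_config()] round-trips to an
#' identical configuration.
#'
#' @param cfg A `qc_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_qc_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Corrected significance level for the multivariate tests
#'
#' Bonferroni correction across the simultaneous hypothesis tests (by default
#' T2 and SPE in each of three parameter blocks, six tests): the family-wise
#' alpha is divided by the number of tests. With `correction = "none"` the
#' initial alpha is used for every test.
#'
#' @param cfg A `qc_config`.
#' @param n_tests Number of simultaneous tests; defaults to `cfg$n_tests`.
#' @return Per-test significance level.
#' @export
#' @examples
#' corrected_alpha(qc_config()) # 0.05 / 6
corrected_alpha <- function(cfg, n_tests = cfg$n_tests) {
  if (identical(cfg$mspc_correction, "none")) return(cfg$alpha_initial)
  cfg$alpha_initial / max(1L, n_tests)
}

#' Absolute half-width of a ppm mass window
#'
#' Converts a relative (ppm) tolerance at a given m/z to its absolute width.
#' At m/z 124.0807 a 10 ppm tolerance is 1.24 mDa, illustrating why relative
#' limits are tight in absolute terms for small masses.
#'
#' @param mz m/z in Da.
#' @param ppm Relative tolerance in ppm.
#' @param unit `"da"` or `"mda"`.
#' @return Absolute tolerance in the requested unit.
#' @export
#' @examples
#' ppm_window(124.0807, 10, unit = "mda") # ~1.24
ppm_window <- function(mz, ppm, unit = c("da", "mda")) {
  unit <- match.arg(unit)
  w <- mz * ppm * 1e-6
  if (unit == "mda") w * 1000 else w
}
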