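#' Extract an ion chromatogram
#'
#' One point per MS1 scan whose retention time falls in
#' `[rt_center - half_window, rt_center + half_window]` (inclusive); the
#' point's intensity is the sum of all centroid intensities within
#' `ppm` of `target_mz` (inclusive boundary), or 0 when no centroid
#' qualifies. The wide default window (20 ppm) deliberately exceeds the
#' 10 ppm mass-error limit so that out-of-limit masses are still seen.
#'
#' @param run A [qc_run()].
#' @param target_mz Theoretical m/z, Da.
#' @param ppm Relative half-window, ppm.
#' @param rt_center Centre of the RT window, seconds.
#' @param half_window RT half-window, seconds.
#' @return An object of class `qc_eic`: a list with numeric vectors `rt`,
#'   `intensity`, plus `target_mz` and `ppm`.
#' @export
extract_eic <- function(run, target_mz, ppm, rt_center, half_window) {
  if (ppm <= 0) abort("ppm must be > 0")
  ms1 <- ms1_spectra(run)
  keep <- which(ms1$rt >= rt_center - half_window &
                  ms1$rt <= rt_center + half_window)
  tol <- target_mz * ppm * 1e-6
  ints <- vapply(keep, function(i) {
    m <- ms1$mz[[i]]
    if (length(m) == 0) return(0)
    inside <- abs(m - target_mz) <= tol
    if (!any(inside)) 0 else sum(ms1$intensity[[i]][inside])
  }, numeric(1))
  structure(
    list(rt = ms1$rt[keep], intensity = as.numeric(ints),
         target_mz = target_mz, ppm = ppm, smoothed = FALSE),
    class = "qc_eic"
  )
}

eic_from_vectors <- function(rt, intensity, target_mz = NA_real_, ppm = NA_real_) {
  structure(list(rt = as.numeric(rt), intensity = as.numeric(intensity),
                 target_mz = target_mz, ppm = ppm, smoothed = FALSE),
            class = "qc_eic")
}

#' Smooth an ion chromatogram
#'
#' Two successive passes of a quadratic five-point Savitzky-Golay filter.
#' Interior points use the classical least-squares weights
#' (-3, 12, 17, 12, -3)/35; the first and last two points are smoothed with
#' the asymmetric quadratic fits over the nearest five points, so the series
#' keeps its length and any polynomial of degree <= 2 is reproduced exactly.
#' Chromatograms shorter than five points are returned unsmoothed and
#' flagged.
#'
#' @param eic A `qc_eic`.
#' @param passes Number of smoothing passes (default 2).
#' @return A `qc_eic` with smoothed intensities; attribute `smoothed`
#'   records whether smoothing was applied.
#' @export
smooth_eic <- function(eic, passes = 2) {
  y <- eic$intensity
  if (length(y) < 5) {
    eic$smoothed <- FALSE
    return(eic)
  }
  for (k in seq_len(passes)) y <- signal::sgolayfilt(y, p = 2, n = 5)
  eic$intensity <- as.numeric(y)
  eic$smoothed <- TRUE
  eic
}

#' Locate the peak apex near the expected retention time
#'
#' The apex is the maximum of the smoothed chromatogram among points within
#' `search_half` seconds of `expected_rt`. Returns `NULL` when the window is
#' empty or the maximum intensity is not positive. Ties resolve to the
#' earliest retention time.
#'
#' @param eic_smoothed A smoothed `qc_eic`.
#' @param expected_rt Expected retention time, seconds.
#' @param search_half Search half-window, seconds (default 13.5 s, i.e. the
#'   27 s extraction window).
#' @return `list(apex_rt =, apex_index =)` or `NULL`.
#' @export
find_apex <- function(eic_smoothed, expected_rt, search_half = 13.5) {
  idx <- which(abs(eic_smoothed$rt - expected_rt) <= search_half)
  if (length(idx) == 0) return(NULL)
  ints <- eic_smoothed$intensity[idx]
  if (max(ints) <= 0) return(NULL)
  best <- idx[which.max(ints)] # which.max takes the first (earliest RT) tie
  list(apex_rt = eic_smoothed$rt[best], apex_index = best)
}

#' Baseline and noise from flanking windows
#'
#' Two 15 s noise windows flank the peak: the pre-window starts 30 s before
#' the apex, `[apex - 30, apex - 15)`, and the post-window starts 15 s after,
#' `(apex + 15, apex + 30]` (half-open away from the peak). Noise within each
#' window is max - min; the smaller of the two is used, which avoids counting
#' an isobaric co-eluting peak in one flank as noise. The baseline is the
#' mean of the window that supplied the noise (the pre-window on ties).
#' A window with fewer than 2 points is excluded; if both are excluded the
#' measurement is flagged low-confidence with baseline and noise 0.
#'
#' @param eic_full An unsmoothed `qc_eic` spanning the noise windows.
#' @param apex_rt Apex retention time, seconds.
#' @param cfg A [qc_config()] supplying `noise_window_len`,
#'   `noise_pre_offset`, `noise_post_offset`.
#' @return `list(baseline =, noise =, low_confidence =)`.
#' @export
estimate_baseline_noise <- function(eic_full, apex_rt, cfg = qc_config()) {
  rt <- eic_full$rt
  y <- eic_full$intensity
  pre_lo <- apex_rt - cfg$noise_pre_offset
  pre_hi <- pre_lo + cfg$noise_window_len
  post_lo <- apex_rt + cfg$noise_post_offset
  post_hi <- post_lo + cfg$noise_window_len
  pre <- y[rt >= pre_lo & rt < pre_hi]
  post <- y[rt > post_lo & rt <= post_hi]
  win_stats <- function(v) {
    if (length(v) < 2) NULL else list(noise = max(v) - min(v), baseline = mean(v))
  }
  s_pre <- win_stats(pre)
  s_post <- win_stats(post)
  if (is.null(s_pre) && is.null(s_post)) {
    return(list(baseline = 0, noise = 0, low_confidence = TRUE))
  }
  if (is.null(s_post) || (!is.null(s_pre) && s_pre$noise <= s_post$noise)) {
    list(baseline = s_pre$baseline, noise = s_pre$noise, low_confidence = FALSE)
  } else {
    list(baseline = s_post$baseline, noise = s_post$noise, low_confidence = FALSE)
  }
}

#' Peak acceptance criteria
#'
#' A peak is accepted when both criteria hold: (i) S/N > `sn_threshold`
#' (signal = height above baseline, noise from
#' [estimate_baseline_noise()]; a zero-noise peak with positive height has
#' infinite S/N) and (ii) at least `min_points_above` raw EIC points within
#' the +/-9 s quantification window lie strictly above
#' baseline + 2 x noise.
#'
#' @param height_above_baseline Apex intensity minus baseline, counts.
#' @param baseline,noise From [estimate_baseline_noise()].
#' @param eic_peak_window Raw (unsmoothed) `qc_eic` restricted to the
#'   quantification window around the apex.
#' @param cfg A [qc_config()].
#' @return `list(accepted =, sn =, points_above =)`.
#' @export
accept_peak <- function(height_above_baseline, baseline, noise,
                        eic_peak_window, cfg = qc_config()) {
  if (noise < 0) abort("noise must be >= 0")
  sn <- if (noise == 0) {
    if (height_above_baseline > 0) Inf else 0
  } else {
    height_above_baseline / noise
  }
  points_above <- sum(eic_peak_window$intensity > baseline + 2 * noise)
  list(accepted = (sn > cfg$sn_threshold) &&
         (points_above >= cfg$min_points_above),
       sn = sn, points_above = as.integer(points_above))
}

#' Mass error at the apex
#'
#' In the apex MS1 scan and its two neighbours on each side (fewer at run
#' edges), the most intense centroid within `eic_ppm` of the target m/z is
#' taken; the measured m/z is the unweighted mean of those (up to five)
#' values, and the mass error is the signed ppm deviation from the
#' theoretical m/z (measured high gives a positive error).
#'
#' @param run A [qc_run()].
#' @param apex_rt Apex retention time, seconds.
#' @param target_mz Theoretical m/z, Da.
#' @param cfg A [qc_config()].
#' @return `list(mean_mz =, mass_error =)`; both `NA` when no scan holds a
#'   qualifying centroid.
#' @export
measure_mass_error <- function(run, apex_rt, target_mz, cfg = qc_config()) {
  ms1 <- ms1_spectra(run)
  if (nrow(ms1) == 0) return(list(mean_mz = NA_real_, mass_error = NA_real_))
  apex_i <- which.min(abs(ms1$rt - apex_rt))
  idx <- max(1L, apex_i - 2L):min(nrow(ms1), apex_i + 2L)
  tol <- target_mz * cfg$eic_ppm * 1e-6
  picked <- vapply(idx, function(i) {
    m <- ms1$mz[[i]]
    if (length(m) == 0) return(NA_real_)
    inside <- which(abs(m - target_mz) <= tol)
    if (length(inside) == 0) return(NA_real_)
    m[inside[which.max(ms1$intensity[[i]][inside])]]
  }, numeric(1))
  picked <- picked[!is.na(picked)]
  if (length(picked) == 0) return(list(mean_mz = NA_real_, mass_error = NA_real_))
  mean_mz <- mean(picked)
  list(mean_mz = mean_mz,
       mass_error = (mean_mz - target_mz) / target_mz * 1e6)
}

#' Measure one compound in one run
#'
#' Full chain for a single compound: wide EIC extraction around the
#' (drift-corrected) expected RT, double Savitzky-Golay smoothing, apex
#' search, baseline/noise estimation from the flanking windows, acceptance
#' test and apex mass error. The reported height is the smoothed apex
#' intensity minus the baseline; `detected` mirrors the acceptance decision.
#' Failures at any stage yield `detected = FALSE` with the stage recorded in
#' `reason`.
#'
#' @param run A [qc_run()].
#' @param spec One row of a [compound_list()].
#' @param corrected_rt Drift-corrected expected RT, seconds; defaults to the
#'   stored expected RT.
#' @param cfg A [qc_config()].
#' @param search_half Apex search half-window; defaults to
#'   `cfg$apex_search_half` (tripled for internal standards in blanks by the
#'   pipeline).
#' @return One-row tibble: `compound_id`, `detected`, `height`, `apex_rt`,
#'   `baseline`, `noise`, `sn`, `points_above`, `mean_mz`, `mass_error`,
#'   `reason`.
#' @export
measure_compound <- function(run, spec, corrected_rt = spec$expected_rt,
                             cfg = qc_config(),
                             search_half = cfg$apex_search_half) {
  stopifnot(nrow(spec) == 1)
  res <- tibble::tibble(
    compound_id = spec$identifier, detected = FALSE, height = NA_real_,
    apex_rt = NA_real_, baseline = NA_real_, noise = NA_real_, sn = NA_real_,
    points_above = NA_integer_, mean_mz = NA_real_, mass_error = NA_real_,
    reason = NA_character_
  )
  wide_half <- search_half + cfg$noise_pre_offset + cfg$noise_window_len
  eic <- extract_eic(run, spec$theoretical_mz, cfg$eic_ppm,
                     corrected_rt, wide_half)
  if (length(eic$rt) == 0) {
    res$reason <- "no_scans"
    return(res)
  }
  sm <- smooth_eic(eic)
  apex <- find_apex(sm, corrected_rt, search_half)
  if (is.null(apex)) {
    res$reason <- "no_apex"
    return(res)
  }
  bn <- estimate_baseline_noise(eic, apex$apex_rt, cfg)
  height <- sm$intensity[apex$apex_index] - bn$baseline
  in_peak <- abs(eic$rt - apex$apex_rt) <= cfg$peak_half_window
  acc <- accept_peak(height, bn$baseline, bn$noise,
                     eic_from_vectors(eic$rt[in_peak], eic$intensity[in_peak]),
                     cfg)
  me <- measure_mass_error(run, apex$apex_rt, spec$theoretical_mz, cfg)
  res$apex_rt <- apex$apex_rt
  res$baseline <- bn$baseline
  res$noise <- bn$noise
  res$sn <- acc$sn
  res$points_above <- acc$points_above
  res$mean_mz <- me$mean_mz
  res$mass_error <- me$mass_error
  if (!acc$accepted) {
    res$reason <- "rejected_peak"
    return(res)
  }
  res$detected <- TRUE
  res$height <- max(height, 0)
  if (is.na(me$mass_error)) res$reason <- "no_mass_measurement"
  if (bn$low_confidence) res$reason <- "low_confidence_baseline"
  res
}

#' Measure every compound of a list in one run
#'
#' @param run A [qc_run()].
#' @param specs A [compound_list()]; only compounds matching the run's
#'   polarity are measured (others are reported undetected with reason
#'   `"polarity_mismatch"`).
#' @param rt_state An [rt_correction_state()] applied to expected RTs.
#' @param cfg A [qc_config()].
#' @param search_half Apex search half-window; default per config, tripled
#'   for internal standards when the run is a blank.
#' @return Tibble with one row per compound (see [measure_compound()]).
#' @export
measure_run <- function(run, specs, rt_state = rt_correction_state(),
                        cfg = qc_config(), search_half = NULL) {
  pol <- run_polarity(run)
  corrected <- apply_rt_correction(specs, rt_state)
  purrr::list_rbind(purrr::map(seq_len(nrow(specs)), function(i) {
    spec <- specs[i, ]
    if (!is.na(pol) && spec$polarity != pol) {
      return(tibble::tibble(
        compound_id = spec$identifier, detected = FALSE, height = NA_real_,
        apex_rt = NA_real_, baseline = NA_real_, noise = NA_real_,
        sn = NA_real_, points_above = NA_integer_, mean_mz = NA_real_,
        mass_error = NA_real_, reason = "polarity_mismatch"
      ))
    }
    half <- search_half %||% (
      if (run$sample_type == "blank" && spec$role == "internal_standard") {
        cfg$apex_search_half * cfg$blank_rt_multiplier
      } else {
        cfg$apex_search_half
      })
    measure_compound(run, spec, corrected$corrected_rt[i], cfg, half)
  }))
}
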