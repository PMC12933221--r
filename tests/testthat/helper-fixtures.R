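# Shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# 100-run in-control history (rolling-median + NOC source), memoised.
nominal_history <- function(seed = 3) {
  key <- paste0("hist_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_history(100, default_internal_standards(),
                                         qc_config(), seed = seed)
  }
  .fixtures[[key]]
}

history_end <- as.POSIXct("2024-06-01 00:00:00", tz = "UTC")

# Minimal run built from explicit MS1 scans: `scans` is a list of
# list(rt =, mz =, intensity =).
make_run <- function(scans, sample_type = "sample", polarity = "positive",
                     acquired_at = history_end) {
  spectra <- tibble::tibble(
    ms_level = 1L,
    rt = vapply(scans, function(s) s$rt, numeric(1)),
    polarity = polarity,
    precursor_mz = NA_real_,
    acquisition_mode = "none",
    mz = lapply(scans, function(s) as.numeric(s$mz)),
    intensity = lapply(scans, function(s) as.numeric(s$intensity))
  )
  qc_run(spectra, path = "synthetic://fixture", acquired_at = acquired_at,
         sample_type = sample_type)
}

# A run whose single m/z channel holds a given EIC trace.
make_eic_run <- function(rt, intensity, mz = 300) {
  make_run(purrr::map2(rt, intensity, function(t, i) {
    list(rt = t, mz = mz, intensity = i)
  }))
}

# Plain history tibble with n detected records per compound, one per day,
# ending just before `at`.
flat_history <- function(compounds, heights, rts, at = history_end, n = 10,
                         mass_error = 0, sample_type = "sample") {
  purrr::list_rbind(purrr::map(seq_len(n), function(i) {
    tibble::tibble(
      run_id = sprintf("h%02d", i), at = at - i * 86400,
      sample_type = sample_type, pass = TRUE, out_of_control = NA,
      compound_id = compounds, detected = TRUE, height = heights,
      apex_rt = rts, mass_error = mass_error
    )
  }))
}

# Measurement tibble from per-compound vectors (NA height => undetected).
make_measurements <- function(compounds, height, apex_rt, mass_error = 0) {
  tibble::tibble(
    compound_id = compounds, detected = !is.na(height),
    height = height, apex_rt = apex_rt, baseline = 0, noise = 1,
    sn = height, points_above = 30L,
    mean_mz = NA_real_, mass_error = mass_error,
    reason = NA_character_
  )
}
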