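#' Scenario configuration for the batch simulator
#'
#' The simulator produces multi-injection batches with the statistical
#' structure the QC assumes — Gaussian chromatographic peaks on a white
#' baseline, lognormal run-to-run intensity variation with a component shared
#' across standards (detector gain), small RT jitter, and a QTOF-like mass
#' error made of a per-run bias common to all standards plus per-scan
#' centroid jitter — and can inject instrument faults:
#'
#' * `nominal`: no fault.
#' * `hv_failure`: high-voltage supply degradation; standards above a pivot
#'   m/z are attenuated (log-m/z interpolation down to `attenuation_max` at
#'   the highest mass), standards at or below it gain `boost_low`.
#' * `pump_drift`: failing organic-phase pump; retention times drift late
#'   across the batch, up to `max_shift` seconds for the earliest eluter at
#'   the last injection, late eluters affected less (`late_factor`).
#' * `ac_mass_bias`: air-conditioning outage; per-standard positive mass-error
#'   shifts (`shift_ppm`, recycled over the standards) too small to breach
#'   the univariate ppm limit.
#' * `post_maintenance_gain`: uniform intensity gain (`gain`) after detector
#'   maintenance; pairwise ratios are unchanged by construction.
#'
#' @param name Scenario name (above).
#' @param n_injections Number of injections (default 25, a typical batch).
#' @param injection_interval Minutes between injections (default 30).
#' @param seed Integer seed; identical configs generate identical batches.
#' @param start_time Timestamp of the first injection.
#' @param parameters Named list of scenario/physics overrides (see
#'   `scenario_defaults()` in the source for the full set).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(name = c("nominal", "hv_failure", "pump_drift",
                                     "ac_mass_bias", "post_maintenance_gain"),
                            n_injections = 25, injection_interval = 30,
                            seed = 1, start_time = as.POSIXct("2024-06-01 08:00:00", tz = "UTC"),
                            parameters = list()) {
  name <- match.arg(name)
  if (n_injections < 1) abort("n_injections must be >= 1")
  p <- scenario_defaults()
  unknown <- setdiff(names(parameters), names(p))
  if (length(unknown) > 0) {
    abort(paste0("unknown scenario parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p[names(parameters)] <- parameters
  structure(list(name = name, n_injections = as.integer(n_injections),
                 injection_interval = injection_interval,
                 seed = as.integer(seed), start_time = start_time,
                 parameters = p),
            class = "scenario_config")
}

scenario_defaults <- function() {
  list(
    # signal physics
    scan_interval = 0.5,      # s between MS1 scans
    peak_sd = 3,              # s, chromatographic peak width
    base_height = 1e5,        # counts at the apex
    baseline_noise_sd = 200,  # counts, white noise on each EIC channel
    run_gain_sdlog = 0.08,    # lognormal run-to-run gain shared by all IS
    is_gain_sdlog = 0.05,     # lognormal per-IS run-to-run variation
    rt_jitter_sd = 1,         # s per IS per run
    mz_jitter_ppm = 0.3,      # per-scan centroid jitter
    run_bias_ppm_sd = 0.15,   # per-run mass bias common to all IS
    # faults
    pivot_mz = 236.1544, attenuation_max = 0.3, boost_low = 1.5,
    max_shift = 30, late_factor = 0.5,
    shift_ppm = c(0.3, 1.3),
    gain = 2.5,
    # MS2 for targets
    dda_targets = character(), ms2_n_fragments = 5L
  )
}

run_seed <- function(scenario, injection_index) {
  (abs(scenario$seed) %% 1000000L) * 2000L + injection_index %% 2000L
}

# Per-compound ground truth for one injection: apex height (counts above
# baseline), apex RT (s) and mass bias (ppm) before measurement noise.
scenario_truth <- function(scenario, injection_index, compounds) {
  p <- scenario$parameters
  n <- scenario$n_injections
  height <- rep(p$base_height, nrow(compounds))
  rt <- compounds$expected_rt
  bias <- rep(0, nrow(compounds))
  if (scenario$name == "hv_failure") {
    mz <- compounds$theoretical_mz
    hi <- mz > p$pivot_mz
    mz_top <- max(mz)
    f <- ifelse(hi,
                exp(log(p$attenuation_max) *
                      (log(mz) - log(p$pivot_mz)) /
                      (log(mz_top) - log(p$pivot_mz))),
                p$boost_low)
    height <- height * f
  } else if (scenario$name == "pump_drift") {
    rt_min <- min(compounds$expected_rt)
    rt_max <- max(compounds$expected_rt)
    g <- 1 - p$late_factor * (compounds$expected_rt - rt_min) /
      max(rt_max - rt_min, 1)
    rt <- rt + (injection_index / n) * p$max_shift * g
  } else if (scenario$name == "ac_mass_bias") {
    bias <- rep_len(p$shift_ppm, nrow(compounds))
  } else if (scenario$name == "post_maintenance_gain") {
    height <- height * p$gain
  }
  tibble::tibble(identifier = compounds$identifier, height = height,
                 rt = rt, bias_ppm = bias)
}

#' Simulate one injection
#'
#' Generates a full scan stream: MS1 scans at a fixed interval covering all
#' expected peaks plus the flanking noise windows, one centroid per compound
#' channel per scan (Gaussian peak + truncated white noise, with per-scan
#' ppm jitter on the centroid mass), and DDA MS2 events near the apex for
#' compounds listed in `parameters$dda_targets`. The random stream is seeded
#' from `(seed, injection_index)`, so batches are reproducible and
#' order-independent.
#'
#' @param scenario A [scenario_config()].
#' @param injection_index 1-based injection number within the batch.
#' @param compounds A [compound_list()].
#' @param sample_type Sample type of the generated run.
#' @return A [qc_run()].
#' @export
simulate_run <- function(scenario, injection_index,
                         compounds = default_internal_standards(),
                         sample_type = "sample") {
  p <- scenario$parameters
  truth <- scenario_truth(scenario, injection_index, compounds)
  run <- withr::with_seed(run_seed(scenario, injection_index), {
    n_c <- nrow(compounds)
    run_gain <- exp(rnorm(1, 0, p$run_gain_sdlog))
    is_gain <- exp(rnorm(n_c, 0, p$is_gain_sdlog))
    rt_jit <- rnorm(n_c, 0, p$rt_jitter_sd)
    run_bias <- rnorm(1, 0, p$run_bias_ppm_sd)

    apex_height <- truth$height * run_gain * is_gain
    apex_rt <- truth$rt + rt_jit
    bias_ppm <- truth$bias_ppm + run_bias

    rt_grid <- seq(0, max(compounds$expected_rt) + 60, by = p$scan_interval)
    n_s <- length(rt_grid)
    # scans x compounds intensity matrix: Gaussian peak + white noise
    signal <- vapply(seq_len(n_c), function(c) {
      apex_height[c] * exp(-(rt_grid - apex_rt[c])^2 / (2 * p$peak_sd^2))
    }, numeric(n_s))
    signal <- pmax(signal + matrix(rnorm(n_s * n_c, 0, p$baseline_noise_sd),
                                   n_s, n_c), 0)
    jitter <- matrix(rnorm(n_s * n_c, 0, p$mz_jitter_ppm), n_s, n_c)
    mz_mat <- matrix(rep(compounds$theoretical_mz, each = n_s), n_s, n_c) *
      (1 + (bias_ppm[col(jitter)] + jitter) * 1e-6)

    spectra <- tibble::tibble(
      ms_level = 1L, rt = rt_grid, polarity = compounds$polarity[1],
      precursor_mz = NA_real_, acquisition_mode = "none",
      mz = lapply(asplit(mz_mat, 1), as.numeric),
      intensity = lapply(asplit(signal, 1), as.numeric)
    )
    # order centroids by m/z within each scan
    ord <- order(compounds$theoretical_mz)
    spectra$mz <- lapply(spectra$mz, function(m) m[ord])
    spectra$intensity <- lapply(spectra$intensity, function(v) v[ord])

    dda_ids <- intersect(p$dda_targets, compounds$identifier)
    if (length(dda_ids) > 0) {
      ms2 <- purrr::list_rbind(purrr::map(dda_ids, function(id) {
        ci <- match(id, compounds$identifier)
        frags <- synthetic_fragments(compounds$theoretical_mz[ci],
                                     p$ms2_n_fragments)
        tibble::tibble(
          ms_level = 2L, rt = apex_rt[ci] + c(-2, 0, 2),
          polarity = compounds$polarity[ci],
          precursor_mz = compounds$theoretical_mz[ci] * (1 + bias_ppm[ci] * 1e-6),
          acquisition_mode = "DDA",
          mz = rep(list(frags$mz), 3),
          intensity = rep(list(frags$intensity), 3)
        )
      }))
      spectra <- dplyr::arrange(dplyr::bind_rows(spectra, ms2), .data$rt)
    }
    spectra
  })
  qc_run(
    run,
    path = sprintf("synthetic://%s_s%d_%03d_%s", scenario$name, scenario$seed,
                   injection_index, sample_type),
    acquired_at = scenario$start_time +
      (injection_index - 1) * scenario$injection_interval * 60,
    sample_type = sample_type,
    batch_id = paste0(scenario$name, "_", scenario$seed)
  )
}

# Deterministic pseudo-fragment spectrum for a precursor: fixed fractional
# masses and intensity pattern so library and acquired spectra agree.
synthetic_fragments <- function(precursor_mz, n = 5L) {
  frac <- seq(0.3, 0.9, length.out = n)
  tibble::tibble(
    mz = round(precursor_mz * frac, 4),
    intensity = round(1000 * (0.4 + 0.6 * sin(seq_len(n))^2), 1)
  )
}

#' Simulate a batch of injections
#'
#' Runs carry ascending timestamps `injection_interval` minutes apart;
#' optionally the first injection is a blank (internal standards only, no
#' fault applied to it beyond the scenario's per-injection model). Returns
#' the runs together with ground-truth labels recording which fault applies
#' to each run.
#'
#' @param scenario A [scenario_config()].
#' @param compounds A [compound_list()].
#' @param blank_first Make injection 1 a blank (default `FALSE`).
#' @return List with `runs` (list of [qc_run()]) and `labels` (tibble:
#'   `run_id`, `injection`, `sample_type`, `fault`).
#' @export
simulate_batch <- function(scenario, compounds = default_internal_standards(),
                           blank_first = FALSE) {
  runs <- purrr::map(seq_len(scenario$n_injections), function(i) {
    st <- if (blank_first && i == 1) "blank" else "sample"
    simulate_run(scenario, i, compounds, sample_type = st)
  })
  labels <- tibble::tibble(
    run_id = vapply(runs, function(r) r$path, character(1)),
    injection = seq_len(scenario$n_injections),
    sample_type = vapply(runs, function(r) r$sample_type, character(1)),
    fault = ifelse(scenario$name == "nominal", "none", scenario$name)
  )
  list(runs = runs, labels = labels)
}

#' Simulate an in-control measurement history
#'
#' Fast path for populating the rolling-median history and the NOC: draws
#' per-run internal-standard measurements from the same statistical model as
#' [simulate_run()] (shared + per-standard lognormal gain, RT jitter, common
#' per-run mass bias plus averaged centroid jitter) without synthesising raw
#' scans, evaluates each run with [evaluate_run()] against the accumulating
#' history, and appends it. Runs are spaced so that `n_runs` fit inside the
#' rolling window ending at `end_time`.
#'
#' @param n_runs Number of historical runs (default 100).
#' @param specs A [compound_list()].
#' @param cfg A [qc_config()].
#' @param seed Integer seed.
#' @param end_time Timestamp just after the last historical run.
#' @param scenario_name Scenario applied to the historical runs (default
#'   `"nominal"`).
#' @return List with `history` (a `qc_history`) and `verdicts` (list of
#'   `qc_verdict`).
#' @export
simulate_history <- function(n_runs = 100,
                             specs = default_internal_standards(),
                             cfg = qc_config(), seed = 1,
                             end_time = as.POSIXct("2024-06-01 00:00:00", tz = "UTC"),
                             scenario_name = "nominal") {
  scenario <- scenario_config(scenario_name, n_injections = n_runs, seed = seed)
  span <- (cfg$rolling_window * 86400) * 0.9
  times <- end_time - span + (seq_len(n_runs) - 1) * span / n_runs
  history <- new_history()
  verdicts <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    m <- simulate_measurements(scenario, i, specs)
    v <- evaluate_run(m, history, cfg, at = times[i],
                      run_id = sprintf("hist_%03d", i),
                      sample_type = "sample", specs = specs)
    history <- update_history(history, v, m, specs)
    verdicts[[i]] <- v
  }
  list(history = history, verdicts = verdicts)
}

#' Measurement-level equivalent of [simulate_run()] + [measure_run()]
#'
#' Same per-run random draws (identical seed stream) as the raw-signal
#' simulator, with the per-scan centroid jitter replaced by its five-scan
#' average, and detection determined by whether the shifted apex still lies
#' inside the apex search window.
#'
#' @inheritParams simulate_run
#' @param cfg A [qc_config()] (supplies the apex search window).
#' @return A measurement tibble as from [measure_run()].
#' @export
simulate_measurements <- function(scenario, injection_index,
                                  compounds = default_internal_standards(),
                                  cfg = qc_config()) {
  p <- scenario$parameters
  truth <- scenario_truth(scenario, injection_index, compounds)
  withr::with_seed(run_seed(scenario, injection_index), {
    n_c <- nrow(compounds)
    run_gain <- exp(rnorm(1, 0, p$run_gain_sdlog))
    is_gain <- exp(rnorm(n_c, 0, p$is_gain_sdlog))
    rt_jit <- rnorm(n_c, 0, p$rt_jitter_sd)
    run_bias <- rnorm(1, 0, p$run_bias_ppm_sd)
    height <- truth$height * run_gain * is_gain
    apex_rt <- truth$rt + rt_jit
    mass_error <- truth$bias_ppm + run_bias +
      rnorm(n_c, 0, p$mz_jitter_ppm / sqrt(5))
    detected <- abs(apex_rt - compounds$expected_rt) <= cfg$apex_search_half
    tibble::tibble(
      compound_id = compounds$identifier,
      detected = detected,
      height = ifelse(detected, height, NA_real_),
      apex_rt = ifelse(detected, apex_rt, NA_real_),
      baseline = 0, noise = p$baseline_noise_sd,
      sn = ifelse(detected, height / p$baseline_noise_sd, NA_real_),
      points_above = ifelse(detected, 30L, NA_integer_),
      mean_mz = ifelse(detected,
                       compounds$theoretical_mz * (1 + mass_error * 1e-6),
                       NA_real_),
      mass_error = ifelse(detected, mass_error, NA_real_),
      reason = ifelse(detected, NA_character_, "no_apex")
    )
  })
}
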