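specs8 <- default_internal_standards()

test_that("rolling medians respect the half-open window and minimum history", {
  at <- history_end
  h <- tibble::tibble(
    run_id = paste0("r", 1:7), at = at - c(1:5, 60, 70) * 86400,
    sample_type = "sample", pass = TRUE, out_of_control = NA,
    compound_id = "x", detected = TRUE,
    height = c(80, 100, 120, 90, 110, 1e6, 1e6),
    apex_rt = c(100, 101, 102, 99, 98, 500, 500), mass_error = 0
  )
  # records at exactly 60 d and older are excluded (half-open window)
  expect_equal(rolling_median(h, "x", at, "height"), 100)
  expect_equal(rolling_median(h, "x", at, "rt"), 100)
  # at the evaluation timestamp itself: excluded
  h2 <- h[1:5, ]
  h2$at <- at
  expect_true(is.na(rolling_median(h2, "x", at, "height")))
  # below the minimum history -> NA
  expect_true(is.na(rolling_median(h[1:3, ], "x", at, "height")))
  expect_equal(rolling_median(h[1:3, ], "x", at, "height", min_records = 3), 100)
})

test_that("height medians pool sample runs only; RT medians use all types", {
  at <- history_end
  blank_h <- flat_history("x", heights = 50, rts = 200, at = at, n = 6,
                          sample_type = "blank")
  expect_true(is.na(rolling_median(blank_h, "x", at, "height")))
  expect_equal(rolling_median(blank_h, "x", at, "rt"), 200)
})

test_that("verdicts categorise breaches the way longitudinal counts expect", {
  cfg <- qc_config()
  at <- history_end
  h <- flat_history(rep(specs8$identifier, 1), heights = rep(1000, 8),
                    rts = specs8$expected_rt, at = at, n = 10)

  nominal <- make_measurements(specs8$identifier, rep(1000, 8),
                               specs8$expected_rt)
  v0 <- evaluate_run(nominal, h, cfg, at, "r0", specs = specs8)
  expect_true(v0$pass)
  expect_equal(v0$category, "pass")

  # one standard at 0.4x its median -> height category
  low <- make_measurements(specs8$identifier, c(400, rep(1000, 7)),
                           specs8$expected_rt)
  v1 <- evaluate_run(low, h, cfg, at, "r1", specs = specs8)
  expect_false(v1$pass)
  expect_equal(v1$category, "height")
  expect_equal(
    v1$standards$normalised_intensity[v1$standards$compound_id == specs8$identifier[1]],
    0.4)

  # +11 s RT deviation and 12 ppm on the same standard -> multiple
  multi <- make_measurements(specs8$identifier, rep(1000, 8),
                             specs8$expected_rt + c(11, rep(0, 7)),
                             mass_error = c(12, rep(0, 7)))
  v2 <- evaluate_run(multi, h, cfg, at, "r2", specs = specs8)
  expect_equal(v2$category, "multiple")
  expect_setequal(v2$reasons, c("retention_time", "mass_error"))

  # an undetected standard dominates the category
  miss <- make_measurements(specs8$identifier,
                            c(NA, 400, rep(1000, 6)),
                            c(NA, specs8$expected_rt[-1]))
  v3 <- evaluate_run(miss, h, cfg, at, "r3", specs = specs8)
  expect_equal(v3$category, "missing_is")
  expect_true("missing_is" %in% v3$reasons)
})

test_that("limits are inclusive: values exactly at a limit pass", {
  cfg <- qc_config()
  at <- history_end
  h <- flat_history(specs8$identifier, rep(1000, 8), specs8$expected_rt,
                    at = at, n = 10)
  edge <- make_measurements(
    specs8$identifier,
    height = c(500, 2000, rep(1000, 6)),        # exactly 0.5x and 2.0x
    apex_rt = specs8$expected_rt + c(0, 0, 10, -10, rep(0, 4)), # exactly 10 s
    mass_error = c(0, 0, 0, 0, 10, -10, 0, 0)   # exactly 10 ppm
  )
  v <- evaluate_run(edge, h, cfg, at, "edge", specs = specs8)
  expect_true(v$pass)
  # one hair beyond each limit fails
  over <- make_measurements(
    specs8$identifier,
    height = c(499.9, rep(1000, 7)),
    apex_rt = specs8$expected_rt, mass_error = 0)
  expect_false(evaluate_run(over, h, cfg, at, "over", specs = specs8)$pass)
})

test_that("checks without sufficient history are skipped, not failed", {
  cfg <- qc_config()
  m <- make_measurements(specs8$identifier, rep(1000, 8), specs8$expected_rt)
  v <- evaluate_run(m, new_history(), cfg, history_end, "first", specs = specs8)
  expect_true(v$pass)
  expect_true(all(c("height", "retention_time") %in% v$skipped_checks))
  expect_true(all(is.na(v$standards$normalised_intensity)))
})

test_that("verdicts are deterministic given history and measurements", {
  cfg <- qc_config()
  h <- flat_history(specs8$identifier, rep(1000, 8), specs8$expected_rt, n = 10)
  m <- make_measurements(specs8$identifier, c(400, rep(1000, 7)),
                         specs8$expected_rt)
  v1 <- evaluate_run(m, h, cfg, history_end, "r", specs = specs8)
  v2 <- evaluate_run(m, h, cfg, history_end, "r", specs = specs8)
  expect_identical(glance(v1), glance(v2))
  expect_identical(tidy(v1), tidy(v2))
})

test_that("category counts satisfy the flag-accounting identity", {
  # mixed campaign: nominal, height fault, drift, mass fault
  cfg <- qc_config()
  hist <- nominal_history()$history
  verdicts <- list()
  t <- history_end
  for (nm in c("nominal", "hv_failure", "pump_drift")) {
    sc <- scenario_config(nm, n_injections = 10, seed = 21, start_time = t)
    for (i in 1:10) {
      m <- simulate_measurements(sc, i, specs8)
      v <- evaluate_run(m, hist, cfg, at = sc$start_time + i * 1800,
                        run_id = paste0(nm, i), specs = specs8)
      verdicts[[length(verdicts) + 1]] <- v
    }
    t <- t + 10 * 1800
  }
  counts <- count_verdicts(verdicts)
  expect_equal(counts$flagged, counts$missing_is + counts$flagged_excl_missing)
  expect_equal(counts$flagged_excl_missing,
               counts$height + counts$retention_time + counts$mass_error +
                 counts$multiple)
  expect_equal(counts$total, 30)
})

test_that("history updates append standards and track the multivariate flag", {
  cfg <- qc_config()
  h <- new_history()
  m <- make_measurements(specs8$identifier, rep(1000, 8), specs8$expected_rt)
  v <- evaluate_run(m, h, cfg, history_end, "r1", specs = specs8)
  h <- update_history(h, v, m, specs8)
  expect_equal(nrow(h), 8)
  expect_true(all(is.na(h$out_of_control)))

  miss <- make_measurements(specs8$identifier, c(NA, rep(1000, 7)),
                            c(NA, specs8$expected_rt[-1]))
  v2 <- evaluate_run(miss, h, cfg, history_end + 60, "r2", specs = specs8)
  h <- update_history(h, v2, miss, specs8)
  expect_equal(sum(!h$detected), 1) # undetected standards recorded as such
})
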