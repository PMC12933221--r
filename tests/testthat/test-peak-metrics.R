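# Independent oracle: least-squares quadratic fit over each 5-point window,
# evaluated at the window centre (asymmetric at the edges).
sg_quadratic_oracle <- function(y) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- min(max(i, 3), n - 2) # centre of the nearest interior window
    idx <- (w - 2):(w + 2)
    d <- data.frame(x = idx - i, y = y[idx])
    fit <- stats::lm(y ~ x + I(x^2), data = d)
    out[i] <- unname(stats::predict(fit, data.frame(x = 0)))
  }
  out
}

test_that("the smoother matches the least-squares quadratic oracle", {
  set.seed(42)
  for (rep in 1:5) {
    y <- rnorm(20, 100, 30)
    eic <- isqc:::eic_from_vectors(seq_along(y), y)
    one_pass <- smooth_eic(eic, passes = 1)
    expect_equal(one_pass$intensity, sg_quadratic_oracle(y), tolerance = 1e-9)
    two_pass <- smooth_eic(eic, passes = 2)
    expect_equal(two_pass$intensity, sg_quadratic_oracle(sg_quadratic_oracle(y)),
                 tolerance = 1e-9)
  }
  # classic interior weights: unit impulse -> (-3,12,17,12,-3)/35
  imp <- smooth_eic(isqc:::eic_from_vectors(1:9, c(0, 0, 0, 0, 35, 0, 0, 0, 0)),
                    passes = 1)
  expect_equal(imp$intensity[3:7], c(-3, 12, 17, 12, -3))
})

test_that("the smoother reproduces polynomials of degree <= 2 and keeps length", {
  x <- 1:15
  for (y in list(rep(7, 15), 2 * x + 1, 0.5 * x^2 - 3 * x + 4)) {
    sm <- smooth_eic(isqc:::eic_from_vectors(x, y))
    expect_equal(sm$intensity, as.numeric(y), tolerance = 1e-9)
    expect_length(sm$intensity, length(y))
  }
  # shorter than the window: returned unsmoothed, flagged
  short <- smooth_eic(isqc:::eic_from_vectors(1:4, c(1, 9, 2, 8)))
  expect_false(short$smoothed)
  expect_equal(short$intensity, c(1, 9, 2, 8))
})

test_that("EIC extraction uses inclusive ppm and RT boundaries", {
  target <- 124.0807
  at_edge <- target * (1 + 20e-6)
  beyond <- target * (1 + 20.5e-6)
  run <- make_run(list(
    list(rt = 10, mz = c(at_edge, beyond), intensity = c(5, 100)),
    list(rt = 20, mz = target, intensity = c(7)),
    list(rt = 30.0001, mz = target, intensity = c(9))
  ))
  eic <- extract_eic(run, target, 20, rt_center = 20, half_window = 10)
  expect_equal(eic$rt, c(10, 20))         # 30.0001 outside inclusive window
  expect_equal(eic$intensity, c(5, 7))    # 20.5 ppm centroid excluded
})

test_that("EIC extraction sums in-window centroids and yields zeros otherwise", {
  run <- make_run(list(
    list(rt = 1, mz = c(299.999, 300.001), intensity = c(10, 20)),
    list(rt = 2, mz = 500, intensity = 50),
    list(rt = 3, mz = numeric(0), intensity = numeric(0))
  ))
  eic <- extract_eic(run, 300, 20, rt_center = 2, half_window = 5)
  expect_equal(eic$intensity, c(30, 0, 0))
  expect_length(eic$rt, 3)
})

test_that("apex search respects the window, positivity and the tie-break", {
  eic <- isqc:::eic_from_vectors(1:11, c(0, 1, 3, 9, 3, 1, 0, 9, 2, 1, 0))
  # both maxima equal 9; earlier RT wins
  apex <- find_apex(eic, expected_rt = 6, search_half = 5)
  expect_equal(apex$apex_rt, 4)
  # restrict window to the later peak
  apex2 <- find_apex(eic, expected_rt = 9, search_half = 1.5)
  expect_equal(apex2$apex_rt, 8)
  expect_null(find_apex(isqc:::eic_from_vectors(1:5, rep(0, 5)), 3, 5))
  expect_null(find_apex(isqc:::eic_from_vectors(numeric(0), numeric(0)), 3, 5))
})

test_that("baseline and noise follow the lower-noise flanking window", {
  # pre-window [apex-30, apex-15): values 10,12,11,10 -> noise 2
  # post-window (apex+15, apex+30]: values 50,10,55,12 -> noise 45
  apex <- 100
  rt <- c(72, 76, 80, 84, 100, 118, 122, 126, 130)
  y <- c(10, 12, 11, 10, 999, 50, 10, 55, 12)
  bn <- estimate_baseline_noise(isqc:::eic_from_vectors(rt, y), apex)
  expect_equal(bn$noise, 2)
  expect_equal(bn$baseline, 10.75)
  expect_false(bn$low_confidence)

  # both windows constant 5 -> noise 0, baseline 5
  y2 <- c(5, 5, 5, 5, 999, 5, 5, 5, 5)
  bn2 <- estimate_baseline_noise(isqc:::eic_from_vectors(rt, y2), apex)
  expect_equal(bn2$noise, 0)
  expect_equal(bn2$baseline, 5)

  # co-eluting peak contaminating only the post-window -> pre-window used
  y3 <- c(10, 12, 11, 10, 999, 400, 800, 600, 300)
  bn3 <- estimate_baseline_noise(isqc:::eic_from_vectors(rt, y3), apex)
  expect_equal(bn3$baseline, 10.75)

  # a window with < 2 points is excluded; both excluded -> flagged
  bn4 <- estimate_baseline_noise(isqc:::eic_from_vectors(c(84, 100), c(10, 999)), apex)
  expect_equal(bn4$noise, 0)
  expect_true(bn4$low_confidence)
})

test_that("peak acceptance applies both criteria with the zero-noise convention", {
  cfg <- qc_config()
  win7 <- isqc:::eic_from_vectors(1:7, rep(200, 7)) # 7 points above anything small
  a <- accept_peak(100, baseline = 0, noise = 10, win7, cfg)
  expect_true(a$accepted); expect_equal(a$sn, 10); expect_equal(a$points_above, 7L)

  b <- accept_peak(40, 0, 10, win7, cfg) # S/N 4 fails criterion (i)
  expect_false(b$accepted)

  win4 <- isqc:::eic_from_vectors(1:4, rep(200, 4)) # only 4 points above
  c <- accept_peak(100, 0, 10, win4, cfg)
  expect_false(c$accepted); expect_equal(c$points_above, 4L)

  d <- accept_peak(100, 0, 0, win7, cfg) # zero noise -> infinite S/N
  expect_true(d$accepted); expect_identical(d$sn, Inf)
})

test_that("acceptance is monotone in peak height", {
  cfg <- qc_config()
  win <- isqc:::eic_from_vectors(1:9, rep(500, 9))
  accepted <- vapply(seq(10, 500, by = 10), function(h) {
    accept_peak(h, baseline = 0, noise = 8, win, cfg)$accepted
  }, logical(1))
  expect_false(any(diff(accepted) < 0)) # never flips accepted -> rejected
})

test_that("mass error is the signed ppm deviation of the five-scan mean m/z", {
  target <- 124.0807
  five_scan_run <- function(mz) {
    make_run(purrr::map(1:5, function(i) list(rt = i, mz = mz, intensity = 100)))
  }
  r <- measure_mass_error(five_scan_run(124.08194), apex_rt = 3, target)
  expect_equal(r$mass_error, 10, tolerance = 0.005) # |err - 10| < 0.05 ppm
  expect_equal(measure_mass_error(five_scan_run(target), 3, target)$mass_error, 0)
  expect_equal(
    measure_mass_error(five_scan_run(target * (1 - 5e-6)), 3, target)$mass_error,
    -5, tolerance = 1e-6)
  # no qualifying centroid anywhere -> undefined
  none <- measure_mass_error(five_scan_run(200), 3, target)
  expect_true(is.na(none$mass_error))
})

test_that("mass-error sign convention holds across random offsets", {
  target <- 315.1711
  set.seed(7)
  for (e in runif(10, -15, 15)) {
    run <- make_run(purrr::map(1:5, function(i) {
      list(rt = i, mz = target * (1 + e * 1e-6), intensity = 50)
    }))
    got <- measure_mass_error(run, 3, target)$mass_error
    expect_equal(got, e, tolerance = 1e-6)
  }
  # most intense centroid per scan wins
  run2 <- make_run(list(list(rt = 1, mz = c(target, target * (1 + 8e-6)),
                             intensity = c(10, 1000))))
  expect_equal(measure_mass_error(run2, 1, target)$mass_error, 8,
               tolerance = 1e-6)
})

test_that("measure_compound detects all standards in a nominal injection", {
  specs <- default_internal_standards()
  run <- simulate_run(scenario_config("nominal", seed = 5), 1, specs)
  m <- measure_run(run, specs)
  expect_true(all(m$detected))
  expect_true(all(m$height > 0))
  expect_true(all(abs(m$apex_rt - specs$expected_rt) < 13.5))
  expect_true(all(abs(m$mass_error) < 2, na.rm = TRUE))
  expect_equal(m$compound_id, specs$identifier)
  # reported height is the smoothed apex minus baseline, hence >= 0
  expect_true(all(m$height >= 0))
})

test_that("a peak shifted beyond the extraction window is reported missing", {
  specs <- default_internal_standards()
  # last injection of a pump-drift batch: earliest eluter shifted ~30 s
  run <- simulate_run(scenario_config("pump_drift", seed = 5), 25, specs)
  m <- measure_run(run, specs)
  lid <- m[m$compound_id == "lidocaine_d10", ]
  expect_false(lid$detected)
})

test_that("an empty run yields all compounds undetected", {
  empty <- qc_run(tibble::tibble(
    ms_level = integer(), rt = numeric(), polarity = character(),
    precursor_mz = numeric(), acquisition_mode = character(),
    mz = list(), intensity = list()
  ), path = "synthetic://empty")
  m <- measure_run(empty, default_internal_standards())
  expect_equal(nrow(m), 8)
  expect_false(any(m$detected))
})
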