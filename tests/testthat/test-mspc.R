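specs8 <- default_internal_standards()

test_that("pairwise ratios follow the shared-denominator definition", {
  expect_equal(unname(pairwise_ratios(c(a = 100, b = 300))), 0.25)
  expect_equal(unname(pairwise_ratios(c(a = 5, b = 5))), 0.5)
  expect_equal(unname(pairwise_ratios(c(a = 0, b = 0))), 0)
  expect_equal(names(pairwise_ratios(c(a = 1, b = 2, c = 3))),
               c("a/b", "a/c", "b/c"))
  # 8 standards -> 28 unordered pairs
  v <- setNames(runif(8, 1, 2), specs8$identifier)
  expect_length(pairwise_ratios(v), 28)
  # complementary orientation sums to one
  r_ab <- pairwise_ratios(c(a = 7, b = 3))[["a/b"]]
  r_ba <- pairwise_ratios(c(b = 3, a = 7))[["b/a"]]
  expect_equal(r_ab + r_ba, 1)
})

test_that("ratio features are invariant to a common gain", {
  m <- make_measurements(specs8$identifier, runif(8, 5e4, 2e5),
                         specs8$expected_rt)
  m_gain <- dplyr::mutate(m, height = .data$height * 2.5)
  expect_equal(block_sample_features(m, "height", specs8),
               block_sample_features(m_gain, "height", specs8))
})

random_noc <- function(n = 30, p = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p) %*% matrix(runif(p * p, -1, 1), p, p)
    colnames(X) <- paste0("f", seq_len(p))
    X
  })
}

test_that("block models are orthonormal, ordered and correctly autoscaled", {
  X <- random_noc(40, 8)
  model <- fit_block_model(X, qc_config(), block = "height")
  P <- model$loadings
  expect_equal(unname(t(P) %*% P), diag(ncol(P)), tolerance = 1e-8)
  expect_true(all(diff(model$score_variances) <= 1e-12))
  expect_gt(model$explained_variance, 0)
  expect_lte(model$explained_variance, 1)
  # autoscaled NOC columns: mean 0, sd 1
  Xs <- scale(X, model$center, model$scale)
  expect_lt(max(abs(colMeans(Xs))), 1e-8)
  expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-6)
  # explained variance is non-decreasing in the number of components
  ev <- vapply(1:4, function(k) {
    fit_block_model(X, qc_config(n_pcs = k))$explained_variance
  }, numeric(1))
  expect_true(all(diff(ev) >= -1e-12))
})

test_that("the corrected alpha and the asymptotic T2 limit behave as expected", {
  model <- fit_block_model(random_noc(), qc_config())
  expect_equal(round(model$alpha, 5), 0.00833)
  # for large n the F-based limit approaches the chi-square quantile
  big <- fit_block_model(random_noc(20000, 6, seed = 2), qc_config())
  expect_equal(big$t2_limit, qchisq(1 - big$alpha, 3), tolerance = 0.01)
})

test_that("T2 equals the brute-force Mahalanobis distance in score space", {
  cfg <- qc_config()
  set.seed(11)
  for (i in 1:50) {
    n <- sample(25:60, 1); p <- sample(4:9, 1)
    X <- matrix(rnorm(n * p), n, p) %*% matrix(runif(p * p, -1, 1), p, p)
    colnames(X) <- paste0("f", seq_len(p))
    model <- fit_block_model(X, cfg)
    x <- setNames(rnorm(p, colMeans(X), apply(X, 2, sd)), colnames(X))
    pr <- project_sample(x, model)
    # oracle: Mahalanobis distance under the full NOC score covariance
    Xs <- scale(X, model$center, model$scale)
    noc_scores <- Xs %*% model$loadings
    xs <- (x - model$center) / model$scale
    s <- drop(xs %*% model$loadings)
    t2_brute <- drop(t(s) %*% solve(stats::cov(noc_scores)) %*% s)
    expect_equal(pr$t2, t2_brute, tolerance = 1e-8)
  }
})

test_that("projection is exact at the centre and conserves energy at full rank", {
  cfg_full <- qc_config(n_pcs = 8)
  X <- random_noc(35, 5, seed = 3)
  model <- fit_block_model(X, cfg_full) # k = rank = 5
  expect_equal(model$k, 5)
  centre <- setNames(model$center, model$feature_names)
  pr0 <- project_sample(centre, model)
  expect_equal(pr0$t2, 0, tolerance = 1e-12)
  expect_equal(pr0$spe, 0, tolerance = 1e-12)
  # SPE + sum(t^2) = ||x_scaled||^2 when k = rank
  x <- setNames(rnorm(5, model$center, model$scale), model$feature_names)
  pr <- project_sample(x, model)
  xs <- (x - model$center) / model$scale
  expect_equal(pr$spe + sum(pr$scores^2), sum(xs^2), tolerance = 1e-8)
  # contributions are score x loading, feature by feature
  expect_equal(
    pr$contributions$contribution[pr$contributions$component == "PC1"],
    unname(pr$scores["PC1"] * model$loadings[, 1]), tolerance = 1e-12)
})

test_that("false-rejection rates on in-control data are calibrated", {
  # paper-scale NOC (100 rows, 28 correlated features): the F-based T2 limit
  # and the combined and-rule stay within the Monte-Carlo band; the
  # moment-matched SPE limit is optimistic at this NOC size (in-sample
  # residuals understate held-out error) but bounded
  withr::with_seed(29, {
    p <- 28; n <- 100; n_new <- 2000
    A <- matrix(rnorm(p * p, 0, 0.35), p, p) + diag(p)
    latent <- function(n) matrix(rnorm(n * p), n, p) %*% A
    X <- latent(n)
    colnames(X) <- paste0("f", seq_len(p))
    model <- fit_block_model(X, qc_config())
    Xnew <- latent(n_new)
    colnames(Xnew) <- colnames(X)
    res <- apply(Xnew, 1, function(x) {
      pr <- project_sample(setNames(x, colnames(X)), model)
      c(t2 = pr$t2_reject, spe = pr$spe_reject)
    })
    alpha <- model$alpha
    mc_band <- alpha + 2 * sqrt(alpha * (1 - alpha) / n_new)
    expect_lte(mean(res["t2", ]), mc_band)
    expect_lte(mean(res["t2", ] & res["spe", ]), mc_band)
    expect_lte(mean(res["spe", ]), 0.06) # known small-NOC optimism, bounded
  })
  # exact regime for the SPE limit (independent features, NOC large enough
  # that loading overfit is negligible): both tests within the band
  withr::with_seed(29, {
    p <- 28; n <- 20000; n_new <- 2000
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", seq_len(p))
    model <- fit_block_model(X, qc_config())
    Xnew <- matrix(rnorm(n_new * p), n_new, p)
    colnames(Xnew) <- colnames(X)
    res <- apply(Xnew, 1, function(x) {
      pr <- project_sample(setNames(x, colnames(X)), model)
      c(t2 = pr$t2_reject, spe = pr$spe_reject)
    })
    mc_band <- model$alpha + 2 * sqrt(model$alpha * (1 - model$alpha) / n_new)
    expect_lte(mean(res["t2", ]), mc_band)
    expect_lte(mean(res["spe", ]), mc_band)
  })
})

test_that("zero-variance features are dropped and guard the SPE", {
  X <- random_noc(30, 4, seed = 4)
  X <- cbind(X, const = 5)
  model <- fit_block_model(X, qc_config())
  expect_equal(model$dropped$feature, "const")
  x <- setNames(c(colMeans(X[, 1:4]), 5), colnames(X))
  expect_equal(project_sample(x, model)$spe, 0, tolerance = 1e-12)
  x_dev <- x; x_dev["const"] <- 5.001
  expect_true(project_sample(x_dev, model)$spe_reject)
})

test_that("NOC assembly filters on verdicts, eligibility and the minimum size", {
  cfg <- qc_config()
  at <- history_end
  mk <- function(id, day, pass, detected = rep(TRUE, 8), ooc = NA) {
    tibble::tibble(run_id = id, at = at - day * 3600, sample_type = "sample",
                   pass = pass, out_of_control = ooc,
                   compound_id = specs8$identifier, detected = detected,
                   height = ifelse(detected, 1000 + day, NA),
                   apex_rt = ifelse(detected, specs8$expected_rt, NA),
                   mass_error = ifelse(detected, 0.1, NA))
  }
  h30 <- purrr::list_rbind(purrr::map(1:30, function(i) mk(paste0("p", i), i, TRUE)))
  h5f <- purrr::list_rbind(purrr::map(31:35, function(i) mk(paste0("f", i), i, FALSE)))
  noc <- build_noc(dplyr::bind_rows(h30, h5f), at, cfg, specs8)
  expect_equal(nrow(noc$height), 30) # failing runs excluded
  expect_equal(ncol(noc$height), 28)
  expect_equal(ncol(noc$mass_error), 8)

  # a run with 7/8 detected standards is excluded under min_is 8
  h_partial <- mk("partial", 0.5, TRUE, detected = c(FALSE, rep(TRUE, 7)))
  noc2 <- build_noc(dplyr::bind_rows(h30, h_partial), at, cfg, specs8)
  expect_false("partial" %in% rownames(noc2$height))

  # runs alarmed by the multivariate tests are not normal operating conditions
  h_ooc <- mk("alarmed", 0.6, TRUE, ooc = TRUE)
  noc3 <- build_noc(dplyr::bind_rows(h30, h_ooc), at, cfg, specs8)
  expect_false("alarmed" %in% rownames(noc3$height))

  # below the minimum NOC size: no model
  h10 <- purrr::list_rbind(purrr::map(1:10, function(i) mk(paste0("p", i), i, TRUE)))
  noc4 <- build_noc(h10, at, cfg, specs8)
  expect_null(noc4$height)
  models <- mspc_models(h10, at, cfg, specs8)
  expect_true(all(vapply(models, is.null, logical(1))))
  m <- make_measurements(specs8$identifier, rep(1000, 8), specs8$expected_rt)
  res <- evaluate_mspc(m, models, cfg, "r", specs8)
  expect_true(is.na(res$out_of_control))
  expect_equal(nrow(res$blocks), 0)
})

test_that("the decision rule distinguishes and/or combinations", {
  # two standards, mass-error block only (k = 1): NOC strongly correlated, a
  # deviation along the anti-correlated direction rejects SPE but not T2
  two <- compound_list(identifier = c("is_a", "is_b"), mz = c(100, 200),
                       rt = c(60, 120))
  at <- history_end
  withr::with_seed(5, {
    common <- rnorm(30, 0, 1)
    h <- purrr::list_rbind(purrr::map(1:30, function(i) {
      tibble::tibble(run_id = paste0("r", i), at = at - i * 3600,
                     sample_type = "sample", pass = TRUE, out_of_control = NA,
                     compound_id = two$identifier, detected = TRUE,
                     height = 1000, apex_rt = two$expected_rt,
                     mass_error = common[i] + rnorm(2, 0, 0.05))
    }))
  })
  cfg_and <- qc_config(n_pcs = 1, min_is_per_polarity = 2, mspc_rule = "and")
  cfg_or <- qc_config(n_pcs = 1, min_is_per_polarity = 2, mspc_rule = "or")
  models <- mspc_models(h, at, cfg_and, two)
  # +2/-2 ppm: orthogonal to the common-bias component -> SPE-only rejection
  m <- make_measurements(two$identifier, c(1000, 1000), two$expected_rt,
                         mass_error = c(2, -2))
  res_and <- evaluate_mspc(m, models, cfg_and, "x", two)
  res_or <- evaluate_mspc(m, models, cfg_or, "x", two)
  blk <- res_and$blocks[res_and$blocks$block == "mass_error", ]
  expect_true(blk$spe_reject)
  expect_false(blk$t2_reject)
  expect_false(res_and$blocks$flagged[res_and$blocks$block == "mass_error"])
  expect_true(res_or$blocks$flagged[res_or$blocks$block == "mass_error"])
})

test_that("disabling the multiple-testing correction widens the per-test alpha", {
  expect_equal(corrected_alpha(qc_config()), 0.05 / 6)
  expect_equal(corrected_alpha(qc_config(), n_tests = 2), 0.025)
  expect_equal(corrected_alpha(qc_config(mspc_correction = "none")), 0.05)
})
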