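#' Pairwise internal-standard ratios
#'
#' Height and retention time enter the multivariate model as ratios over all
#' unique internal-standard pairs, `R = v_i / (v_i + v_j)` for `i < j` in
#' compound-list order. Ratios cancel shifts common to all standards
#' (detector gain, uniform RT drift), so a uniform change leaves the feature
#' vector untouched. Only one orientation is stored — the complementary
#' ratio is `1 - R`. Missing values must be set to 0 beforehand; a pair with
#' both values 0 yields 0 (maximally anomalous under reconstruction rather
#' than undefined).
#'
#' @param values Named numeric vector, one value per internal standard, in
#'   compound-list order.
#' @return Named numeric vector of length `p(p-1)/2` with names
#'   `"<id_i>/<id_j>"`.
#' @export
#' @examples
#' pairwise_ratios(c(a = 100, b = 300)) # a/(a+b) = 0.25
pairwise_ratios <- function(values) {
  p <- length(values)
  ids <- names(values) %||% paste0("v", seq_len(p))
  if (p < 2) return(setNames(numeric(0), character(0)))
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  i <- pairs[, "row"]; j <- pairs[, "col"]
  denom <- values[i] + values[j]
  r <- ifelse(denom == 0, 0, values[i] / denom)
  setNames(as.numeric(r), paste0(ids[i], "/", ids[j]))
}

mspc_blocks <- c("height", "retention_time", "mass_error")

# Per-run feature vector for one block: zero-impute missing standards first,
# then ratios for height/RT, raw ppm for mass error.
block_features <- function(values, block) {
  values[is.na(values)] <- 0
  if (block == "mass_error") values else pairwise_ratios(values)
}

wide_metric <- function(history, is_ids, col) {
  w <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(history), "run_id", "compound_id",
                  value = dplyr::all_of(col)),
    names_from = "compound_id", values_from = "value"
  )
  missing_ids <- setdiff(is_ids, names(w))
  for (id in missing_ids) w[[id]] <- NA_real_
  w[, c("run_id", is_ids), drop = FALSE]
}

#' Assemble the normal-operating-conditions (NOC) matrices
#'
#' For each parameter block, one row per QC-passing sample run in the
#' half-open window `[at - window, at)` that has at least
#' `min_is_per_polarity` detected internal standards. Height and retention
#' time rows are transformed to pairwise ratios; mass-error rows are the raw
#' per-standard ppm values. Runs previously declared out of control by the
#' multivariate tests are excluded as well — they are not normal operating
#' conditions, and retraining on them would absorb a persistent fault. A
#' block with fewer than `min_noc` rows returns `NULL` and multivariate
#' control silently defers to the univariate checks.
#'
#' @param history A `qc_history` tibble (each row carries the run's
#'   univariate outcome in `pass`).
#' @param at Evaluation timestamp.
#' @param cfg A [qc_config()].
#' @param specs A [compound_list()].
#' @param polarity Run polarity.
#' @return Named list of numeric matrices (or `NULL`s), one per block, with
#'   run ids as row names.
#' @export
build_noc <- function(history, at, cfg = qc_config(),
                      specs = default_internal_standards(),
                      polarity = "positive") {
  is_ids <- internal_standards_only(specs, polarity)$identifier
  h <- history_window(history, at, cfg$rolling_window)
  h <- h[h$sample_type == "sample" & h$pass &
           (is.na(h$out_of_control) | !h$out_of_control) &
           h$compound_id %in% is_ids, , drop = FALSE]
  if (nrow(h) == 0) {
    return(setNames(vector("list", 3), mspc_blocks))
  }
  n_det <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(h), .data$run_id),
                            n = sum(.data$detected))
  eligible <- n_det$run_id[n_det$n >= cfg$min_is_per_polarity]
  h <- h[h$run_id %in% eligible, , drop = FALSE]
  h$height[!h$detected] <- NA_real_
  h$apex_rt[!h$detected] <- NA_real_
  h$mass_error[!h$detected] <- NA_real_

  feature_rows <- function(col, block) {
    w <- wide_metric(h, is_ids, col)
    if (nrow(w) < cfg$min_noc) return(NULL)
    M <- as.matrix(w[, is_ids, drop = FALSE])
    rows <- lapply(seq_len(nrow(M)), function(i) {
      block_features(setNames(M[i, ], is_ids), block)
    })
    X <- do.call(rbind, rows)
    rownames(X) <- w$run_id
    X
  }
  list(
    height = feature_rows("height", "height"),
    retention_time = feature_rows("apex_rt", "retention_time"),
    mass_error = feature_rows("mass_error", "mass_error")
  )
}

#' Fit the PCA control model for one parameter block
#'
#' The NOC matrix is autoscaled (per-feature mean 0, sd 1; zero-variance
#' features are dropped from the model and recorded), decomposed by PCA, and
#' the first `n_pcs` components retained (fewer if the matrix has lower
#' rank). Per-component score variances use the n-1 denominator. Control
#' limits at significance `alpha`:
#'
#' * Hotelling's T2 for a new observation:
#'   `k(n-1)(n+1) / (n(n-k)) * F(1 - alpha; k, n - k)`;
#' * SPE via the moment-matched scaled chi-square on the NOC SPE values:
#'   `g * chisq(1 - alpha; h)` with `g = v/(2m)`, `h = 2m^2/v`, where `m`
#'   and `v` are the mean and variance of the NOC SPE distribution.
#'
#' Component signs are fixed by making each PC's largest-magnitude loading
#' positive, so contributions are deterministic.
#'
#' @param noc_matrix Numeric matrix, runs x features.
#' @param cfg A [qc_config()].
#' @param alpha Per-test significance level; defaults to
#'   [corrected_alpha()] of `cfg`.
#' @param block Block label carried in the model.
#' @return An object of class `noc_model`.
#' @export
fit_block_model <- function(noc_matrix, cfg = qc_config(),
                            alpha = corrected_alpha(cfg), block = "height") {
  n <- nrow(noc_matrix)
  if (n < 3) abort("NOC matrix needs at least 3 rows")
  mu <- colMeans(noc_matrix)
  sdev <- apply(noc_matrix, 2, sd)
  keep <- sdev > 1e-12
  if (!any(keep)) abort("all NOC features are constant; no model can be fitted")
  dropped <- tibble::tibble(feature = colnames(noc_matrix)[!keep],
                            mean = mu[!keep])
  X <- scale(noc_matrix[, keep, drop = FALSE], center = mu[keep],
             scale = sdev[keep])
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev[1], 1e-12) * 1e-8)
  k <- min(cfg$n_pcs, rank, ncol(X))
  if (k < cfg$n_pcs) {
    inform(paste0("block '", block, "': rank ", rank,
                  " < n_pcs; using k = ", k))
  }
  P <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic orientation: largest |loading| positive per component
  for (j in seq_len(k)) {
    lead <- which.max(abs(P[, j]))
    if (P[lead, j] < 0) P[, j] <- -P[, j]
  }
  scores <- X %*% P
  lambda <- apply(scores, 2, var)
  total_var <- sum(pc$sdev^2)
  explained <- if (total_var > 0) sum(lambda) / total_var else NA_real_

  t2_limit <- k * (n - 1) * (n + 1) / (n * (n - k)) * qf(1 - alpha, k, n - k)
  resid <- X - scores %*% t(P)
  spe_noc <- rowSums(resid^2)
  m <- mean(spe_noc)
  v <- var(spe_noc)
  spe_limit <- if (m <= 0 || v <= 0) {
    0
  } else {
    (v / (2 * m)) * qchisq(1 - alpha, 2 * m^2 / v)
  }

  structure(
    list(block = block, n_samples = n,
         feature_names = colnames(noc_matrix)[keep],
         center = mu[keep], scale = sdev[keep], dropped = dropped,
         loadings = P, score_variances = as.numeric(lambda),
         explained_variance = explained, k = k,
         t2_limit = t2_limit, spe_limit = spe_limit, alpha = alpha),
    class = "noc_model"
  )
}

#' @export
print.noc_model <- function(x, ...) {
  cat("<noc_model> block '", x$block, "': n = ", x$n_samples,
      ", k = ", x$k, " PCs (", round(100 * x$explained_variance, 1),
      "% variance)\n", sep = "")
  cat("  T2 limit ", signif(x$t2_limit, 4), ", SPE limit ",
      signif(x$spe_limit, 4), " at alpha ", signif(x$alpha, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_block_model
#' @param x A `noc_model`.
#' @param ... Unused.
#' @export
tidy.noc_model <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading") |>
    dplyr::mutate(block = x$block, .before = 1)
}

#' @rdname fit_block_model
#' @export
glance.noc_model <- function(x, ...) {
  tibble::tibble(
    block = x$block, n_samples = x$n_samples, k = x$k,
    explained_variance = x$explained_variance,
    t2_limit = x$t2_limit, spe_limit = x$spe_limit, alpha = x$alpha,
    n_features = length(x$feature_names), n_dropped = nrow(x$dropped)
  )
}

#' Project one run onto a block's control model
#'
#' The feature vector is autoscaled with the NOC statistics, projected onto
#' the retained loadings, and tested twice: Hotelling's T2
#' (`sum(t_i^2 / lambda_i)`, the Mahalanobis distance of the score vector)
#' against `t2_limit`, and the squared prediction error
#' (`||x_scaled - reconstruction||^2`) against `spe_limit`. Deviations on
#' features that were constant in the NOC are added to the SPE as squared
#' deviations from the NOC constant over a floor sd of 1e-8. Per-feature,
#' per-component contributions are score x loading.
#'
#' @param values Named numeric feature vector (same names as the NOC matrix;
#'   build with [block_sample_features()]).
#' @param model A `noc_model`.
#' @return List with `t2`, `spe`, `t2_reject`, `spe_reject`, `scores` and a
#'   `contributions` tibble.
#' @export
project_sample <- function(values, model) {
  x <- values[model$feature_names]
  if (any(is.na(x))) {
    abort("sample feature vector does not cover the model's features")
  }
  xs <- (x - model$center) / model$scale
  scores <- drop(xs %*% model$loadings)
  t2 <- sum(scores^2 / model$score_variances)
  recon <- drop(model$loadings %*% scores)
  spe <- sum((xs - recon)^2)
  if (nrow(model$dropped) > 0) {
    dv <- values[model$dropped$feature]
    spe <- spe + sum(((dv - model$dropped$mean) / 1e-8)^2)
  }
  contributions <- tibble::tibble(
    block = model$block,
    component = rep(colnames(model$loadings), each = length(xs)),
    feature = rep(model$feature_names, times = length(scores)),
    contribution = as.numeric(model$loadings *
                                rep(scores, each = length(xs)))
  )
  list(t2 = t2, spe = spe,
       t2_reject = t2 > model$t2_limit,
       spe_reject = spe > model$spe_limit,
       scores = setNames(as.numeric(scores), colnames(model$loadings)),
       contributions = contributions)
}

#' Feature vector of one run for one block
#'
#' @param measurements [measure_run()] output.
#' @param block One of `"height"`, `"retention_time"`, `"mass_error"`.
#' @param specs A [compound_list()].
#' @param polarity Run polarity.
#' @return Named numeric vector; undetected standards contribute 0.
#' @export
block_sample_features <- function(measurements, block,
                                  specs = default_internal_standards(),
                                  polarity = "positive") {
  is_ids <- internal_standards_only(specs, polarity)$identifier
  col <- switch(block, height = "height", retention_time = "apex_rt",
                mass_error = "mass_error",
                abort(paste0("unknown block: ", block)))
  v <- setNames(rep(NA_real_, length(is_ids)), is_ids)
  m <- measurements[measurements$compound_id %in% is_ids, , drop = FALSE]
  vals <- m[[col]]
  vals[!m$detected] <- 0
  v[m$compound_id] <- vals
  v[is.na(v)] <- 0
  block_features(v, block)
}

#' Fit all block models from history
#'
#' Builds the NOC matrices with [build_noc()] and fits one `noc_model` per
#' block with enough history. With the Bonferroni correction the per-test
#' alpha is `alpha_initial` divided by the number of tests actually run
#' (two per available block; six when all three blocks have models).
#'
#' @inheritParams build_noc
#' @return Named list of `noc_model` objects (absent blocks are `NULL`),
#'   with the per-test alpha as attribute `alpha`.
#' @export
mspc_models <- function(history, at, cfg = qc_config(),
                        specs = default_internal_standards(),
                        polarity = "positive") {
  noc <- build_noc(history, at, cfg, specs, polarity)
  # a block is usable only if it exists and at least one feature varies
  avail <- vapply(noc, function(X) {
    !is.null(X) && nrow(X) >= 3 && any(apply(X, 2, sd) > 1e-12)
  }, logical(1))
  n_tests <- 2L * sum(avail)
  alpha <- if (n_tests == 0) {
    corrected_alpha(cfg)
  } else {
    corrected_alpha(cfg, n_tests = n_tests)
  }
  models <- setNames(vector("list", length(mspc_blocks)), mspc_blocks)
  for (b in mspc_blocks[avail]) {
    models[[b]] <- fit_block_model(noc[[b]], cfg, alpha = alpha, block = b)
  }
  attr(models, "alpha") <- alpha
  models
}

#' Multivariate control decision for one run
#'
#' Projects the run onto every available block model and combines the six
#' tests (T2 and SPE per block). Under the default `"and"` rule the run is
#' out of control when some block rejects both T2 and SPE; the `"or"` rule
#' flags on either rejection.
#'
#' @param measurements [measure_run()] output for the run.
#' @param models Output of [mspc_models()].
#' @param cfg A [qc_config()].
#' @param run_id Run identifier.
#' @param specs A [compound_list()].
#' @param polarity Run polarity.
#' @return An `mspc_result`: list with `run_id`, `blocks` tibble (statistics,
#'   limits, rejections), `out_of_control`, `flagged_blocks`,
#'   `contributions`, `rule`, `alpha`. When no block model exists the result
#'   has zero block rows and `out_of_control = NA`.
#' @export
evaluate_mspc <- function(measurements, models, cfg = qc_config(),
                          run_id = NA_character_,
                          specs = default_internal_standards(),
                          polarity = "positive") {
  rows <- list()
  contribs <- list()
  for (b in mspc_blocks) {
    model <- models[[b]]
    if (is.null(model)) next
    feats <- block_sample_features(measurements, b, specs, polarity)
    pr <- project_sample(feats, model)
    flagged <- if (cfg$mspc_rule == "and") {
      pr$t2_reject && pr$spe_reject
    } else {
      pr$t2_reject || pr$spe_reject
    }
    rows[[b]] <- tibble::tibble(
      block = b, t2 = pr$t2, t2_limit = model$t2_limit,
      t2_reject = pr$t2_reject, spe = pr$spe, spe_limit = model$spe_limit,
      spe_reject = pr$spe_reject, flagged = flagged
    )
    contribs[[b]] <- pr$contributions
  }
  blocks <- purrr::list_rbind(rows)
  structure(
    list(run_id = run_id, blocks = blocks,
         out_of_control = if (nrow(blocks) == 0) NA else any(blocks$flagged),
         flagged_blocks = if (nrow(blocks)) blocks$block[blocks$flagged] else character(),
         contributions = purrr::list_rbind(contribs),
         rule = cfg$mspc_rule,
         alpha = attr(models, "alpha") %||% corrected_alpha(cfg)),
    class = "mspc_result"
  )
}

#' @export
print.mspc_result <- function(x, ...) {
  cat("<mspc_result> run ", x$run_id %||% "?", ": ",
      if (is.na(x$out_of_control)) "no model (insufficient NOC)"
      else if (x$out_of_control) paste0("OUT OF CONTROL [",
                                        paste(x$flagged_blocks, collapse = ", "), "]")
      else "in control", "\n", sep = "")
  if (nrow(x$blocks)) print(x$blocks)
  invisible(x)
}

#' @rdname evaluate_mspc
#' @param x An `mspc_result`.
#' @param ... Unused.
#' @export
tidy.mspc_result <- function(x, ...) {
  dplyr::mutate(x$blocks, run_id = x$run_id, .before = 1)
}

#' @rdname evaluate_mspc
#' @export
glance.mspc_result <- function(x, ...) {
  tibble::tibble(
    run_id = x$run_id, out_of_control = x$out_of_control,
    flagged_blocks = paste(x$flagged_blocks, collapse = ";"),
    n_blocks = nrow(x$blocks), rule = x$rule, alpha = x$alpha
  )
}
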