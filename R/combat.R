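#' Fit a parametric empirical-Bayes ComBat batch-effect model
#'
#' Estimates scanner/batch location and scale effects on the tract feature
#' matrix with the classic parametric empirical-Bayes ComBat model:
#' (i) feature-wise standardization using a least-squares fit of batch
#' means and optional covariates, with the variance pooled across all fit
#' subjects; (ii) method-of-moments hyperpriors across features (normal
#' prior on the location effects, inverse-gamma on the scale effects);
#' (iii) iterative conditional updates of the per-feature-by-batch
#' posterior means `gamma_star` and scales `delta_star` to convergence.
#'
#' `fit_on = "controls"` (the default) estimates all model parameters from
#' the control subjects only, so that patient pathology cannot contaminate
#' the batch estimates; patients are still adjusted with the per-batch
#' parameters when the model is applied. `fit_on = "all"` uses every
#' subject, matching a plain column-wise call on the combined table.
#'
#' @param tm A [tract_matrix()] at stage `"raw"`.
#' @param batch Metadata column holding the scanner/batch label.
#' @param covariates Character vector of metadata columns whose effects
#'   must be preserved through harmonization (e.g. `c("age", "sex")`);
#'   default none.
#' @param fit_on `"controls"` or `"all"`.
#' @param conv Convergence tolerance on the relative change of the EB
#'   updates (default 1e-6).
#' @param max_iter Iteration cap for the EB updates (default 500).
#' @return An object of class `combat_model`.
#' @export
fit_combat <- function(tm, batch = "batch", covariates = character(),
                       fit_on = c("controls", "all"),
                       conv = 1e-6, max_iter = 500L) {
  stopifnot(inherits(tm, "tract_matrix"))
  fit_on <- match.arg(fit_on)
  meta <- tm$metadata
  if (!batch %in% names(meta)) {
    abort_fixelnorm(sprintf("metadata has no column '%s'", batch),
                    "fixelnorm_config_error")
  }
  fit_idx <- if (fit_on == "controls" && "group" %in% names(meta)) {
    which(meta$group == "control")
  } else {
    seq_len(nrow(meta))
  }
  Y <- tm$values[, fit_idx, drop = FALSE]   # features x fit subjects
  bvec <- as.character(meta[[batch]][fit_idx])
  batches <- unique(bvec)
  n_b <- table(factor(bvec, levels = batches))
  G <- nrow(Y)

  if (length(batches) < 2L) {
    warn("single batch in fit set; returning identity harmonization model")
    model <- .identity_combat(tm, batch, batches, fit_idx)
    return(model)
  }
  if (any(n_b < 2L)) {
    abort_fixelnorm("every batch must have at least 2 fit subjects",
                    "fixelnorm_design_error")
  }

  X_cov <- .covariate_matrix(meta[fit_idx, , drop = FALSE], covariates)
  B_design <- stats::model.matrix(~ 0 + factor(bvec, levels = batches))
  colnames(B_design) <- batches
  X <- cbind(B_design, X_cov)
  if (qr(X)$rank < ncol(X)) {
    abort_fixelnorm("covariate design matrix is rank deficient",
                    "fixelnorm_design_error")
  }

  # (i) standardization
  n <- ncol(Y)
  B_hat <- solve(crossprod(X), t(X) %*% t(Y))       # p x G
  alpha <- as.numeric(matrix(as.numeric(n_b) / n, nrow = 1) %*%
                        B_hat[seq_along(batches), , drop = FALSE])
  beta <- B_hat[-seq_along(batches), , drop = FALSE]  # covar coefs x G
  fitted_full <- t(X %*% B_hat)                     # G x n
  pooled_var <- rowMeans((Y - fitted_full)^2)       # divisor n
  if (any(pooled_var <= 0)) {
    abort_fixelnorm("zero pooled variance for at least one feature",
                    "fixelnorm_design_error")
  }
  stand_mean <- alpha +
    if (ncol(X_cov) > 0) t(X_cov %*% beta) else matrix(0, G, n)
  s_data <- (Y - stand_mean) / sqrt(pooled_var)

  # (ii) per-batch moments + hyperpriors across features
  gamma_hat <- t(vapply(batches, function(b) {
    rowMeans(s_data[, bvec == b, drop = FALSE])
  }, numeric(G)))                                   # batches x G
  delta_hat <- t(vapply(batches, function(b) {
    apply(s_data[, bvec == b, drop = FALSE], 1, var)
  }, numeric(G)))
  gamma_bar <- rowMeans(gamma_hat)
  tau_sq <- apply(gamma_hat, 1, var)
  lambda <- apply(delta_hat, 1, .aprior)
  theta <- apply(delta_hat, 1, .bprior)

  # (iii) iterative conditional EB updates
  gamma_star <- matrix(NA_real_, length(batches), G)
  delta_star <- matrix(NA_real_, length(batches), G)
  iters <- integer(length(batches))
  for (bi in seq_along(batches)) {
    sd_b <- s_data[, bvec == batches[bi], drop = FALSE]
    sol <- .eb_iterate(sd_b, gamma_hat[bi, ], delta_hat[bi, ],
                       gamma_bar[bi], tau_sq[bi], lambda[bi], theta[bi],
                       conv, max_iter)
    gamma_star[bi, ] <- sol$gamma
    delta_star[bi, ] <- sol$delta
    iters[bi] <- sol$iter
  }
  dimnames(gamma_star) <- dimnames(delta_star) <-
    list(batches, rownames(tm$values))

  structure(list(
    batch_key = batch, batches = batches, n_b = as.integer(n_b),
    covariates = covariates,
    alpha = setNames(alpha, rownames(tm$values)),
    beta = beta, pooled_var = setNames(pooled_var, rownames(tm$values)),
    gamma_star = gamma_star, delta_star = delta_star,
    priors = tibble(batch = batches, gamma_bar = gamma_bar,
                    tau_sq = tau_sq, lambda = lambda, theta = theta),
    fit_subjects = meta$id[fit_idx], fit_on = fit_on,
    identity = FALSE, iterations = iters
  ), class = "combat_model")
}

.covariate_matrix <- function(meta, covariates) {
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow = nrow(meta), ncol = 0))
  }
  missing <- setdiff(covariates, names(meta))
  if (length(missing) > 0) {
    abort_fixelnorm(
      paste("metadata lacks covariate columns:",
            paste(missing, collapse = ", ")),
      "fixelnorm_config_error")
  }
  f <- stats::as.formula(paste("~", paste(covariates, collapse = "+")))
  mm <- stats::model.matrix(f, data = as.data.frame(meta))
  mm[, -1, drop = FALSE]   # drop intercept; batch dummies span it
}

# method-of-moments inverse-gamma hyperparameters on the scale effects
.aprior <- function(d) {
  m <- mean(d); s2 <- var(d)
  (2 * s2 + m^2) / s2
}
.bprior <- function(d) {
  m <- mean(d); s2 <- var(d)
  (m * s2 + m^3) / s2
}

.eb_iterate <- function(s_data_b, g_hat, d_hat, g_bar, t2, lambda, theta,
                        conv, max_iter) {
  n <- ncol(s_data_b)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (n * t2 * g_hat + d_old * g_bar) / (n * t2 + d_old)
    ss <- rowSums((s_data_b - g_new)^2)
    d_new <- (theta + 0.5 * ss) / (n / 2 + lambda - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / abs(d_old))
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_old, delta = d_old, iter = it)
}

.identity_combat <- function(tm, batch, batches, fit_idx) {
  G <- nrow(tm$values)
  gn <- matrix(0, length(batches), G,
               dimnames = list(batches, rownames(tm$values)))
  dn <- matrix(1, length(batches), G,
               dimnames = list(batches, rownames(tm$values)))
  structure(list(
    batch_key = batch, batches = batches,
    n_b = as.integer(table(tm$metadata[[batch]][fit_idx])),
    covariates = character(),
    alpha = setNames(rowMeans(tm$values[, fit_idx, drop = FALSE]),
                     rownames(tm$values)),
    beta = matrix(numeric(0), 0, G),
    pooled_var = setNames(rep(1, G), rownames(tm$values)),
    gamma_star = gn, delta_star = dn,
    priors = tibble(batch = batches, gamma_bar = 0, tau_sq = 0,
                    lambda = NA_real_, theta = NA_real_),
    fit_subjects = tm$metadata$id[fit_idx], fit_on = "all",
    identity = TRUE, iterations = integer(length(batches))
  ), class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat("<combat_model> ", length(x$alpha), " features, batches: ",
      paste(x$batches, collapse = ", "),
      if (x$identity) " (identity)", "\n", sep = "")
  invisible(x)
}

#' Apply a fitted ComBat model to a tract matrix
#'
#' Each value is standardized with the model's intercept, covariate
#' coefficients and pooled variance, shifted by its batch's posterior
#' location effect, rescaled by its batch's posterior scale effect, and
#' de-standardized. Subjects outside the fit set (e.g. patients when the
#' model was fit on controls) are adjusted with the same per-batch
#' parameters.
#'
#' @param tm A [tract_matrix()].
#' @param model A `combat_model` from [fit_combat()].
#' @return A [tract_matrix()] at stage `"harmonized"`.
#' @export
apply_combat <- function(tm, model) {
  stopifnot(inherits(tm, "tract_matrix"), inherits(model, "combat_model"))
  meta <- tm$metadata
  bvec <- as.character(meta[[model$batch_key]])
  unseen <- setdiff(unique(bvec), model$batches)
  if (length(unseen) > 0) {
    abort_fixelnorm(
      paste("batch labels not present in the fitted model:",
            paste(unseen, collapse = ", ")),
      "fixelnorm_application_error")
  }
  if (model$identity) {
    out <- tm
    out$stage <- "harmonized"
    return(out)
  }
  Y <- tm$values
  G <- nrow(Y)
  X_cov <- .covariate_matrix(meta, model$covariates)
  stand_mean <- model$alpha +
    if (ncol(X_cov) > 0) t(X_cov %*% model$beta) else matrix(0, G, ncol(Y))
  z <- (Y - stand_mean) / sqrt(model$pooled_var)
  bi <- match(bvec, model$batches)
  z_adj <- (z - t(model$gamma_star[bi, , drop = FALSE])) /
    sqrt(t(model$delta_star[bi, , drop = FALSE]))
  values <- z_adj * sqrt(model$pooled_var) + stand_mean
  tract_matrix(values, tm$tracts, meta, stage = "harmonized")
}

#' Tidy a ComBat model: per-feature-by-batch adjustments
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return Tibble with `feature`, `batch`, `gamma_star`, `delta_star`.
#' @method tidy combat_model
#' @export
tidy.combat_model <- function(x, ...) {
  tidyr::expand_grid(batch = x$batches, feature = names(x$alpha)) |>
    dplyr::mutate(
      gamma_star = purrr::map2_dbl(.data$batch, .data$feature,
                                   ~ x$gamma_star[.x, .y]),
      delta_star = purrr::map2_dbl(.data$batch, .data$feature,
                                   ~ x$delta_star[.x, .y]))
}

#' One-row ComBat model summary
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return Tibble with counts, fit mode and EB iteration counts.
#' @method glance combat_model
#' @export
glance.combat_model <- function(x, ...) {
  tibble(n_features = length(x$alpha), n_batches = length(x$batches),
         n_fit_subjects = length(x$fit_subjects), fit_on = x$fit_on,
         identity = x$identity,
         max_iterations = if (length(x$iterations)) max(x$iterations) else 0L)
}

#' Serialize a ComBat model to JSON for audit
#'
#' @param model A `combat_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_combat_model <- function(model, path) {
  x <- unclass(model)
  x$gamma_star <- as.data.frame(x$gamma_star)
  x$delta_star <- as.data.frame(x$delta_star)
  x$beta <- as.data.frame(x$beta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
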