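# Out-of-sample prediction of real-world outcome targets from factor
# scores, with permutation nulls and ontological fingerprints.
#
# cv R^2 is the squared Pearson correlation between the concatenated
# out-of-fold predictions and the actual target; the conventional
# 1 - SSE/SST is reported alongside. Standardization and penalty selection
# happen strictly inside training folds.

#' Derive outcome target factor scores
#'
#' Residualizes the outcome DVs on age and sex, runs the BIC dimensionality
#' sweep and oblimin EFA on the residuals, and returns ten Berge factor
#' scores: the prediction targets.
#'
#' @param x A [dv_matrix()] of outcome DVs.
#' @param covariates A [covariate_table()].
#' @param f_candidates Candidate factor numbers for the sweep (default
#'   `1:min(floor(m/3), 25)`).
#' @param seed Integer seed.
#' @return List with `scores` (`factor_scores`), `model` (`factor_model`),
#'   `sweep` (`dimensionality_sweep`), `residualized` (the residualized
#'   `dv_matrix`).
#' @export
derive_outcome_targets <- function(x, covariates, f_candidates = NULL, seed = 1) {
  res <- residualize_covariates(x, covariates)
  sw <- select_dimensionality(res, f_candidates = f_candidates, seed = seed)
  model <- sw$best_model
  scores <- factor_scores(model, res)
  list(scores = scores, model = model, sweep = sw, residualized = res)
}

#' Balanced k-fold assignment for a continuous target
#'
#' Bins the target into decile strata and deals each stratum's participants
#' across folds (smallest fold first), so fold-wise target means and
#' variances are balanced and fold sizes differ by at most one.
#'
#' @param target Numeric vector.
#' @param k Number of folds.
#' @param seed Integer seed (shuffling within strata).
#' @return Integer vector of fold ids in `1..k`.
#' @export
balanced_kfold <- function(target, k = 10, seed = 1) {
  n <- length(target)
  if (k > n) stop("k exceeds number of participants")
  rs <- restore_rng_state(); on.exit(rs(), add = TRUE)
  set.seed(seed)
  n_strata <- min(10, max(1, floor(n / k)))
  qs <- stats::quantile(target, probs = seq(0, 1, length.out = n_strata + 1))
  strata <- cut(target, breaks = unique(qs), include.lowest = TRUE,
                labels = FALSE)
  strata[is.na(strata)] <- 1L
  # stable order within strata: sort by target (ties by index), then shuffle;
  # concatenated strata are dealt cyclically so fold sizes differ by <= 1
  ord <- unlist(lapply(sort(unique(strata)), function(s) {
    idx <- which(strata == s)
    idx <- idx[order(target[idx], idx)]
    idx[sample.int(length(idx))]
  }))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

scores_matrix <- function(features) {
  if (inherits(features, "factor_scores")) return(features$scores)
  if (inherits(features, "dv_matrix")) return(features$values)
  as.matrix(features)
}

fit_model_once <- function(X, y, model, seed = 1) {
  switch(model,
    ridge = ridge_loo_fit(X, y),
    lasso = {
      cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = 5,
                                 standardize = TRUE)
      co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
      list(kind = "lasso", fit = cvfit, beta = co[-1], intercept = co[1])
    },
    rf = {
      if (!requireNamespace("ranger", quietly = TRUE))
        stop("ranger required for model = 'rf'")
      df <- data.frame(y = y, X)
      list(kind = "rf",
           fit = ranger::ranger(y ~ ., data = df, num.trees = 500,
                                seed = seed))
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("e1071 required for model = 'svm'")
      list(kind = "svm", fit = e1071::svm(X, y, kernel = "radial"))
    },
    stop("unknown model: ", model))
}

predict_model <- function(fit, X) {
  if (!is.null(fit$lambda)) return(ridge_predict(fit, X))
  switch(fit$kind,
    lasso = as.numeric(stats::predict(fit$fit, newx = X, s = "lambda.min")),
    rf = stats::predict(fit$fit, data = data.frame(X))$predictions,
    svm = as.numeric(stats::predict(fit$fit, X)))
}

#' Cross-validated prediction of one target
#'
#' Balanced k-fold CV; within each training fold the features are
#' standardized with training statistics and the model's penalty is selected
#' internally; predictions for all folds are concatenated and compared with
#' the actual target. In-sample metrics come from a full-data fit, whose
#' standardized ridge coefficients are the target's fingerprint.
#'
#' @param features `factor_scores`, `dv_matrix`, or numeric matrix.
#' @param target Numeric vector.
#' @param model `"ridge"` (primary), `"lasso"`, `"rf"`, or `"svm"`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Object of class `prediction_result`: `cv_r2` (squared Pearson of
#'   out-of-fold predictions vs target), `cv_r` (signed), `cv_r2_sse`
#'   (1 - SSE/SST), `cv_mae`, `insample_r2`, `insample_mae`, `betas`
#'   (standardized, ridge full fit), `folds`, `oof_predictions`,
#'   `constant_prediction` flag.
#' @export
cv_predict <- function(features, target, model = "ridge", k = 10, seed = 1) {
  X <- scores_matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(target)
  stopifnot(nrow(X) == length(y))
  folds <- balanced_kfold(y, k = k, seed = seed)
  if (model == "ridge") {
    oof <- as.numeric(ridge_cv_oof(X, y, as.integer(folds),
                                   default_ridge_grid()))
  } else {
    oof <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_model_once(X[tr, , drop = FALSE], y[tr], model, seed = seed)
      oof[!tr] <- predict_model(fit, X[!tr, , drop = FALSE])
    }
  }
  constant <- stats::sd(oof) < 1e-12
  cv_r <- if (constant) 0 else stats::cor(oof, y)
  full <- fit_model_once(X, y, model, seed = seed)
  ins <- predict_model(full, X)
  ins_r <- if (stats::sd(ins) < 1e-12) 0 else stats::cor(ins, y)
  betas <- if (model == "ridge") {
    stats::setNames(full$beta_std / stats::sd(y), colnames(X))
  } else {
    ridge_full <- ridge_loo_fit(X, y)
    stats::setNames(ridge_full$beta_std / stats::sd(y), colnames(X))
  }
  structure(list(cv_r2 = cv_r^2, cv_r = cv_r,
                 cv_r2_sse = 1 - sum((y - oof)^2) / sum((y - mean(y))^2),
                 cv_mae = mean(abs(y - oof)),
                 insample_r2 = ins_r^2, insample_mae = mean(abs(y - ins)),
                 betas = betas, folds = folds, oof_predictions = oof,
                 model = model, constant_prediction = constant),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("<prediction_result> model = ", x$model,
      "; cv R^2 = ", round(x$cv_r2, 3),
      ", in-sample R^2 = ", round(x$insample_r2, 3),
      if (!is.null(x$p_value)) paste0(", p = ", signif(x$p_value, 3)),
      "\n", sep = "")
  invisible(x)
}

#' Permutation null for cross-validated prediction
#'
#' Shuffles the target, rebuilds balanced folds on the shuffled target, and
#' reruns the full CV pipeline (including internal penalty selection) for
#' each permutation. The observed `cv_r2` is compared with the null via
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param features,target,model,k As in [cv_predict()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed (observed folds and shuffles).
#' @return A `prediction_result` with `null_distribution`, `null_95` (95th
#'   percentile of null cv R^2), and `p_value` added.
#' @export
permutation_null <- function(features, target, model = "ridge", n_perm = 2500,
                             k = 10, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is coarse")
  obs <- cv_predict(features, target, model = model, k = k, seed = seed)
  X <- scores_matrix(features)
  y <- as.numeric(target)
  rs <- restore_rng_state(); on.exit(rs(), add = TRUE)
  set.seed(seed + 1L)
  null <- vapply(seq_len(n_perm), function(b) {
    yp <- y[sample.int(length(y))]
    cv_predict(X, yp, model = model, k = k, seed = seed)$cv_r2
  }, 0)
  obs$null_distribution <- null
  obs$null_95 <- as.numeric(stats::quantile(null, 0.95))
  obs$p_value <- (1 + sum(null >= obs$cv_r2)) / (1 + n_perm)
  obs
}

#' Ontological fingerprints from prediction results
#'
#' The fingerprint of a target is its profile of standardized ridge
#' coefficients over the predictor factors; inverting the matrix gives one
#' factor's profile across all targets.
#'
#' @param results Named list of `prediction_result` objects (one per
#'   target), or a single `prediction_result`.
#' @param direction `"target_wise"` (targets in rows) or `"feature_wise"`
#'   (the exact transpose).
#' @return Matrix of standardized coefficients.
#' @export
fingerprint <- function(results, direction = c("target_wise", "feature_wise")) {
  direction <- match.arg(direction)
  if (inherits(results, "prediction_result")) results <- list(target = results)
  M <- do.call(rbind, lapply(results, function(r) r$betas))
  rownames(M) <- names(results)
  if (direction == "feature_wise") t(M) else M
}

#' Run the outcome-prediction analysis for a set of targets
#'
#' @param features `factor_scores` (e.g. survey factors) or matrix.
#' @param targets `factor_scores` or matrix of target columns.
#' @param model,k,n_perm,seed As in [permutation_null()]; `n_perm = 0` skips
#'   the null.
#' @return Named list of `prediction_result` objects.
#' @export
predict_outcomes <- function(features, targets, model = "ridge", k = 10,
                             n_perm = 2500, seed = 1) {
  TM <- scores_matrix(targets)
  if (is.null(colnames(TM))) colnames(TM) <- paste0("target", seq_len(ncol(TM)))
  out <- lapply(seq_len(ncol(TM)), function(j) {
    if (n_perm > 0)
      permutation_null(features, TM[, j], model = model, n_perm = n_perm,
                       k = k, seed = seed + j)
    else cv_predict(features, TM[, j], model = model, k = k, seed = seed + j)
  })
  names(out) <- colnames(TM)
  out
}
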