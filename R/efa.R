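# Exploratory factor analysis: the quantitative psychological space.
#
# The model is the common factor decomposition X - mu = L F + eps: each
# standardized DV is a linear combination of f latent factors (loadings L,
# factor correlations Phi after oblique rotation) plus unique variance Psi.
# Maximum-likelihood uniquenesses come from the Wishart likelihood of the
# correlation matrix; direct oblimin (quartimin) rotation supplies an
# interpretable oblique basis without changing fit; ten Berge weights give
# factor scores whose correlations reproduce Phi.

#' Fit a maximum-likelihood EFA with oblimin rotation
#'
#' Fits the common factor model to the Pearson correlation matrix of the
#' standardized DVs by maximum likelihood, rotates with direct oblimin
#' (gamma = 0, gradient projection, seeded random starts), and computes
#' ten Berge correlation-preserving score weights.
#'
#' @param x A [dv_matrix()].
#' @param f Number of factors (must be < number of DVs and leave the model
#'   identified).
#' @param seed Integer seed controlling the rotation starts.
#' @param n_rotation_starts Number of oblimin starts (identity + random).
#' @return An object of class `factor_model`: `loadings` (m x f), `Phi`
#'   (f x f), `uniqueness`, `weights` (m x f ten Berge), `communality`,
#'   `n_factors`, `fit` (`loglik_stat`, `chi2`, `df`, `bic`, `n_obs`),
#'   `rotation`, `dv_names`, `heywood` (flag vector), `R` (correlation
#'   matrix used).
#' @export
fit_efa <- function(x, f, seed = 1, n_rotation_starts = 10) {
  stopifnot(inherits(x, "dv_matrix"))
  R <- stats::cor(x$values)
  fit_efa_cor(R, n_obs = nrow(x$values), f = f, seed = seed,
              n_rotation_starts = n_rotation_starts)
}

#' Fit an EFA directly from a correlation matrix
#'
#' @param R Correlation matrix (symmetric, unit diagonal).
#' @param n_obs Number of observations behind `R`.
#' @param f Number of factors.
#' @param seed,n_rotation_starts As in [fit_efa()].
#' @return A `factor_model` (see [fit_efa()]).
#' @export
fit_efa_cor <- function(R, n_obs, f, seed = 1, n_rotation_starts = 10) {
  m <- ncol(R)
  if (f >= m) stop("number of factors (", f, ") must be < number of DVs (", m, ")")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    R <- R + diag(1e-8, m)
    R <- stats::cov2cor(R)
    message("correlation matrix near-singular; ridge-regularized by 1e-8")
  }
  fa <- tryCatch(
    stats::factanal(covmat = R, factors = f, n.obs = n_obs, rotation = "none",
                    control = list(nstart = 1, lower = 0.001,
                                   opt = list(factr = 1e4))),
    error = function(e) stop("ML factor fit failed for f = ", f, ": ",
                             conditionMessage(e)))
  A <- matrix(fa$loadings, m, f)
  # the boundary candidate (no common variance: L = 0, Psi = 1) can match or
  # beat the reported optimum when R carries no shared signal (e.g. exactly
  # identity, where ML is non-unique); prefer it as the parsimonious tie-break
  null_disc <- -determinant(R, logarithm = TRUE)$modulus[1]
  if (is.finite(null_disc) &&
      null_disc <= as.numeric(fa$criteria["objective"]) + 1e-10) {
    A[] <- 0
    fa$uniquenesses[] <- 1
    fa$criteria["objective"] <- null_disc
    if (!is.null(fa$STATISTIC))
      fa$STATISTIC[] <- max((n_obs - 1 - (2 * m + 5) / 6 - 2 * f / 3) *
                              null_disc, 0)
  }
  rot <- rotate_oblimin(A, n_starts = n_rotation_starts, seed = seed)
  L <- rot$loadings
  Phi <- rot$Phi
  psi <- as.numeric(fa$uniquenesses)
  h2 <- diag(L %*% Phi %*% t(L))
  df <- ((m - f)^2 - (m + f)) / 2
  chi2 <- if (!is.null(fa$STATISTIC)) as.numeric(fa$STATISTIC) else NA_real_
  if (is.na(chi2)) {
    # Bartlett-corrected likelihood-ratio statistic from the ML discrepancy
    Sigma <- L %*% Phi %*% t(L) + diag(psi, m)
    disc <- log(det(Sigma)) - log(det(R)) +
      sum(diag(solve(Sigma, R))) - m
    chi2 <- max((n_obs - 1 - (2 * m + 5) / 6 - 2 * f / 3) * disc, 0)
  }
  bic <- if (df > 0) chi2 - df * log(n_obs) else NA_real_
  W <- tenberge_weights(R, L, Phi)
  dv_names <- colnames(R)
  if (is.null(dv_names)) dv_names <- paste0("dv", seq_len(m))
  rownames(L) <- rownames(W) <- dv_names
  structure(list(loadings = L, Phi = Phi, uniqueness = psi, weights = W,
                 communality = stats::setNames(h2, dv_names), n_factors = f,
                 fit = list(chi2 = chi2, df = df, bic = bic, n_obs = n_obs,
                            criterion = as.numeric(fa$criteria["objective"])),
                 rotation = "oblimin", dv_names = dv_names,
                 heywood = psi <= 0.001 + 1e-12, R = R),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> ", length(x$dv_names), " DVs, ", x$n_factors,
      " oblimin factors; BIC = ", round(x$fit$bic, 1),
      if (any(x$heywood)) paste0("; ", sum(x$heywood), " Heywood case(s)"),
      "\n", sep = "")
  invisible(x)
}

# ten Berge correlation-preserving factor-score weights for oblique factors:
# with L* = L Phi^(1/2), C = R^(-1/2) L* (L*' R^(-1) L*)^(-1/2),
# W = R^(-1/2) C Phi^(1/2); then cor(Z W) = Phi when the model holds.
tenberge_weights <- function(R, L, Phi) {
  Phi_h <- mat_sqrt(Phi)
  Ls <- L %*% Phi_h
  R_ih <- mat_sqrt(R, inverse = TRUE)
  M <- t(Ls) %*% solve(R, Ls)
  C <- R_ih %*% Ls %*% mat_sqrt((M + t(M)) / 2, inverse = TRUE)
  R_ih %*% C %*% Phi_h
}

#' Sweep candidate dimensionalities and select by BIC
#'
#' Fits the EFA at each candidate number of factors and selects the
#' converged fit minimizing BIC = chi^2 - df * log(n), with the
#' Bartlett-corrected likelihood-ratio chi^2 and
#' df = ((m - f)^2 - (m + f)) / 2.
#'
#' @param x A [dv_matrix()].
#' @param f_candidates Integer vector of candidate factor numbers; default
#'   `1:min(floor(m/3), 25)`.
#' @param seed Seed forwarded to each fit's rotation.
#' @return An object of class `dimensionality_sweep`: data frame `sweep`
#'   (`f`, `bic`, `chi2`, `df`, `converged`), `best_f`, and `best_model`.
#' @export
select_dimensionality <- function(x, f_candidates = NULL, seed = 1) {
  stopifnot(inherits(x, "dv_matrix"))
  m <- ncol(x$values)
  if (is.null(f_candidates)) f_candidates <- seq_len(min(floor(m / 3), 25))
  f_candidates <- sort(unique(as.integer(f_candidates)))
  if (!length(f_candidates) || any(f_candidates >= m) || any(f_candidates < 1))
    stop("f_candidates must be a nonempty set of integers in [1, m)")
  R <- stats::cor(x$values)
  n <- nrow(x$values)
  fits <- lapply(f_candidates, function(f)
    tryCatch(fit_efa_cor(R, n, f, seed = seed), error = function(e) NULL))
  sweep_df <- data.frame(
    f = f_candidates,
    bic = vapply(fits, function(m_) if (is.null(m_)) NA_real_ else m_$fit$bic, 0),
    chi2 = vapply(fits, function(m_) if (is.null(m_)) NA_real_ else m_$fit$chi2, 0),
    df = vapply(fits, function(m_) if (is.null(m_)) NA_real_ else m_$fit$df, 0),
    converged = !vapply(fits, is.null, TRUE))
  ok <- which(sweep_df$converged & is.finite(sweep_df$bic))
  if (!length(ok)) stop("no candidate dimensionality converged with finite BIC")
  best <- ok[which.min(sweep_df$bic[ok])]
  structure(list(sweep = sweep_df, best_f = f_candidates[best],
                 best_model = fits[[best]]),
            class = "dimensionality_sweep")
}

#' @export
print.dimensionality_sweep <- function(x, ...) {
  cat("<dimensionality_sweep> candidates ", min(x$sweep$f), "..",
      max(x$sweep$f), "; best_f = ", x$best_f, " (BIC = ",
      round(x$sweep$bic[x$sweep$f == x$best_f], 1), ")\n", sep = "")
  invisible(x)
}

#' ten Berge factor scores for the fitting sample
#'
#' @param model A `factor_model`.
#' @param x The [dv_matrix()] to score (standardized internally with its own
#'   means/sds); must contain exactly the model's DVs.
#' @return An object of class `factor_scores`: `scores` (n x f), `method`.
#' @export
factor_scores <- function(model, x) {
  apply_weights(model, x)
}

#' Apply a frozen weight matrix to (new) data
#'
#' Computes factor scores for new participants under the model's score
#' weights. The new data are standardized with their own sample means and
#' standard deviations (switchable), so the same linear combination of
#' standardized DVs is applied at both time points.
#'
#' @param model A `factor_model`.
#' @param x A [dv_matrix()] containing the model's DVs.
#' @param scaling `"own"` (default; standardize with `x`'s own statistics)
#'   — the alternative `"none"` assumes `x` is already standardized.
#' @return A `factor_scores` object.
#' @export
apply_weights <- function(model, x, scaling = c("own", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(model, "factor_model"), inherits(x, "dv_matrix"))
  missing_dv <- setdiff(model$dv_names, colnames(x$values))
  extra_dv <- setdiff(colnames(x$values), model$dv_names)
  if (length(missing_dv))
    stop("data missing model DVs: ", paste(utils::head(missing_dv, 5), collapse = ", "))
  xx <- if (length(extra_dv)) subset_dvs(x, dvs = model$dv_names) else x
  Z <- xx$values[, model$dv_names, drop = FALSE]
  if (scaling == "own") Z <- scale(Z)
  S <- Z %*% model$weights
  colnames(S) <- paste0("F", seq_len(ncol(S)))
  rownames(S) <- xx$participant_ids
  structure(list(scores = S, method = "tenBerge"), class = "factor_scores")
}

#' Bootstrap stability of factor loadings
#'
#' Refits the EFA on `n_boot` random 90% subsamples (without replacement, the
#' default; switch to case resampling with `replace = TRUE`), aligns each
#' refit to the base solution, and returns element-wise mean and sd of the
#' aligned loadings.
#'
#' @param x A [dv_matrix()].
#' @param f Number of factors.
#' @param n_boot Number of subsamples.
#' @param keep_frac Fraction of participants kept per subsample.
#' @param seed Integer seed.
#' @param replace Resample with replacement instead of subsampling.
#' @return List with `mean`, `sd` (m x f matrices), `base` (the base
#'   `factor_model`), `n_failed`.
#' @export
bootstrap_loadings <- function(x, f, n_boot = 1000, keep_frac = 0.9, seed = 1,
                               replace = FALSE) {
  stopifnot(inherits(x, "dv_matrix"))
  base <- fit_efa(x, f, seed = seed)
  n <- nrow(x$values)
  keep_n <- if (replace) n else max(round(keep_frac * n), f + 2)
  rs <- restore_rng_state(); on.exit(rs(), add = TRUE)
  set.seed(seed)
  acc <- matrix(0, length(base$dv_names), f)
  acc2 <- matrix(0, length(base$dv_names), f)
  n_ok <- 0L; n_fail <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, keep_n, replace = replace)
    fit <- tryCatch(
      fit_efa_cor(stats::cor(x$values[idx, , drop = FALSE]), keep_n, f,
                  seed = seed + b, n_rotation_starts = 2),
      error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1L; next }
    L_al <- align_factors(base$loadings, fit$loadings)$loadings
    acc <- acc + L_al
    acc2 <- acc2 + L_al^2
    n_ok <- n_ok + 1L
  }
  if (n_fail > 0.1 * n_boot)
    stop(n_fail, "/", n_boot, " bootstrap refits failed")
  mu <- acc / n_ok
  sd_ <- sqrt(pmax(acc2 / n_ok - mu^2, 0) * n_ok / max(n_ok - 1, 1))
  dimnames(mu) <- dimnames(sd_) <- dimnames(base$loadings)
  list(mean = mu, sd = sd_, base = base, n_failed = n_fail)
}

#' Leave-one-measure-out robustness of the factor solution
#'
#' Drops each measure (all of its DVs) in turn, refits the EFA, aligns to the
#' base solution over the shared DVs, and reports per-factor Tucker
#' congruence.
#'
#' @param x A [dv_matrix()].
#' @param f Number of factors.
#' @param seed Seed forwarded to fits.
#' @return Data frame with one row per dropped measure and columns
#'   `measure`, `n_dvs_dropped`, `congruence_F1` ... `congruence_Ff`,
#'   `mean_congruence`; skipped measures (refit impossible) carry NA.
#' @export
drop_measure_robustness <- function(x, f, seed = 1) {
  stopifnot(inherits(x, "dv_matrix"))
  measures <- unique(x$dv_meta$measure)
  if (length(measures) < 2) stop("need at least 2 measures")
  base <- fit_efa(x, f, seed = seed)
  rows <- lapply(measures, function(ms) {
    keep <- x$dv_meta$dv_name[x$dv_meta$measure != ms]
    n_drop <- sum(x$dv_meta$measure == ms)
    if (length(keep) <= f) {
      warning("dropping measure '", ms, "' leaves m <= f; skipped")
      return(c(rep(NA_real_, f), NA_real_, n_drop))
    }
    fit <- tryCatch(fit_efa(subset_dvs(x, dvs = keep), f, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit)) return(c(rep(NA_real_, f), NA_real_, n_drop))
    cong <- align_factors(base$loadings[keep, , drop = FALSE],
                          fit$loadings)$congruence
    c(cong, mean(cong), n_drop)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(paste0("congruence_F", seq_len(f)), "mean_congruence",
                  "n_dvs_dropped")
  cbind(data.frame(measure = measures, stringsAsFactors = FALSE), out)
}

#' Reliability of factor scores across two sessions
#'
#' Per-factor Pearson r and ICC(3,k) between matched T1/T2 factor scores,
#' plus a 2-D principal-component projection of the stacked scores with the
#' variance it explains (for stability visualization).
#'
#' @param scores_t1,scores_t2 `factor_scores` objects (or score matrices)
#'   with matching rows (participants) and columns (factors).
#' @return List with `table` (per-factor `pearson_r`, `icc3k`),
#'   `pca_coords` (2n x 2, T1 rows then T2 rows), `pca_var_explained`.
#' @export
factor_score_reliability <- function(scores_t1, scores_t2) {
  S1 <- if (inherits(scores_t1, "factor_scores")) scores_t1$scores else as.matrix(scores_t1)
  S2 <- if (inherits(scores_t2, "factor_scores")) scores_t2$scores else as.matrix(scores_t2)
  stopifnot(all(dim(S1) == dim(S2)))
  if (nrow(S1) < 3) stop("need at least 3 matched participants")
  r <- vapply(seq_len(ncol(S1)), function(j) stats::cor(S1[, j], S2[, j]), 0)
  icc <- vapply(seq_len(ncol(S1)), function(j) icc3k_one(cbind(S1[, j], S2[, j])), 0)
  pc <- stats::prcomp(rbind(S1, S2), center = TRUE, scale. = FALSE)
  kd <- min(2L, ncol(pc$x))
  ve <- sum(pc$sdev[seq_len(kd)]^2) / sum(pc$sdev^2)
  list(table = data.frame(factor = paste0("F", seq_len(ncol(S1))),
                          pearson_r = r, icc3k = icc),
       pca_coords = pc$x[, seq_len(kd), drop = FALSE],
       pca_var_explained = ve)
}

#' Serialize a factor model to JSON
#'
#' @param model A `factor_model`.
#' @param path Output JSON path.
#' @export
write_factor_model <- function(model, path) {
  obj <- list(dv_names = model$dv_names, n_factors = model$n_factors,
              rotation = model$rotation,
              loadings = unname(model$loadings), Phi = model$Phi,
              uniqueness = model$uniqueness, weights = unname(model$weights),
              communality = unname(model$communality), fit = model$fit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
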