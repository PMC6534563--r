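# Task-survey separability: sparse partial-correlation graph over all DVs
# (graphical lasso, penalty chosen by extended BIC) and held-out
# cross-category prediction of each DV.

#' Sparse partial-correlation graph via the graphical lasso
#'
#' Estimates an L1-penalized precision matrix over the DV correlation matrix
#' on a log-spaced penalty grid, selects the penalty minimizing the extended
#' BIC, and reports partial correlations
#' `rho_ij = -omega_ij / sqrt(omega_ii * omega_jj)`.
#'
#' @param x A [dv_matrix()].
#' @param ebic_gamma Extended-BIC hyperparameter (default 0.5).
#' @param lambda_grid Penalty grid; default 100 log-spaced values in
#'   `[0.01 * lambda_max, lambda_max]` where `lambda_max` is the largest
#'   absolute off-diagonal correlation.
#' @param n_lambda Grid size when `lambda_grid` is NULL.
#' @return Object of class `pcorr_graph`: `pcorr` (m x m partial
#'   correlations, unit diagonal), `Theta` (precision), `edges` (data frame
#'   `dv_i`, `dv_j`, `pcorr` for nonzero entries), `lambda_selected`,
#'   `ebic_gamma`, `ebic_path`, `dv_meta`.
#' @export
fit_partial_correlation_graph <- function(x, ebic_gamma = 0.5,
                                          lambda_grid = NULL, n_lambda = 100) {
  stopifnot(inherits(x, "dv_matrix"))
  n <- nrow(x$values)
  if (n <= 3) stop("need n > 3 participants")
  S <- stats::cor(x$values)
  m <- ncol(S)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    S <- stats::cov2cor(S + diag(1e-8, m))
    message("empirical correlation near-singular; ridge-regularized by 1e-8")
  }
  if (is.null(lambda_grid)) {
    lam_max <- max(abs(S[upper.tri(S)]))
    lambda_grid <- exp(seq(log(lam_max), log(0.01 * lam_max),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)  # warm starts downward
  W <- S + diag(lambda_grid[1], m)
  B <- matrix(0, m, m)
  path <- data.frame(lambda = lambda_grid, ebic = NA_real_,
                     n_edges = NA_integer_, converged = NA)
  best <- NULL
  seen_patterns <- list()
  cached_fits <- list()
  for (i in seq_along(lambda_grid)) {
    fit <- glasso_cpp(S, matrix(lambda_grid[i], m, m), W, B)
    W <- fit$W; B <- fit$B
    A <- abs(fit$Theta) > 1e-8; diag(A) <- FALSE
    E <- sum(A) / 2
    pattern <- which(A[upper.tri(A)])
    hit <- 0L
    for (k in seq_along(seen_patterns))
      if (identical(seen_patterns[[k]], pattern)) { hit <- k; break }
    if (hit == 0L) {
      # EBIC is evaluated at the MLE constrained to this edge pattern
      # (zero penalty on allowed edges, effectively infinite elsewhere)
      Rho_c <- ifelse(A, 0, 1e6); diag(Rho_c) <- 0
      refit <- glasso_cpp(S, Rho_c, S + diag(1e-8, m), matrix(0, m, m))
      ld <- determinant(refit$Theta, logarithm = TRUE)
      ebic <- if (ld$sign <= 0) NA_real_ else {
        loglik <- (n / 2) * (as.numeric(ld$modulus) - sum(S * refit$Theta))
        -2 * loglik + E * log(n) + 4 * E * ebic_gamma * log(m)
      }
      seen_patterns[[length(seen_patterns) + 1]] <- pattern
      cached_fits[[length(cached_fits) + 1]] <- list(ebic = ebic,
                                                     Theta = refit$Theta)
      hit <- length(seen_patterns)
    }
    cached <- cached_fits[[hit]]
    path$ebic[i] <- cached$ebic; path$n_edges[i] <- E
    path$converged[i] <- fit$converged
    if (!is.na(cached$ebic) && (is.null(best) || cached$ebic < best$ebic))
      best <- list(Theta = cached$Theta, lambda = lambda_grid[i],
                   ebic = cached$ebic)
  }
  if (is.null(best)) stop("graphical lasso failed to produce a valid fit")
  Theta <- best$Theta
  dsq <- sqrt(diag(Theta))
  pcorr <- -Theta / outer(dsq, dsq)
  diag(pcorr) <- 1
  dimnames(pcorr) <- dimnames(S)
  ut <- which(upper.tri(pcorr) & abs(pcorr) > 1e-8, arr.ind = TRUE)
  edges <- data.frame(dv_i = rownames(pcorr)[ut[, 1]],
                      dv_j = colnames(pcorr)[ut[, 2]],
                      pcorr = pcorr[ut], stringsAsFactors = FALSE)
  structure(list(pcorr = pcorr, Theta = Theta, edges = edges,
                 lambda_selected = best$lambda, ebic_gamma = ebic_gamma,
                 ebic_path = path, dv_meta = x$dv_meta),
            class = "pcorr_graph")
}

#' @export
print.pcorr_graph <- function(x, ...) {
  cat("<pcorr_graph> ", nrow(x$pcorr), " DVs, ", nrow(x$edges),
      " edges; lambda = ", signif(x$lambda_selected, 3),
      " (EBIC gamma = ", x$ebic_gamma, ")\n", sep = "")
  invisible(x)
}

#' Threshold a partial-correlation graph and export edge lists
#'
#' Keeps edges with `|pcorr| >= min_abs_pcorr`, writes a weighted edge-list
#' CSV and a GraphML file, and summarizes edge density within tasks, within
#' surveys, and across categories.
#'
#' @param graph A `pcorr_graph`.
#' @param min_abs_pcorr Threshold (the figure-style 0.05 or the
#'   methods-style 0.01).
#' @param path Optional CSV path for the edge list.
#' @param graphml_path Optional GraphML output path.
#' @return List with `edges` (thresholded), `density` (per block: realized
#'   edges / possible edges).
#' @export
threshold_and_export <- function(graph, min_abs_pcorr = 0.05, path = NULL,
                                 graphml_path = NULL) {
  stopifnot(inherits(graph, "pcorr_graph"))
  ed <- graph$edges[abs(graph$edges$pcorr) >= min_abs_pcorr, , drop = FALSE]
  cat_of <- stats::setNames(graph$dv_meta$category, graph$dv_meta$dv_name)
  n_cat <- table(factor(graph$dv_meta$category,
                        levels = unique(graph$dv_meta$category)))
  block <- function(c1, c2) {
    if (!c1 %in% names(n_cat) || !c2 %in% names(n_cat)) return(NA_real_)
    possible <- if (c1 == c2) n_cat[[c1]] * (n_cat[[c1]] - 1) / 2
    else n_cat[[c1]] * n_cat[[c2]]
    if (possible == 0) return(NA_real_)
    got <- sum((cat_of[ed$dv_i] == c1 & cat_of[ed$dv_j] == c2) |
                 (cat_of[ed$dv_i] == c2 & cat_of[ed$dv_j] == c1))
    got / possible
  }
  density <- c(within_task = block("task", "task"),
               within_survey = block("survey", "survey"),
               cross = block("task", "survey"))
  if (!is.null(path))
    utils::write.table(ed, path, sep = ",", row.names = FALSE, quote = TRUE)
  if (!is.null(graphml_path))
    write_graphml(graph$dv_meta, ed, graphml_path)
  list(edges = ed, density = density)
}

write_graphml <- function(dv_meta, edges, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="category" for="node" attr.name="category" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  for (i in seq_len(nrow(dv_meta)))
    writeLines(sprintf('    <node id="%s"><data key="category">%s</data></node>',
                       esc(dv_meta$dv_name[i]), esc(dv_meta$category[i])), con)
  for (i in seq_len(nrow(edges)))
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="weight">%.10g</data></edge>',
      esc(edges$dv_i[i]), esc(edges$dv_j[i]), edges$pcorr[i]), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}

#' Held-out prediction of each DV from own- and other-category DVs
#'
#' Every DV is predicted twice with 10-fold cross-validated ridge regression
#' (penalty selected by internal leave-one-out): once from all other task
#' DVs and once from all other survey DVs, always excluding the predicted DV
#' itself. Comparing the four target-category x predictor-category
#' combinations quantifies how separable the two measurement categories are.
#'
#' @param x A [dv_matrix()] with both task and survey DVs.
#' @param k Number of CV folds.
#' @param seed Integer seed (fold construction).
#' @return Data frame of class `cross_prediction_table`: `dv_name`,
#'   `target_category`, `predictor_set`, `cv_r2`.
#' @export
cross_category_prediction <- function(x, k = 10, seed = 1) {
  stopifnot(inherits(x, "dv_matrix"))
  cats <- c("task", "survey")
  if (!all(cats %in% x$dv_meta$category))
    stop("need both task and survey DVs")
  vals <- x$values
  rows <- list()
  for (target_cat in intersect(cats, unique(x$dv_meta$category))) {
    targets <- x$dv_meta$dv_name[x$dv_meta$category == target_cat]
    for (pred_cat in cats) {
      pool <- x$dv_meta$dv_name[x$dv_meta$category == pred_cat]
      for (dv in targets) {
        preds <- setdiff(pool, dv)
        if (!length(preds)) stop("empty predictor set for ", dv)
        res <- cv_predict(vals[, preds, drop = FALSE], vals[, dv],
                          model = "ridge", k = k, seed = seed)
        rows[[length(rows) + 1]] <- data.frame(
          dv_name = dv, target_category = target_cat,
          predictor_set = pred_cat, cv_r2 = res$cv_r2,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cross_prediction_table", "data.frame")
  out
}

#' Summarize a cross-prediction table
#'
#' @param tab A `cross_prediction_table`.
#' @return Data frame of mean cv R^2 per target/predictor combination.
#' @export
summarize_cross_prediction <- function(tab) {
  stats::aggregate(cv_r2 ~ target_category + predictor_set, data = tab, FUN = mean)
}
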