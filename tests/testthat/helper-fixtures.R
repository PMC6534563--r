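# Shared fixtures: all test data are generated in code.

make_meta <- function(dv_names, category = "task",
                      measure = paste0("meas_", dv_names)) {
  data.frame(dv_name = dv_names, measure = measure, category = category,
             stringsAsFactors = FALSE)
}

toy_matrix <- function(n = 6, m = 3, seed = 1, category = "task") {
  set.seed(seed)
  vals <- matrix(rnorm(n * m), n, m,
                 dimnames = list(NULL, paste0("dv", seq_len(m))))
  dv_matrix(vals, sprintf("p%02d", seq_len(n)), make_meta(colnames(vals),
                                                          category))
}

# A small battery generated from an explicit loading matrix (unit-variance
# DVs), for tests that need direct control over planted structure.
battery_from_loadings <- function(L, n, Phi = diag(ncol(L)), seed = 1,
                                  category = "task",
                                  measure = NULL, noise_sd = NULL) {
  set.seed(seed)
  m <- nrow(L)
  h2 <- diag(L %*% Phi %*% t(L))
  if (is.null(noise_sd)) noise_sd <- sqrt(pmax(1 - h2, 1e-6))
  f <- ncol(L)
  F <- matrix(rnorm(n * f), n, f) %*% chol(Phi)
  X <- F %*% t(L) + sweep(matrix(rnorm(n * m), n, m), 2, noise_sd, "*")
  if (is.null(rownames(L))) rownames(L) <- sprintf("dv%02d", seq_len(m))
  colnames(X) <- rownames(L)
  if (is.null(measure)) measure <- paste0("meas_", colnames(X))
  list(x = dv_matrix(X, sprintf("p%04d", seq_len(n)),
                     make_meta(colnames(X), category, measure)),
       F = F)
}

# Block loading matrix: `per_block` DVs per factor, primary loadings drawn
# from `primary`, optional uniform cross-loadings.
block_loadings <- function(n_factors, per_block, primary = c(0.6, 0.8),
                           cross = 0, seed = 1) {
  set.seed(seed)
  m <- n_factors * per_block
  L <- matrix(runif(m * n_factors, -cross, cross), m, n_factors)
  for (b in seq_len(n_factors)) {
    rows <- ((b - 1) * per_block + 1):(b * per_block)
    L[rows, b] <- runif(per_block, primary[1], primary[2])
  }
  rownames(L) <- sprintf("f%d_dv%02d", rep(seq_len(n_factors), each = per_block),
                         seq_len(m))
  L
}

# All permutations of a vector (for brute-force oracles on small problems).
all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# Memoized 200 x 200 permutation-null calibration (shared by the type-I
# error check and the p-value uniformity check).
.calibration_cache <- new.env(parent = emptyenv())
null_calibration_pvalues <- function() {
  if (!is.null(.calibration_cache$p)) return(.calibration_cache$p)
  set.seed(424242)
  n <- 200; p_feat <- 6
  X <- matrix(rnorm(n * p_feat), n, p_feat)
  pvals <- vapply(seq_len(200), function(r) {
    y <- rnorm(n)
    permutation_null(X, y, model = "ridge", n_perm = 200, k = 10,
                     seed = 1000 + r)$p_value
  }, 0)
  .calibration_cache$p <- pvals
  pvals
}
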