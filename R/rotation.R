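# Oblique rotation by gradient projection, factor congruence and alignment.
# Rotation changes the basis of the latent space without changing model fit;
# alignment makes solutions from refits (bootstrap, measure dropout)
# comparable by resolving the permutation/sign indeterminacy.

# Direct quartimin (oblimin with gamma = 0) criterion and its gradient.
quartimin_criterion <- function(L) {
  L2 <- L^2
  N <- matrix(1, ncol(L), ncol(L)) - diag(ncol(L))
  M <- L2 %*% N
  list(f = sum(L2 * M) / 4, Gq = L * M)
}

# Gradient projection algorithm for oblique rotation (quartimin criterion).
# A: unrotated loadings; Tmat: starting rotation matrix with unit-norm columns.
gpa_oblique <- function(A, Tmat = diag(ncol(A)), maxit = 1000, eps = 1e-6) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  cr <- quartimin_criterion(L)
  f <- cr$f
  G <- -t(t(L) %*% cr$Gq %*% Ti)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 1:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Ti_t <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Ti_t)) {
        Lt <- A %*% t(Ti_t)
        crt <- quartimin_criterion(Lt)
        if (crt$f < f - 0.5 * s^2 * al) break
      }
      al <- al / 2
    }
    Tmat <- Tt; Ti <- Ti_t; L <- Lt; f <- crt$f
    G <- -t(t(L) %*% crt$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, Tmat = Tmat,
       criterion = f, converged = converged)
}

# Oblimin rotation with multiple seeded random starts; keeps the solution
# with the lowest criterion value, then orders factors by explained variance
# and fixes signs so each factor's dominant loadings are positive.
rotate_oblimin <- function(A, n_starts = 10, seed = 1) {
  f <- ncol(A)
  if (f == 1)
    return(list(loadings = A, Phi = matrix(1, 1, 1), criterion = 0,
                converged = TRUE))
  best <- gpa_oblique(A)
  if (n_starts > 1) {
    rs <- restore_rng_state()
    on.exit(rs(), add = TRUE)
    set.seed(seed)
    for (s in seq_len(n_starts - 1)) {
      X <- matrix(stats::rnorm(f * f), f, f)
      T0 <- X %*% diag(1 / sqrt(colSums(X^2)), f)
      cand <- tryCatch(gpa_oblique(A, T0), error = function(e) NULL)
      if (!is.null(cand) && cand$converged && cand$criterion < best$criterion - 1e-10)
        best <- cand
    }
  }
  canonicalize_solution(best$loadings, best$Phi, criterion = best$criterion,
                        converged = best$converged)
}

# Order factors by sum of squared loadings (descending) and flip signs so
# that the sum of each factor's loadings is non-negative.
canonicalize_solution <- function(L, Phi, ...) {
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, sgn, "*")
  Phi <- diag(sgn, length(sgn)) %*% Phi %*% diag(sgn, length(sgn))
  dimnames(Phi) <- NULL
  c(list(loadings = L, Phi = Phi), list(...))
}

# Hold the caller's RNG state so seeded internals don't disturb it.
restore_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
}

#' Tucker congruence between two loading matrices
#'
#' The congruence coefficient of factor j is the cosine between the j-th
#' columns: `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`.
#'
#' @param L1,L2 Loading matrices with the same dimensions (columns = factors).
#' @return Numeric vector of per-factor congruence coefficients in `[-1, 1]`.
#' @export
tucker_congruence <- function(L1, L2) {
  stopifnot(all(dim(L1) == dim(L2)))
  vapply(seq_len(ncol(L1)), function(j) {
    d <- sqrt(sum(L1[, j]^2) * sum(L2[, j]^2))
    if (d == 0) return(0)
    sum(L1[, j] * L2[, j]) / d
  }, 0)
}

# Cross-congruence matrix: C[j, l] = congruence(L1[, j], L2[, l]).
congruence_matrix <- function(L1, L2) {
  n1 <- sqrt(colSums(L1^2)); n2 <- sqrt(colSums(L2^2))
  n1[n1 == 0] <- 1; n2[n2 == 0] <- 1
  (t(L1) %*% L2) / outer(n1, n2)
}

# Exact solution of the linear assignment problem (minimize total cost) by
# the shortest-augmenting-path (Jonker-Volgenant) algorithm. Square cost
# matrix; returns for each row the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  INF <- Inf
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1                    # column indices offset by 1 (1 = virtual)
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1
  ans
}

#' Align a refit factor solution to a reference solution
#'
#' Resolves the column permutation and sign indeterminacy of a refit loading
#' matrix by maximizing the total absolute Tucker congruence with the
#' reference, solving the underlying assignment problem exactly.
#'
#' @param L_ref Reference loading matrix (m x f).
#' @param L_new Refit loading matrix to align (same dimensions).
#' @param Phi_new Optional factor correlation matrix of the refit, permuted
#'   and sign-flipped consistently.
#' @param W_new Optional score-weight matrix, transformed consistently.
#' @return List with `loadings`, `perm`, `signs`, `congruence` (per-factor,
#'   vs reference, after alignment), and `Phi`/`W` when supplied.
#' @export
align_factors <- function(L_ref, L_new, Phi_new = NULL, W_new = NULL) {
  stopifnot(all(dim(L_ref) == dim(L_new)))
  C <- congruence_matrix(L_ref, L_new)
  perm <- solve_assignment(-abs(C))   # maximize total |congruence|
  L_al <- L_new[, perm, drop = FALSE]
  sgn <- ifelse(diag(congruence_matrix(L_ref, L_al)) < 0, -1, 1)
  L_al <- sweep(L_al, 2, sgn, "*")
  out <- list(loadings = L_al, perm = perm, signs = sgn,
              congruence = tucker_congruence(L_ref, L_al))
  S <- diag(sgn, length(sgn))
  if (!is.null(Phi_new))
    out$Phi <- S %*% Phi_new[perm, perm, drop = FALSE] %*% S
  if (!is.null(W_new))
    out$W <- sweep(W_new[, perm, drop = FALSE], 2, sgn, "*")
  out
}

# Symmetric matrix square root and inverse square root via eigendecomposition.
mat_sqrt <- function(M, inverse = FALSE, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, tol)
  d <- if (inverse) 1 / sqrt(vals) else sqrt(vals)
  e$vectors %*% diag(d, length(d)) %*% t(e$vectors)
}
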