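# L2-penalized linear regression with the penalty selected by efficient
# leave-one-out error, computed in closed form from the eigendecomposition
# of X'X. Used for cross-category DV prediction and for outcome prediction.

default_ridge_grid <- function() 10^seq(-3, 3, length.out = 25)

# Fit ridge on (X, y) with internal LOO selection of lambda over `grid`.
# X is standardized internally (training statistics), y centered.
# Returns coefficients on the original scale plus standardized coefficients.
ridge_loo_fit <- function(X, y, grid = default_ridge_grid()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  mx <- colMeans(X)
  sx <- sqrt(pmax(colSums(X * X) - n * mx^2, 0) / (n - 1))
  sx[sx == 0] <- 1
  Z <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y)
  yc <- y - my
  e <- eigen(crossprod(Z), symmetric = TRUE)
  V <- e$vectors
  d <- pmax(e$values, 0)
  U <- Z %*% V                       # n x p, columns orthogonal, |u_k|^2 = d_k
  Uy <- as.numeric(crossprod(U, yc)) # length p
  # all penalties at once: shrinkage factors as a p x |grid| matrix
  SH <- 1 / (outer(d, grid, "+"))
  Yhat <- U %*% (Uy * SH)            # n x |grid| fitted values
  Hii <- (U^2) %*% SH                # n x |grid| leverages
  loo <- colMeans(((yc - Yhat) / pmax(1 - Hii, 1e-8))^2)
  lam <- grid[which.min(loo)]
  beta_z <- V %*% ((1 / (d + lam)) * Uy)   # standardized coefficients
  beta <- beta_z / sx
  intercept <- my - sum(beta * mx)
  list(lambda = lam, beta = as.numeric(beta),
       beta_std = as.numeric(beta_z), intercept = intercept,
       loo_mse = min(loo), x_center = mx, x_scale = sx, y_center = my)
}

ridge_predict <- function(fit, X_new) {
  as.numeric(as.matrix(X_new) %*% fit$beta + fit$intercept)
}
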