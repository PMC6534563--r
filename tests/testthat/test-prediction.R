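test_that("outcome targets recover planted dimensionality and shed covariates", {
  cfg <- battery_config(n_participants = 500, n_retest = 10,
                        task = list(n_dvs = 8, n_factors = 2),
                        survey = list(n_dvs = 24, n_factors = 6),
                        outcomes = list(n_outcome_factors = 3,
                                        dvs_per_factor = 4,
                                        target_r2 = c(0.2, 0.1, 0.05)),
                        seed = 5)
  gb <- generate_battery(cfg)
  oo <- generate_outcomes(gb$truth, cfg)
  tg <- derive_outcome_targets(oo$outcomes, oo$covariates,
                               f_candidates = 1:6, seed = 5)
  expect_equal(tg$sweep$best_f, 3)
  idx <- match(rownames(tg$scores$scores), oo$covariates$participant_id)
  expect_lt(max(abs(cor(tg$scores$scores, oo$covariates$age[idx]))), 0.05)
  expect_lt(max(abs(cor(tg$scores$scores, oo$covariates$sex[idx]))), 0.05)
})

test_that("balanced folds match the study's train/test split sizes", {
  set.seed(11)
  y <- rnorm(522)
  f <- balanced_kfold(y, k = 10, seed = 1)
  sizes <- as.integer(table(f))
  expect_setequal(unique(sizes), c(52L, 53L))
  expect_equal(sum(sizes == 53L), 2L)
  expect_equal(sort(unique(f)), 1:10)
  # leave-one-out limit
  f1 <- balanced_kfold(rnorm(30), k = 30, seed = 1)
  expect_equal(as.integer(table(f1)), rep(1L, 30))
  expect_error(balanced_kfold(rnorm(5), k = 10), "exceeds")
})

test_that("balanced folds equalize fold means better than random folds", {
  set.seed(13)
  y <- rexp(200)
  wins <- vapply(1:100, function(s) {
    bal <- balanced_kfold(y, 10, seed = s)
    set.seed(s + 5000)
    rnd <- sample(rep_len(1:10, 200))
    var(tapply(y, bal, mean)) < var(tapply(y, rnd, mean))
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("cross-validated ridge: exact feature, null features, OLS limit", {
  set.seed(17)
  X <- matrix(rnorm(300 * 5), 300, 5)
  res <- cv_predict(X, X[, 3], k = 10, seed = 1)
  expect_gt(res$cv_r2, 0.99)
  expect_lt(res$cv_mae, 0.05)

  null_r2 <- vapply(1:20, function(s) {
    Xs <- matrix(rnorm(500 * 17), 500, 17)
    cv_predict(Xs, rnorm(500), k = 10, seed = s)$cv_r2
  }, 0)
  expect_lt(mean(null_r2), 0.02)

  # ridge with penalty -> 0 equals OLS
  Xo <- matrix(rnorm(100 * 3), 100, 3)
  yo <- Xo %*% c(1, -2, 0.5) + rnorm(100)
  fit <- psychspace:::ridge_loo_fit(Xo, yo, grid = 1e-10)
  ols <- unname(coef(lm(yo ~ Xo)))
  expect_equal(c(fit$intercept, fit$beta), ols, tolerance = 1e-6)
})

test_that("planted linear signal is recovered at its population R^2", {
  r2s <- vapply(1:20, function(s) {
    set.seed(300 + s)
    n <- 500
    X <- matrix(rnorm(n * 8), n, 8)
    beta <- c(1, -0.8, 0.5, rep(0, 5))
    signal <- X %*% beta
    y <- sqrt(0.25) * signal / sd(signal) + sqrt(0.75) * rnorm(n)
    cv_predict(X, y, k = 10, seed = s)$cv_r2
  }, 0)
  expect_lt(abs(mean(r2s) - 0.25), 0.10)
})

test_that("leakage sentinels behave: target-in-features vs shuffled features", {
  set.seed(23)
  n <- 300
  y <- rnorm(n)
  X_leak <- cbind(y, matrix(rnorm(n * 4), n, 4))
  expect_gt(cv_predict(X_leak, y, k = 10, seed = 1)$cv_r2, 0.99)
  X_shuf <- X_leak[sample.int(n), ]
  expect_lt(cv_predict(X_shuf, y, k = 10, seed = 1)$cv_r2, 0.05)
})

test_that("regularized in-sample fit is optimistic on average", {
  diffs <- vapply(1:15, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(200 * 6), 200, 6)
    y <- X[, 1] * 0.3 + rnorm(200)
    r <- cv_predict(X, y, k = 10, seed = s)
    r$insample_r2 - r$cv_r2
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("permutation null: strong signal reaches the minimum p-value", {
  set.seed(31)
  n <- 500
  X <- matrix(rnorm(n * 8), n, 8)
  signal <- X %*% c(1, -1, 0.5, rep(0, 5))
  y <- sqrt(0.3) * signal / sd(signal) + sqrt(0.7) * rnorm(n)
  pn <- permutation_null(X, y, n_perm = 150, seed = 2)
  expect_equal(pn$p_value, 1 / 151)
  expect_length(pn$null_distribution, 150)
  expect_gt(pn$cv_r2, pn$null_95)
  expect_warning(permutation_null(X, y, n_perm = 50, seed = 2), "n_perm")
})

test_that("permutation p-values are calibrated and near-uniform under the null", {
  pvals <- null_calibration_pvalues()
  # type-I error at the 0.05 level
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
  # approximate uniformity
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fingerprints recover planted coefficient structure", {
  set.seed(41)
  n <- 500
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- 0.5 * X[, 4] + rnorm(n, 0, sqrt(1 - 0.25))
  res <- cv_predict(X, y, k = 10, seed = 1)
  expect_equal(which.max(abs(res$betas)), 4L, ignore_attr = TRUE)
  expect_true(all(abs(res$betas[-4]) < 0.1))

  # planted coefficient matrix: sign pattern of large entries recovered
  B <- matrix(0, 6, 3)
  B[1, 1] <- 0.6; B[3, 1] <- -0.4; B[2, 2] <- 0.5; B[5, 3] <- -0.6
  Y <- X %*% B + matrix(rnorm(n * 3), n, 3)
  results <- lapply(1:3, function(j) cv_predict(X, Y[, j], k = 10, seed = j))
  names(results) <- paste0("t", 1:3)
  fp <- fingerprint(results)
  big <- abs(B) >= 0.3
  expect_true(all(sign(t(fp))[big] == sign(B)[big]))
  expect_identical(fingerprint(results, "feature_wise"), t(fp))
})

test_that("alternate models run and the rf/svm path returns ridge betas", {
  set.seed(51)
  X <- matrix(rnorm(150 * 4), 150, 4)
  y <- X[, 1] + rnorm(150)
  for (mdl in c("lasso", "rf", "svm")) {
    r <- cv_predict(X, y, model = mdl, k = 5, seed = 1)
    expect_true(is.finite(r$cv_r2))
    expect_length(r$betas, 4)
  }
})
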