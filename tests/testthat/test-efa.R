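test_that("one-factor solution on a 3-variable problem matches the closed form", {
  # lambda_1 = sqrt(r12 * r13 / r23), etc.
  R <- matrix(c(1, .72, .63, .72, 1, .56, .63, .56, 1), 3, 3)
  fit <- fit_efa_cor(R, n_obs = 500, f = 1)
  expect_equal(unname(fit$loadings[, 1]), c(0.9, 0.8, 0.7), tolerance = 1e-3)
  expect_error(fit_efa_cor(R, 500, 3), "must be <")
})

test_that("an identity correlation matrix yields zero loadings", {
  fit <- fit_efa_cor(diag(6), n_obs = 2000, f = 1)
  expect_lt(max(abs(fit$loadings)), 1e-8)
  expect_lt(max(fit$communality), 1e-8)
})

test_that("a converged fit reconstructs the correlation matrix", {
  L <- block_loadings(3, 6, primary = c(0.6, 0.8), seed = 13)
  bat <- battery_from_loadings(L, n = 5000, seed = 13)
  fit <- fit_efa(bat$x, 3)
  Sigma <- fit$loadings %*% fit$Phi %*% t(fit$loadings) +
    diag(fit$uniqueness)
  expect_lt(max(abs(Sigma - fit$R)), 0.05)  # sampling-level discrepancy
})

test_that("BIC sweep recovers planted dimensionality", {
  cfg <- battery_config(n_participants = 500, n_retest = 10,
                        task = list(n_dvs = 30, n_factors = 5,
                                    primary_range = c(0.6, 0.8)),
                        survey = list(n_dvs = 8, n_factors = 2),
                        seed = 77)
  gb <- generate_battery(cfg)
  sw <- select_dimensionality(category_dvs(gb$battery, "task"), 2:8, seed = 1)
  expect_equal(sw$best_f, 5)
  expect_true(all(sw$sweep$converged))
  expect_identical(sw$best_model$n_factors, 5L)

  one <- battery_from_loadings(matrix(runif(10, .6, .8), 10, 1,
                                      dimnames = list(paste0("d", 1:10), NULL)),
                               n = 500, seed = 3)
  expect_equal(select_dimensionality(one$x, 1:4, seed = 1)$best_f, 1)
})

test_that("BIC sweep is reproducible under a fixed seed", {
  x <- toy_matrix(n = 200, m = 12, seed = 5)
  s1 <- select_dimensionality(x, 1:3, seed = 9)
  s2 <- select_dimensionality(x, 1:3, seed = 9)
  expect_identical(s1$sweep, s2$sweep)
  expect_identical(s1$best_model$loadings, s2$best_model$loadings)
})

test_that("ten Berge scores reproduce the factor correlation structure", {
  # orthogonal planted factors: score correlations near identity
  L <- block_loadings(3, 8, primary = c(0.65, 0.85), seed = 17)
  bat <- battery_from_loadings(L, n = 2000, seed = 17)
  fit <- fit_efa(bat$x, 3)
  sc <- factor_scores(fit, bat$x)
  expect_equal(colMeans(sc$scores), rep(0, 3), ignore_attr = TRUE,
               tolerance = 1e-10)
  # defining property: cor(scores) = Phi-hat
  expect_lt(max(abs(cor(sc$scores) - fit$Phi)), 0.02)
  # with orthogonal planting, Phi-hat itself is near identity
  expect_lt(max(abs(fit$Phi - diag(3))), 0.1)
  expect_true(all(abs(cor(sc$scores)[upper.tri(diag(3))]) < 0.1))
  # low-uniqueness structure: scores track the true factors
  al <- align_factors(L, fit$loadings)
  r_true <- vapply(1:3, function(j)
    abs(cor(sc$scores[, al$perm[j]], bat$F[, j])), 0)
  expect_true(all(r_true > 0.9))
})

test_that("frozen weights applied to the training data reproduce the scores", {
  L <- block_loadings(2, 6, seed = 23)
  bat <- battery_from_loadings(L, n = 300, seed = 23)
  fit <- fit_efa(bat$x, 2)
  s1 <- factor_scores(fit, bat$x)
  s2 <- apply_weights(fit, bat$x)
  expect_equal(s1$scores, s2$scores, tolerance = 1e-10)
  expect_error(apply_weights(fit, subset_dvs(bat$x, dvs = 1:5)), "missing")
})

test_that("factor scores on a retest session match analytic attenuation", {
  cfg <- battery_config(n_participants = 600, n_retest = 600,
                        task = list(n_dvs = 24, n_factors = 3,
                                    primary_range = c(0.5, 0.7),
                                    reliability_mean = 0.7,
                                    reliability_sd = 0.05),
                        survey = list(n_dvs = 8, n_factors = 2),
                        seed = 41)
  gb <- generate_battery(cfg)
  rp <- generate_retest(cfg, gb$truth, gb$battery)
  task_dvs <- gb$battery$dv_meta$dv_name[gb$battery$dv_meta$category == "task"]
  fit <- fit_efa(category_dvs(gb$battery, "task"), 3, seed = 2)
  s1 <- apply_weights(fit, subset_dvs(rp$t1, dvs = task_dvs))
  s2 <- apply_weights(fit, subset_dvs(rp$t2, dvs = task_dvs))
  fsr <- factor_score_reliability(s1, s2)
  # analytic score reliability under the planted model: the stable part of
  # w'z is w' (R - diag(session var)) w
  W <- fit$weights
  R_pop <- gb$truth$L[task_dvs, ] %*% gb$truth$Phi %*% t(gb$truth$L[task_dvs, ]) +
    diag(gb$truth$reliability[task_dvs] -
           gb$truth$communality[task_dvs]) +
    diag(gb$truth$session_sd[match(task_dvs, rownames(gb$truth$L))]^2)
  stable_pop <- R_pop - diag(gb$truth$session_sd[
    match(task_dvs, rownames(gb$truth$L))]^2)
  analytic <- diag(t(W) %*% stable_pop %*% W) / diag(t(W) %*% R_pop %*% W)
  expect_true(all(abs(fsr$table$pearson_r - analytic) < 0.05))
})

test_that("factor score reliability is 1 for identical sessions and the 2-D
          projection explains the top-2 eigenvalue share", {
  set.seed(51)
  S <- matrix(rnorm(100 * 4), 100, 4) %*% diag(c(3, 2, 1, 0.5))
  fsr <- factor_score_reliability(S, S)
  expect_equal(fsr$table$pearson_r, rep(1, 4))
  expect_equal(fsr$table$icc3k, rep(1, 4))
  ev <- eigen(cov(rbind(S, S)), symmetric = TRUE)$values
  expect_equal(fsr$pca_var_explained, sum(ev[1:2]) / sum(ev), tolerance = 1e-10)
})

test_that("bootstrap loadings: tight structure gives tiny sd, alignment is
          invariant to DV order", {
  L <- block_loadings(2, 6, primary = c(0.8, 0.9), seed = 61)
  bat <- battery_from_loadings(L, n = 800, seed = 61)
  b <- bootstrap_loadings(bat$x, 2, n_boot = 100, seed = 4)
  expect_lt(max(b$sd), 0.02)
  # element-wise mean close to the base fit
  expect_lt(max(abs(b$mean - b$base$loadings)), 0.02)
  perm <- sample(seq_len(nrow(L)))
  bp <- bootstrap_loadings(subset_dvs(bat$x, dvs = perm), 2, n_boot = 30,
                           seed = 4)
  b30 <- bootstrap_loadings(bat$x, 2, n_boot = 30, seed = 4)
  nm <- rownames(b30$mean)
  expect_equal(bp$mean[nm, ], b30$mean[nm, ], tolerance = 1e-6)
})

test_that("bootstrap loading sd shrinks with sample size", {
  L <- block_loadings(2, 5, primary = c(0.5, 0.7), seed = 71)
  small <- battery_from_loadings(L, n = 200, seed = 71)
  big <- battery_from_loadings(L, n = 2000, seed = 72)
  b_small <- bootstrap_loadings(small$x, 2, n_boot = 60, seed = 1)
  b_big <- bootstrap_loadings(big$x, 2, n_boot = 60, seed = 1)
  expect_gt(mean(b_big$sd < b_small$sd), 0.95)
})

test_that("dropping a measure only matters when it defines a factor", {
  set.seed(81)
  # 3 factors, each defined by one measure of 6 DVs, plus a null measure
  L <- rbind(block_loadings(3, 6, primary = c(0.65, 0.85), seed = 81),
             matrix(runif(12, -0.1, 0.1), 4, 3))
  rownames(L) <- sprintf("dv%02d", 1:22)
  measure <- c(rep(c("meas_a", "meas_b", "meas_c"), each = 6), rep("null_meas", 4))
  bat <- battery_from_loadings(L, n = 800, seed = 81, measure = measure)
  rob <- drop_measure_robustness(bat$x, 3, seed = 1)
  null_row <- rob[rob$measure == "null_meas", ]
  expect_true(all(null_row[paste0("congruence_F", 1:3)] > 0.98))
  defining <- rob[rob$measure == "meas_a", ]
  expect_lt(min(defining[paste0("congruence_F", 1:3)]), 0.8)
})
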