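test_that("generated correlations match the planted population structure", {
  cfg <- battery_config(n_participants = 50000, n_retest = 10,
                        task = list(n_dvs = 10, n_factors = 2),
                        survey = list(n_dvs = 10, n_factors = 2),
                        seed = 3)
  gb <- generate_battery(cfg)
  tr <- gb$truth
  pop <- tr$L %*% tr$Phi %*% t(tr$L) +
    diag(tr$reliability - tr$communality) + diag(tr$session_sd^2)
  emp <- cor(gb$battery$values)
  expect_lt(max(abs(emp - pop)), 0.02)
  # unit variances by construction
  expect_equal(unname(apply(gb$battery$values, 2, var)), rep(1, 20),
               tolerance = 0.03)
})

test_that("uncoupled categories show only sampling-level cross correlations", {
  cfg <- battery_config(n_participants = 5000, n_retest = 10,
                        task = list(n_dvs = 8, n_factors = 2),
                        survey = list(n_dvs = 8, n_factors = 2),
                        cross_category_corr = 0, seed = 7)
  gb <- generate_battery(cfg)
  R <- cor(gb$battery$values)
  cross <- R[gb$battery$dv_meta$category == "task",
             gb$battery$dv_meta$category == "survey"]
  expect_lt(mean(abs(cross)), 2 / sqrt(5000))
})

test_that("noise-free unit-reliability battery has rank = number of factors", {
  cfg <- battery_config(n_participants = 100, n_retest = 10,
                        task = list(n_dvs = 8, n_factors = 2,
                                    primary_range = c(1, 1),
                                    cross_range = c(0, 0)),
                        survey = list(n_dvs = 8, n_factors = 2,
                                      primary_range = c(1, 1),
                                      cross_range = c(0, 0)),
                        seed = 9)
  gb <- generate_battery(cfg)
  expect_equal(qr(gb$battery$values)$rank, 4)
  expect_equal(unname(gb$truth$reliability), rep(1, 16), tolerance = 1e-12)
})

test_that("retest sessions behave as the planted reliabilities dictate", {
  # perfect reliability: the two sessions are identical
  cfg1 <- battery_config(n_participants = 80, n_retest = 40,
                         task = list(n_dvs = 6, n_factors = 2,
                                     reliability = rep(1, 6)),
                         survey = list(n_dvs = 6, n_factors = 2,
                                       reliability = rep(1, 6)),
                         seed = 11)
  gb1 <- generate_battery(cfg1)
  rp1 <- generate_retest(cfg1, gb1$truth, gb1$battery)
  expect_equal(rp1$t1$values, rp1$t2$values, tolerance = 1e-12)

  # heterogeneous groups: survey mean retest r above task mean in every seed
  gaps <- vapply(1:5, function(s) {
    cfg <- battery_config(n_participants = 400, n_retest = 150,
                          task = list(n_dvs = 12, n_factors = 2),
                          survey = list(n_dvs = 12, n_factors = 2),
                          seed = 500 + s)
    gb <- generate_battery(cfg)
    rp <- generate_retest(cfg, gb$truth, gb$battery)
    tab <- retest_pearson(rp)
    is_task <- gb$battery$dv_meta$category == "task"
    mean(tab$pearson_r[!is_task]) - mean(tab$pearson_r[is_task])
  }, 0)
  expect_true(all(gaps > 0))
})

test_that("infeasible explicit reliability is rejected at generation", {
  cfg <- battery_config(n_participants = 100, n_retest = 10,
                        task = list(n_dvs = 6, n_factors = 2,
                                    primary_range = c(0.7, 0.9),
                                    reliability = rep(0.1, 6)),
                        survey = list(n_dvs = 6, n_factors = 2),
                        seed = 13)
  expect_error(generate_battery(cfg), "below communality")
  expect_error(battery_config(outcomes = list(target_r2 = 1.2)), "target R")
})

test_that("outcome generation hits the configured population R^2", {
  cfg <- battery_config(n_participants = 20000, n_retest = 10,
                        task = list(n_dvs = 6, n_factors = 2),
                        survey = list(n_dvs = 18, n_factors = 3),
                        outcomes = list(n_outcome_factors = 2,
                                        dvs_per_factor = 3,
                                        target_r2 = c(0.3, 0)),
                        seed = 17)
  gb <- generate_battery(cfg)
  oo <- generate_outcomes(gb$truth, cfg)
  Fs <- gb$truth$factor_scores[, 3:5]
  r2 <- vapply(1:2, function(k)
    summary(lm(oo$latents[, k] ~ Fs))$r.squared, 0)
  expect_lt(abs(r2[1] - 0.3), 0.02)
  expect_lt(r2[2], 0.01)
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- battery_config(n_participants = 60, n_retest = 20,
                        task = list(n_dvs = 6, n_factors = 2),
                        survey = list(n_dvs = 6, n_factors = 2),
                        seed = 19)
  g1 <- generate_battery(cfg)
  g2 <- generate_battery(cfg)
  expect_identical(g1$battery$values, g2$battery$values)
  expect_identical(g1$truth$L, g2$truth$L)
  r1 <- generate_retest(cfg, g1$truth, g1$battery)
  r2 <- generate_retest(cfg, g2$truth, g2$battery)
  expect_identical(r1$t2$values, r2$t2$values)
  o1 <- generate_outcomes(g1$truth, cfg)
  o2 <- generate_outcomes(g2$truth, cfg)
  expect_identical(o1$outcomes$values, o2$outcomes$values)
  expect_identical(o1$B, o2$B)
})
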