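# Synthetic battery generator with planted structure.
#
# Trait scores are drawn from N(0, Phi_joint), where Phi_joint couples the
# task-factor and survey-factor blocks at a configurable (weak) cross
# correlation. Each DV is
#     DV_i = L_i. f + s_i xi_i + e_i,
# with stable specific factor xi_i and session-only noise e_i, scaled so the
# DV has unit variance and retest reliability r_i = communality + s_i^2
# (reliability can never fall below communality: the signal cannot be less
# stable than the trait it carries). A second session redraws only e.
# Outcome DVs load on latent outcome traits that mix survey factors (via a
# coefficient matrix B) with independent variation so the survey-explained
# population R^2 per outcome is exactly the configured target.

#' Default generator configuration
#'
#' Emulates the study design: 522 participants with a 150-participant
#' retest, 129 task DVs on 5 oblique factors and 64 survey DVs on 12,
#' weakly correlated across categories; task reliabilities are heterogeneous
#' (mean 0.45, sd 0.21) and survey reliabilities high (mean 0.80, sd 0.06);
#' primary loading ranges are set so mean planted communalities sit near
#' 0.23 (task) and 0.58 (survey). Eight outcome traits are generated from
#' the survey factors with per-outcome target R^2 averaging about 0.1.
#'
#' @param n_participants,n_retest Sample sizes.
#' @param task,survey Per-category lists: `n_dvs`, `n_factors`,
#'   `primary_range`, `cross_range` (absolute value bounds; sign random),
#'   `phi_corr` (exchangeable factor correlation), `reliability_mean`,
#'   `reliability_sd`, `reliability_clip`, optional explicit `reliability`
#'   vector.
#' @param cross_category_corr Correlation between every task and survey
#'   factor pair.
#' @param outcomes List: `n_outcome_factors`, `dvs_per_factor`,
#'   `loading_range`, `target_r2` (vector, recycled), `b_nonzero` (survey
#'   factors feeding each outcome), `b_range`, `age_beta`, `sex_beta`.
#' @param seed Integer seed.
#' @return A list of class `generator_config`.
#' @export
battery_config <- function(n_participants = 522, n_retest = 150,
                           task = list(), survey = list(),
                           cross_category_corr = 0.1,
                           outcomes = list(), seed = 1) {
  task_def <- list(n_dvs = 129, n_factors = 5,
                   primary_range = c(0.30, 0.60), cross_range = c(0, 0.10),
                   phi_corr = 0.30, reliability_mean = 0.45,
                   reliability_sd = 0.21, reliability_clip = c(0.05, 0.95),
                   reliability = NULL)
  survey_def <- list(n_dvs = 64, n_factors = 12,
                     primary_range = c(0.60, 0.90), cross_range = c(0, 0.10),
                     phi_corr = 0.25, reliability_mean = 0.80,
                     reliability_sd = 0.06, reliability_clip = c(0.55, 0.98),
                     reliability = NULL)
  out_def <- list(n_outcome_factors = 8, dvs_per_factor = 3,
                  loading_range = c(0.70, 0.90),
                  target_r2 = c(0.29, 0.15, 0.12, 0.10, 0.08, 0.06, 0.05, 0.03),
                  b_nonzero = 3, b_range = c(0.3, 1),
                  age_beta = 0.15, sex_beta = 0.15)
  cfg <- list(n_participants = n_participants, n_retest = n_retest,
              task = utils::modifyList(task_def, task),
              survey = utils::modifyList(survey_def, survey),
              cross_category_corr = cross_category_corr,
              outcomes = utils::modifyList(out_def, outcomes),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 10, cfg$n_retest <= cfg$n_participants,
            cfg$cross_category_corr >= 0, cfg$cross_category_corr < 1)
  for (cat in c("task", "survey")) {
    cc <- cfg[[cat]]
    stopifnot(cc$n_dvs >= cc$n_factors, cc$n_factors >= 1,
              all(cc$primary_range >= 0), all(cc$primary_range <= 1))
  }
  if (any(cfg$outcomes$target_r2 < 0) || any(cfg$outcomes$target_r2 >= 1))
    stop("outcome target R^2 must lie in [0, 1)")
  Phi <- joint_phi(cfg)
  if (min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8)
    stop("joint factor correlation matrix is not positive definite")
  invisible(cfg)
}

joint_phi <- function(cfg) {
  ft <- cfg$task$n_factors; fs <- cfg$survey$n_factors
  f <- ft + fs
  Phi <- matrix(cfg$cross_category_corr, f, f)
  Phi[1:ft, 1:ft] <- cfg$task$phi_corr
  Phi[(ft + 1):f, (ft + 1):f] <- cfg$survey$phi_corr
  diag(Phi) <- 1
  Phi
}

# Draw the planted joint loading matrix and per-DV metadata/reliabilities.
plant_structure <- function(cfg) {
  ft <- cfg$task$n_factors; fs <- cfg$survey$n_factors
  m <- cfg$task$n_dvs + cfg$survey$n_dvs
  L <- matrix(0, m, ft + fs)
  block <- integer(m)
  cat_v <- character(m)
  name_v <- character(m)
  reliab <- numeric(m)
  Phi <- joint_phi(cfg)
  row <- 0
  for (cat in c("task", "survey")) {
    cc <- cfg[[cat]]
    off <- if (cat == "task") 0 else ft
    blocks <- rep(seq_len(cc$n_factors), length.out = cc$n_dvs)
    blocks <- sort(blocks)
    for (i in seq_len(cc$n_dvs)) {
      row <- row + 1
      b <- blocks[i]
      for (attempt in 1:50) {
        lrow <- numeric(ft + fs)
        lrow[off + b] <- stats::runif(1, cc$primary_range[1], cc$primary_range[2])
        others <- setdiff(seq_len(cc$n_factors), b)
        lrow[off + others] <- stats::runif(length(others), cc$cross_range[1],
                                           cc$cross_range[2]) *
          sample(c(-1, 1), length(others), replace = TRUE)
        h2 <- drop(t(lrow) %*% Phi %*% lrow)
        if (h2 <= 0.98) break  # redraw pathological rows (unless forced)
      }
      L[row, ] <- lrow
      block[row] <- off + b
      cat_v[row] <- cat
      name_v[row] <- sprintf("%s_f%02d_dv%03d", cat, b, i)
      h2 <- drop(t(lrow) %*% Phi %*% lrow)
      r_i <- if (!is.null(cc$reliability)) {
        cc$reliability[i]
      } else {
        min(max(stats::rnorm(1, cc$reliability_mean, cc$reliability_sd),
                cc$reliability_clip[1]), cc$reliability_clip[2])
      }
      if (!is.null(cc$reliability) && r_i < h2)
        stop("configured reliability ", round(r_i, 3), " below communality ",
             round(h2, 3), " for DV ", name_v[row])
      # floor at communality (+ a small stable-specific margin when possible)
      reliab[row] <- max(r_i, min(h2 + 0.02, max(h2, 0.99)), h2)
    }
  }
  rownames(L) <- name_v
  list(L = L, Phi = Phi, block = block, category = cat_v, dv_names = name_v,
       reliability = reliab)
}

#' Generate a synthetic battery with planted ground truth
#'
#' @param cfg A [battery_config()].
#' @return List with `battery` (a [dv_matrix()] of task + survey DVs) and
#'   `truth` (class `ground_truth`): planted `L`, `Phi`, `reliability`,
#'   `cluster_labels` (factor-block ids), `factor_scores` (trait level),
#'   `stable_part`, `session_sd`, `category`, `config`.
#' @export
generate_battery <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  rs <- restore_rng_state(); on.exit(rs(), add = TRUE)
  set.seed(cfg$seed)
  pl <- plant_structure(cfg)
  n <- cfg$n_participants
  m <- nrow(pl$L)
  f <- ncol(pl$L)
  h2 <- diag(pl$L %*% pl$Phi %*% t(pl$L))
  s2 <- pl$reliability - h2          # stable specific variance, >= 0
  sess2 <- pmax(1 - pl$reliability, 0)
  Fscores <- matrix(stats::rnorm(n * f), n, f) %*% chol(pl$Phi)
  Xi <- matrix(stats::rnorm(n * m), n, m)
  stable <- Fscores %*% t(pl$L) + sweep(Xi, 2, sqrt(s2), "*")
  E1 <- sweep(matrix(stats::rnorm(n * m), n, m), 2, sqrt(sess2), "*")
  vals <- stable + E1
  colnames(vals) <- pl$dv_names
  ids <- sprintf("p%04d", seq_len(n))
  rownames(vals) <- ids
  meta <- data.frame(dv_name = pl$dv_names,
                     measure = sprintf("%s_meas%02d", pl$category, pl$block),
                     category = pl$category, stringsAsFactors = FALSE)
  battery <- dv_matrix(vals, ids, meta)
  truth <- structure(
    list(L = pl$L, Phi = pl$Phi,
         reliability = stats::setNames(pl$reliability, pl$dv_names),
         communality = stats::setNames(h2, pl$dv_names),
         cluster_labels = stats::setNames(pl$block, pl$dv_names),
         factor_scores = Fscores, stable_part = stable,
         session_sd = sqrt(sess2), category = pl$category,
         participant_ids = ids, config = cfg),
    class = "ground_truth")
  list(battery = battery, truth = truth)
}

#' Generate a retest session for a subsample
#'
#' The second session keeps traits and specific factors fixed and redraws
#' only the session noise; the retest subset is sampled uniformly.
#'
#' @param cfg The [battery_config()] used for the battery.
#' @param truth The `ground_truth` from [generate_battery()].
#' @param battery The first-session [dv_matrix()].
#' @return A [retest_pair()] over the `n_retest` subsample.
#' @export
generate_retest <- function(cfg, truth, battery) {
  stopifnot(inherits(truth, "ground_truth"))
  rs <- restore_rng_state(); on.exit(rs(), add = TRUE)
  set.seed(cfg$seed + 1000003L)
  n <- cfg$n_participants
  sub <- sort(sample.int(n, cfg$n_retest))
  m <- ncol(truth$stable_part)
  E2 <- sweep(matrix(stats::rnorm(length(sub) * m), length(sub), m), 2,
              truth$session_sd, "*")
  vals2 <- truth$stable_part[sub, , drop = FALSE] + E2
  ids <- truth$participant_ids[sub]
  rownames(vals2) <- ids
  t2 <- dv_matrix(vals2, ids, battery$dv_meta)
  t1 <- subset_dvs(battery, participants = ids)
  retest_pair(t1, t2)
}

#' Generate outcome DVs (and covariates) from the survey factors
#'
#' Latent outcome trait k is
#' `sqrt(R2_k) * std(F_survey B_k) + sqrt(1 - R2_k) * z_k`, so the
#' population R^2 of the trait given the survey factors equals the
#' configured target exactly. Each outcome DV loads on one trait, with age
#' and sex effects added (to be removed by residualization) and independent
#' noise.
#'
#' @param truth `ground_truth` from [generate_battery()].
#' @param cfg The [battery_config()].
#' @param covariates Optional [covariate_table()]; generated if missing
#'   (age ~ Uniform(18, 65), sex ~ Bernoulli(0.5)).
#' @return List with `outcomes` (a [dv_matrix()], category `"outcome"`),
#'   `covariates`, `latents` (n x K outcome traits), `B` (survey factors x
#'   outcomes), `target_r2`.
#' @export
generate_outcomes <- function(truth, cfg, covariates = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  rs <- restore_rng_state(); on.exit(rs(), add = TRUE)
  set.seed(cfg$seed + 2000003L)
  oc <- cfg$outcomes
  K <- oc$n_outcome_factors
  ft <- cfg$task$n_factors; fs <- cfg$survey$n_factors
  Fs <- truth$factor_scores[, (ft + 1):(ft + fs), drop = FALSE]
  Phi_s <- truth$Phi[(ft + 1):(ft + fs), (ft + 1):(ft + fs), drop = FALSE]
  r2 <- rep(oc$target_r2, length.out = K)
  B <- matrix(0, fs, K)
  for (k in seq_len(K)) {
    nz <- sample.int(fs, min(oc$b_nonzero, fs))
    B[nz, k] <- stats::runif(length(nz), oc$b_range[1], oc$b_range[2]) *
      sample(c(-1, 1), length(nz), replace = TRUE)
    if (r2[k] > 0 && all(B[, k] == 0))
      stop("target R^2 > 0 with all-zero coefficients for outcome ", k)
  }
  n <- cfg$n_participants
  pop_sd <- sqrt(pmax(diag(t(B) %*% Phi_s %*% B), 1e-12))
  U <- sweep(Fs %*% B, 2, pop_sd, "/")        # population-standardized
  Z <- matrix(stats::rnorm(n * K), n, K)
  latents <- sweep(U, 2, sqrt(r2), "*") + sweep(Z, 2, sqrt(1 - r2), "*")
  if (is.null(covariates)) {
    covariates <- covariate_table(truth$participant_ids,
                                  age = stats::runif(n, 18, 65),
                                  sex = stats::rbinom(n, 1, 0.5))
  }
  z_age <- as.numeric(scale(covariates$age))
  z_sex <- as.numeric(scale(covariates$sex))
  m_out <- K * oc$dvs_per_factor
  vals <- matrix(0, n, m_out)
  names_v <- character(m_out)
  j <- 0
  for (k in seq_len(K)) for (d in seq_len(oc$dvs_per_factor)) {
    j <- j + 1
    lam <- stats::runif(1, oc$loading_range[1], oc$loading_range[2])
    vals[, j] <- lam * latents[, k] +
      oc$age_beta * z_age + oc$sex_beta * z_sex +
      stats::rnorm(n, sd = sqrt(1 - lam^2))
    names_v[j] <- sprintf("outcome_f%02d_dv%02d", k, d)
  }
  colnames(vals) <- names_v
  rownames(vals) <- truth$participant_ids
  meta <- data.frame(dv_name = names_v,
                     measure = sprintf("outcome_meas%02d",
                                       rep(seq_len(K), each = oc$dvs_per_factor)),
                     category = "outcome", stringsAsFactors = FALSE)
  list(outcomes = dv_matrix(vals, truth$participant_ids, meta),
       covariates = covariates, latents = latents, B = B, target_r2 = r2)
}

#' Serialize ground truth to JSON (for recovery tests and audits)
#'
#' @param truth A `ground_truth`.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(dv_names = rownames(truth$L), L = unname(truth$L),
              Phi = truth$Phi, reliability = unname(truth$reliability),
              cluster_labels = unname(truth$cluster_labels),
              category = truth$category)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
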