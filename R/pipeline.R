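# End-to-end orchestration: reliability -> category association ->
# per-category EFA -> clustering/consensus -> outcome EFA -> prediction,
# with every artifact written as CSV/JSON plus a run manifest.

#' Build a pipeline configuration
#'
#' @param generator A [battery_config()] (synthetic input), or NULL when
#'   `input` paths are given.
#' @param input Optional list of file paths: `battery`, `battery_meta`,
#'   `retest_t2`, `outcomes`, `outcomes_meta`, `covariates` (CSV with
#'   participant_id, age, sex).
#' @param stages Character vector of stages to run, a subset of
#'   `c("reliability", "network", "efa", "clustering", "prediction")`.
#' @param efa Per-stage parameters: `f_candidates_task`,
#'   `f_candidates_survey`, `n_boot`.
#' @param clustering `min_cluster_size`, `deep_split`, `linkage`, `n_sim`,
#'   `drop_frac`.
#' @param network `ebic_gamma`, `n_lambda`, `edge_threshold`, plus
#'   `cross_prediction` (logical; the held-out DV analysis is the slowest
#'   stage).
#' @param prediction `model`, `k`, `n_perm`, `f_candidates_outcome`.
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = battery_config(), input = NULL,
                            stages = c("reliability", "network", "efa",
                                       "clustering", "prediction"),
                            efa = list(), clustering = list(),
                            network = list(), prediction = list(),
                            seed = 1, out_dir = "psychspace_results") {
  cfg <- list(
    generator = generator, input = input, stages = stages,
    efa = utils::modifyList(list(f_candidates_task = NULL,
                                 f_candidates_survey = NULL, n_boot = 100),
                            efa),
    clustering = utils::modifyList(list(min_cluster_size = 3, deep_split = 2,
                                        linkage = "average", n_sim = 500,
                                        drop_frac = 0.2), clustering),
    network = utils::modifyList(list(ebic_gamma = 0.5, n_lambda = 50,
                                     edge_threshold = 0.05,
                                     cross_prediction = FALSE), network),
    prediction = utils::modifyList(list(model = "ridge", k = 10, n_perm = 500,
                                        f_candidates_outcome = NULL),
                                   prediction),
    seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys as in [pipeline_config()], with
#'   `generator` keys forwarded to [battery_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$input)) NULL else do.call(battery_config,
                                                  if (is.null(y$generator)) list()
                                                  else y$generator)
  pipeline_config(generator = gen, input = y$input,
                  stages = if (is.null(y$stages)) c("reliability", "network",
                                                    "efa", "clustering",
                                                    "prediction") else y$stages,
                  efa = if (is.null(y$efa)) list() else y$efa,
                  clustering = if (is.null(y$clustering)) list() else y$clustering,
                  network = if (is.null(y$network)) list() else y$network,
                  prediction = if (is.null(y$prediction)) list() else y$prediction,
                  seed = if (is.null(y$seed)) 1 else y$seed,
                  out_dir = if (is.null(y$out_dir)) "psychspace_results" else y$out_dir)
}

write_csv_ <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  path
}

write_matrix_csv_ <- function(M, path, rowname_col = "name") {
  df <- data.frame(rn = rownames(M), as.data.frame(M, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  write_csv_(df, path)
}

#' Run the full ontology-discovery pipeline
#'
#' Loads or generates the battery, then runs the enabled stages in order:
#' DV test-retest reliability; the all-DV partial-correlation graph (and
#' optionally held-out cross-category prediction); per-category BIC sweep,
#' EFA and bootstrap; loading-space clustering with dynamic hybrid cut,
#' fixed-height comparison and consensus robustness; outcome EFA and
#' permutation-nulled outcome prediction from survey and task factor
#' scores. Every stage writes its artifacts under `cfg$out_dir` and is
#' recorded in `manifest.json`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[psychspace] ", ...)
  manifest <- list(seed = cfg$seed, stages = list(),
                   package_version = as.character(utils::packageVersion("psychspace")))
  results <- list()

  run_stage <- function(name, expr) {
    log_msg("stage: ", name)
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(completed = TRUE)
    val
  }

  # -- inputs -----------------------------------------------------------
  if (!is.null(cfg$input)) {
    battery <- load_dv_matrix(cfg$input$battery, cfg$input$battery_meta)
    truth <- NULL
    retest <- if (!is.null(cfg$input$retest_t2)) {
      t2 <- load_dv_matrix(cfg$input$retest_t2, cfg$input$battery_meta)
      retest_pair(battery, t2)
    }
    outcomes <- if (!is.null(cfg$input$outcomes))
      load_dv_matrix(cfg$input$outcomes, cfg$input$outcomes_meta)
    covariates <- if (!is.null(cfg$input$covariates)) {
      cv <- utils::read.csv(cfg$input$covariates, stringsAsFactors = FALSE)
      covariate_table(cv$participant_id, cv$age, cv$sex)
    }
  } else {
    gen_cfg <- cfg$generator
    gen_cfg$seed <- cfg$seed
    gen_cfg <- validate_config(gen_cfg)
    gb <- run_stage("generate", generate_battery(gen_cfg))
    battery <- gb$battery; truth <- gb$truth
    retest <- generate_retest(gen_cfg, truth, battery)
    oo <- generate_outcomes(truth, gen_cfg)
    outcomes <- oo$outcomes; covariates <- oo$covariates
    write_matrix(battery, file.path(cfg$out_dir, "battery.csv"))
    write_ground_truth(truth, file.path(cfg$out_dir, "ground_truth.json"))
    manifest$generator_seed <- gen_cfg$seed
  }

  # -- reliability ------------------------------------------------------
  if ("reliability" %in% cfg$stages && !is.null(retest)) {
    rel <- run_stage("reliability", reliability_table(retest))
    write_reliability(rel, file.path(cfg$out_dir, "reliability.csv"))
    results$reliability <- rel
  }

  # -- network ----------------------------------------------------------
  if ("network" %in% cfg$stages) {
    graph <- run_stage("network",
      fit_partial_correlation_graph(battery, ebic_gamma = cfg$network$ebic_gamma,
                                    n_lambda = cfg$network$n_lambda))
    thr <- threshold_and_export(graph, cfg$network$edge_threshold,
                                path = file.path(cfg$out_dir, "edges.csv"),
                                graphml_path = file.path(cfg$out_dir, "graph.graphml"))
    results$network <- list(graph = graph, thresholded = thr)
    if (isTRUE(cfg$network$cross_prediction)) {
      cp <- run_stage("cross_prediction",
                      cross_category_prediction(battery, seed = cfg$seed))
      write_csv_(cp, file.path(cfg$out_dir, "cross_prediction.csv"))
      results$cross_prediction <- cp
    }
  }

  # -- per-category EFA -------------------------------------------------
  models <- list()
  if (any(c("efa", "clustering", "prediction") %in% cfg$stages)) {
    for (cat in c("task", "survey")) {
      if (!cat %in% battery$dv_meta$category) next
      sub <- category_dvs(battery, cat)
      cand <- cfg$efa[[paste0("f_candidates_", cat)]]
      sw <- run_stage(paste0("efa_", cat),
                      select_dimensionality(sub, f_candidates = cand,
                                            seed = cfg$seed))
      model <- sw$best_model
      write_csv_(sw$sweep, file.path(cfg$out_dir, paste0("sweep_", cat, ".csv")))
      write_factor_model(model, file.path(cfg$out_dir, paste0("efa_", cat, ".json")))
      write_matrix_csv_(model$loadings,
                        file.path(cfg$out_dir, paste0("loadings_", cat, ".csv")),
                        "dv_name")
      sc <- factor_scores(model, sub)
      write_matrix_csv_(sc$scores,
                        file.path(cfg$out_dir, paste0("scores_", cat, ".csv")),
                        "participant_id")
      boot <- run_stage(paste0("bootstrap_", cat),
                        bootstrap_loadings(sub, model$n_factors,
                                           n_boot = cfg$efa$n_boot,
                                           seed = cfg$seed))
      models[[cat]] <- list(sweep = sw, model = model, scores = sc, boot = boot,
                            data = sub)
      if (!is.null(retest)) {
        t1s <- apply_weights(model, subset_dvs(retest$t1, dvs = model$dv_names))
        t2s <- apply_weights(model, subset_dvs(retest$t2, dvs = model$dv_names))
        fsr <- factor_score_reliability(t1s, t2s)
        write_csv_(fsr$table,
                   file.path(cfg$out_dir, paste0("factor_reliability_", cat, ".csv")))
        models[[cat]]$score_reliability <- fsr
      }
    }
    results$efa <- models
  }

  # -- clustering -------------------------------------------------------
  if ("clustering" %in% cfg$stages) {
    cl_out <- list()
    for (cat in names(models)) {
      model <- models[[cat]]$model
      if (model$n_factors < 2) {
        log_msg("skipping clustering for ", cat, ": needs >= 2 factors")
        next
      }
      cl <- run_stage(paste0("clustering_", cat), {
        d <- loading_distance(model$loadings)
        tree <- build_tree(d, linkage = cfg$clustering$linkage)
        dyn <- dynamic_tree_cut(tree,
                                min_cluster_size = cfg$clustering$min_cluster_size,
                                deep_split = cfg$clustering$deep_split)
        fh <- fixed_height_cut(tree,
                               n_clusters = length(setdiff(unique(dyn$labels), 0L)))
        cons <- consensus_cluster(models[[cat]]$boot$mean, models[[cat]]$boot$sd,
                                  n_sim = cfg$clustering$n_sim,
                                  drop_frac = cfg$clustering$drop_frac,
                                  seed = cfg$seed, base_labels = dyn$labels,
                                  min_cluster_size = cfg$clustering$min_cluster_size,
                                  deep_split = cfg$clustering$deep_split,
                                  linkage = cfg$clustering$linkage)
        mds <- embed_2d(d, "mds", seed = cfg$seed)
        list(distance = d, tree = tree, dynamic = dyn, fixed = fh,
             ami_dynamic_vs_fixed = adjusted_mutual_information(dyn$labels,
                                                                fh$labels),
             consensus = cons, mds = mds)
      })
      write_cluster_labels(cl$dynamic,
                           file.path(cfg$out_dir, paste0("clusters_", cat, ".csv")))
      write_tree_json(cl$dynamic,
                      file.path(cfg$out_dir, paste0("tree_", cat, ".json")))
      write_matrix_csv_(cl$consensus$cooccurrence,
                        file.path(cfg$out_dir, paste0("cooccurrence_", cat, ".csv")),
                        "dv_name")
      write_matrix_csv_(cl$mds$coords,
                        file.path(cfg$out_dir, paste0("mds_", cat, ".csv")),
                        "dv_name")
      cl_out[[cat]] <- cl
    }
    results$clustering <- cl_out
  }

  # -- prediction -------------------------------------------------------
  if ("prediction" %in% cfg$stages && !is.null(outcomes) &&
      !is.null(covariates)) {
    pred <- run_stage("prediction", {
      tg <- derive_outcome_targets(outcomes, covariates,
                                   f_candidates = cfg$prediction$f_candidates_outcome,
                                   seed = cfg$seed)
      per_feature <- list()
      for (cat in names(models)) {
        res <- predict_outcomes(models[[cat]]$scores, tg$scores,
                                model = cfg$prediction$model,
                                k = cfg$prediction$k,
                                n_perm = cfg$prediction$n_perm,
                                seed = cfg$seed)
        per_feature[[cat]] <- res
        summ <- data.frame(
          target = names(res),
          cv_r2 = vapply(res, function(r) r$cv_r2, 0),
          insample_r2 = vapply(res, function(r) r$insample_r2, 0),
          cv_mae = vapply(res, function(r) r$cv_mae, 0),
          null_95 = vapply(res, function(r)
            if (is.null(r$null_95)) NA_real_ else r$null_95, 0),
          p_value = vapply(res, function(r)
            if (is.null(r$p_value)) NA_real_ else r$p_value, 0))
        write_csv_(summ, file.path(cfg$out_dir,
                                   paste0("prediction_", cat, ".csv")))
        write_matrix_csv_(fingerprint(res),
                          file.path(cfg$out_dir,
                                    paste0("fingerprints_", cat, ".csv")),
                          "target")
      }
      list(targets = tg, results = per_feature)
    })
    results$prediction <- pred
  }

  manifest$config_hash <- digest_config(cfg)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  log_msg("done; artifacts in ", cfg$out_dir)
  invisible(results)
}

# Deterministic fingerprint of the configuration (no external digest dep).
digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")], auto_unbox = TRUE,
                        digits = NA, force = TRUE)
  raw <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
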