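# Clustering of DVs in factor-loading space.
#
# DVs are embedded by their loading rows; distance is 1 - |r| between rows
# (sign-invariant, since a measure's direction is arbitrary). The dendrogram
# is cut adaptively with a dynamic hybrid procedure: branches are detected
# from tree shape (size, core scatter, gap criteria) and stragglers are
# attached to the nearest cluster by average dissimilarity.

#' Absolute-correlation distance between loading rows
#'
#' `d_ij = 1 - |cor(L_i., L_j.)|` over the f loading entries of DVs i and j.
#'
#' @param L Loading matrix (DVs in rows, factors in columns, f >= 2).
#' @return Object of class `dv_distance`: `d` (m x m, zero diagonal,
#'   entries in `[0, 1]`) and `labels`.
#' @export
loading_distance <- function(L) {
  L <- as.matrix(L)
  if (ncol(L) < 2) stop("need at least 2 factors to correlate loading rows")
  rs <- apply(L, 1, stats::sd)
  if (any(rs == 0))
    stop("constant loading row(s): ",
         paste(rownames(L)[rs == 0], collapse = ", "))
  d <- 1 - abs(stats::cor(t(L)))
  d[d < 0] <- 0; d[d > 1] <- 1
  diag(d) <- 0
  labels <- rownames(L)
  if (is.null(labels)) labels <- paste0("dv", seq_len(nrow(L)))
  dimnames(d) <- list(labels, labels)
  structure(list(d = d, labels = labels), class = "dv_distance")
}

#' Distance from any symmetric dissimilarity matrix
#'
#' @param d Symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @param labels Optional labels.
#' @return A `dv_distance`.
#' @export
dv_distance <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  if (any(d < -1e-12) || any(d > 1 + 1e-12)) stop("entries must lie in [0, 1]")
  diag(d) <- 0
  if (is.null(labels)) labels <- paste0("dv", seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  structure(list(d = d, labels = labels), class = "dv_distance")
}

#' Agglomerative tree over a DV distance matrix
#'
#' @param dist_obj A `dv_distance`.
#' @param linkage Linkage method for [stats::hclust()]; average linkage
#'   (UPGMA) is the default companion to the dynamic hybrid cut.
#' @return Object of class `cluster_solution` holding the `hclust` tree
#'   (`tree`), the `dv_distance`, labels `NULL` until a cut is applied,
#'   and `method = "tree"`.
#' @export
build_tree <- function(dist_obj, linkage = "average") {
  stopifnot(inherits(dist_obj, "dv_distance"))
  if (length(dist_obj$labels) < 2) stop("need at least 2 DVs")
  hc <- stats::hclust(stats::as.dist(dist_obj$d), method = linkage)
  structure(list(tree = hc, dist = dist_obj, labels = NULL,
                 method = "tree", params = list(linkage = linkage)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> ", length(x$tree$labels), " DVs; method = ",
      x$method, sep = "")
  if (!is.null(x$labels))
    cat("; ", length(setdiff(unique(x$labels), 0L)), " clusters",
        if (any(x$labels == 0L)) paste0(" (", sum(x$labels == 0L), " unassigned)"),
        sep = "")
  cat("\n")
  invisible(x)
}

# Branch bookkeeping for the dynamic hybrid cut: does an open branch qualify
# as a cluster when it attaches to the rest of the tree at height attach_h?
branch_qualifies <- function(members, merge_heights, attach_h, min_size,
                             max_core_scatter, min_gap, ref_height,
                             min_split_height = 0) {
  size <- length(members)
  if (size < min_size) return(FALSE)
  if (attach_h < min_split_height) return(FALSE)
  k <- min(min_size, size)
  hs <- sort(merge_heights)
  core_scatter <- if (length(hs)) mean(hs[seq_len(max(k - 1, 1))]) else ref_height
  top <- if (length(hs)) max(hs) else ref_height
  gap <- attach_h - top
  (core_scatter <= max_core_scatter) && (gap >= min_gap)
}

#' Dynamic hybrid cut of a dendrogram
#'
#' Adaptive-height cluster detection: descending merges are examined
#' bottom-up and a branch is declared a cluster when it is large enough
#' (`min_cluster_size`), internally tight (core scatter of its earliest
#' merges below a threshold), and well separated from its sibling (gap
#' between attachment height and branch top above a threshold). The
#' scatter/gap thresholds are set relative to the height range by
#' `deep_split` (0-4; larger = more, smaller clusters). In the second
#' (hybrid) stage, objects left unassigned are attached to the nearest
#' cluster by average dissimilarity.
#'
#' @param solution A `cluster_solution` from [build_tree()].
#' @param dist_obj The `dv_distance` the tree was built on (defaults to the
#'   one stored in `solution`).
#' @param min_cluster_size Minimum cluster size (default 3).
#' @param deep_split Integer 0-4 controlling split sensitivity (default 2).
#' @param cut_height Static pre-cut height; default 99% of the tallest merge.
#' @param min_split_height Merges below this absolute height never separate
#'   clusters (guards against splitting a single tight block whose internal
#'   structure is noise; distances live in `[0, 1]`).
#' @param pam_stage Run the straggler-assignment stage (default TRUE).
#' @return A `cluster_solution` with integer `labels` per DV (0 =
#'   unassigned), clusters numbered by decreasing size.
#' @export
dynamic_tree_cut <- function(solution, dist_obj = solution$dist,
                             min_cluster_size = 3, deep_split = 2,
                             cut_height = NULL, min_split_height = 0.05,
                             pam_stage = TRUE) {
  stopifnot(inherits(solution, "cluster_solution"))
  hc <- solution$tree
  m <- length(hc$labels)
  if (min_cluster_size > m) stop("min_cluster_size exceeds number of DVs")
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4")
  h <- hc$height
  if (is.null(cut_height)) cut_height <- 0.99 * max(h)
  ref_height <- as.numeric(stats::quantile(h, 0.05))
  mcs_rel <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  span <- max(cut_height - ref_height, .Machine$double.eps)
  max_core_scatter <- ref_height + mcs_rel * span
  min_gap <- (1 - mcs_rel) * 0.75 * span

  # Bottom-up pass over merges: each active node is either an "open" branch
  # (members + internal merge heights) or already contains finalized clusters.
  node <- vector("list", m - 1)
  get_info <- function(id) {
    if (id < 0) list(members = -id, heights = numeric(0), final = FALSE)
    else node[[id]]
  }
  clusters <- list()
  unassigned <- integer(0)
  finalize <- function(info) clusters[[length(clusters) + 1]] <<- info$members
  for (i in seq_len(m - 1)) {
    A <- get_info(hc$merge[i, 1])
    B <- get_info(hc$merge[i, 2])
    hi <- h[i]
    if (hi > cut_height) {
      # above the static cut: close any open children, never merge
      for (ch in list(A, B)) if (!ch$final) {
        if (branch_qualifies(ch$members, ch$heights, cut_height, min_cluster_size,
                             max_core_scatter, min_gap, ref_height,
                             min_split_height))
          finalize(ch)
        else unassigned <- c(unassigned, ch$members)
      }
      node[[i]] <- list(members = c(A$members, B$members), heights = numeric(0),
                        final = TRUE)
      next
    }
    if (A$final || B$final) {
      for (ch in list(A, B)) if (!ch$final) {
        if (branch_qualifies(ch$members, ch$heights, hi, min_cluster_size,
                             max_core_scatter, min_gap, ref_height,
                             min_split_height))
          finalize(ch)
        else unassigned <- c(unassigned, ch$members)
      }
      node[[i]] <- list(members = c(A$members, B$members), heights = numeric(0),
                        final = TRUE)
    } else {
      qA <- branch_qualifies(A$members, A$heights, hi, min_cluster_size,
                             max_core_scatter, min_gap, ref_height,
                             min_split_height)
      qB <- branch_qualifies(B$members, B$heights, hi, min_cluster_size,
                             max_core_scatter, min_gap, ref_height,
                             min_split_height)
      if (qA && qB) {
        finalize(A); finalize(B)
        node[[i]] <- list(members = c(A$members, B$members),
                          heights = numeric(0), final = TRUE)
      } else {
        node[[i]] <- list(members = c(A$members, B$members),
                          heights = c(A$heights, B$heights, hi), final = FALSE)
      }
    }
  }
  if (!length(clusters)) {
    # no qualifying split anywhere: the whole tree is one cluster
    clusters <- list(seq_len(m))
    unassigned <- integer(0)
  }
  labels <- integer(m)
  ord <- order(vapply(clusters, length, 0L), decreasing = TRUE)
  for (k in seq_along(ord)) labels[clusters[[ord[k]]]] <- k
  D <- dist_obj$d
  if (pam_stage && length(unassigned) && length(clusters)) {
    for (i in unassigned) {
      avg <- vapply(seq_along(ord), function(k)
        mean(D[i, clusters[[ord[k]]]]), 0)
      k_best <- which.min(avg)
      if (avg[k_best] <= cut_height) labels[i] <- k_best
    }
  }
  names(labels) <- hc$labels
  structure(list(tree = hc, dist = dist_obj, labels = labels,
                 method = "dynamic_hybrid",
                 params = list(min_cluster_size = min_cluster_size,
                               deep_split = deep_split,
                               cut_height = cut_height,
                               min_split_height = min_split_height,
                               pam_stage = pam_stage)),
            class = "cluster_solution")
}

#' Fixed-height cut of a dendrogram
#'
#' Cuts the tree at a single height or into a requested number of clusters.
#' In sweep mode (no height or cluster count given) it evaluates every
#' distinct merge-height cut, scores each by mean silhouette, and returns
#' the maximizing cut plus the full silhouette-versus-height curve.
#'
#' @param solution A `cluster_solution` from [build_tree()].
#' @param dist_obj The `dv_distance` (defaults to the stored one).
#' @param height Cut height.
#' @param n_clusters Number of clusters (alternative to `height`).
#' @return A `cluster_solution` (method `"fixed_height"`); in sweep mode the
#'   `params` carry `sweep` (data frame `height`, `k`, `mean_silhouette`).
#' @export
fixed_height_cut <- function(solution, dist_obj = solution$dist,
                             height = NULL, n_clusters = NULL) {
  stopifnot(inherits(solution, "cluster_solution"))
  hc <- solution$tree
  if (!is.null(height)) {
    if (height < 0 || height > max(hc$height) * (1 + 1e-8))
      stop("height outside tree range [0, ", max(hc$height), "]")
    labels <- stats::cutree(hc, h = height)
    params <- list(height = height)
  } else if (!is.null(n_clusters)) {
    labels <- stats::cutree(hc, k = n_clusters)
    params <- list(n_clusters = n_clusters)
  } else {
    hs <- sort(unique(hc$height))
    mids <- (hs + c(hs[-1], max(hs) * 1.01)) / 2
    rows <- lapply(mids, function(ht) {
      lab <- stats::cutree(hc, h = ht)
      k <- length(unique(lab))
      sil <- if (k >= 2 && k < length(lab))
        mean_silhouette(dist_obj, lab) else NA_real_
      data.frame(height = ht, k = k, mean_silhouette = sil)
    })
    sweep_df <- do.call(rbind, rows)
    best <- which.max(sweep_df$mean_silhouette)
    labels <- stats::cutree(hc, h = sweep_df$height[best])
    params <- list(height = sweep_df$height[best], sweep = sweep_df)
  }
  labels <- as.integer(labels)
  names(labels) <- hc$labels
  structure(list(tree = hc, dist = dist_obj, labels = labels,
                 method = "fixed_height", params = params),
            class = "cluster_solution")
}

#' Silhouette scores for a clustering of DVs
#'
#' `s(i) = (b - a) / max(a, b)` with `a` the mean intra-cluster distance and
#' `b` the mean distance to the nearest other cluster; singleton clusters
#' score 0. Unassigned DVs (label 0) are excluded from the mean with a
#' warning.
#'
#' @param dist_obj A `dv_distance`.
#' @param labels Integer labels (0 = unassigned).
#' @return List with `scores` (per included DV) and `mean`.
#' @export
silhouette_scores <- function(dist_obj, labels) {
  stopifnot(inherits(dist_obj, "dv_distance"))
  labels <- as.integer(labels)
  keep <- labels != 0L
  if (any(!keep))
    warning(sum(!keep), " unassigned DV(s) excluded from silhouette")
  lab <- labels[keep]
  if (length(unique(lab)) < 2)
    stop("silhouette undefined for a single cluster")
  sil <- cluster::silhouette(lab, stats::as.dist(dist_obj$d[keep, keep]))
  s <- stats::setNames(sil[, "sil_width"], dist_obj$labels[keep])
  list(scores = s, mean = mean(s))
}

mean_silhouette <- function(dist_obj, labels) {
  silhouette_scores(dist_obj, labels)$mean
}

# Exact expected mutual information under the permutation (hypergeometric)
# null, for the margins of the contingency table. Natural logarithms.
expected_mutual_information <- function(a, b, N) {
  emi <- 0
  lg <- lgamma
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - N)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        term <- nij / N * log(N * nij / (ai * bj))
        lp <- lg(ai + 1) + lg(bj + 1) + lg(N - ai + 1) + lg(N - bj + 1) -
          lg(N + 1) - lg(nij + 1) - lg(ai - nij + 1) - lg(bj - nij + 1) -
          lg(N - ai - bj + nij + 1)
        emi <- emi + term * exp(lp)
      }
    }
  }
  emi
}

#' Adjusted mutual information between two partitions
#'
#' `AMI = (MI - E[MI]) / (mean(H_a, H_b) - E[MI])`, with the expected mutual
#' information computed exactly over the hypergeometric distribution of
#' contingency cells given the margins. 1 means identical partitions up to
#' relabeling; 0 is chance-level agreement.
#'
#' @param labels_a,labels_b Label vectors over the same objects.
#' @return AMI (scalar).
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  N <- length(labels_a)
  tab <- table(labels_a, labels_b)
  a <- rowSums(tab); b <- colSums(tab)
  if (length(a) == 1 && length(b) == 1) return(1)  # both trivial, identical
  H <- function(mrg) { p <- mrg[mrg > 0] / N; -sum(p * log(p)) }
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / N * log(N * nij / (a[i] * b[j]))
  }
  emi <- expected_mutual_information(as.numeric(a), as.numeric(b), N)
  denom <- mean(c(H(a), H(b))) - emi
  if (abs(denom) < .Machine$double.eps^0.5)
    return(if (abs(mi - emi) < .Machine$double.eps^0.5) 0 else 1)
  unname(as.numeric((mi - emi) / denom))
}

#' Consensus clustering robustness from simulated loading matrices
#'
#' Draws `n_sim` loading matrices element-wise from
#' `Normal(loading_mean, loading_sd)` (the bootstrap summaries), randomly
#' drops `drop_frac` of the DVs in each draw, reruns the
#' distance/tree/dynamic-cut pipeline, and accumulates how often each DV
#' pair lands in the same cluster (conditional on both being retained).
#' Consensus clusters are obtained by running the identical pipeline on
#' `1 - cooccurrence`.
#'
#' @param loading_mean,loading_sd m x f matrices (e.g. from
#'   [bootstrap_loadings()]).
#' @param n_sim Number of simulated loading matrices.
#' @param drop_frac Fraction of DVs dropped per simulation.
#' @param seed Integer seed.
#' @param base_labels Optional reference labels; default: the pipeline run
#'   on `loading_mean`.
#' @param min_cluster_size,deep_split,linkage Clustering parameters.
#' @return List of class `consensus_result`: `cooccurrence` (m x m),
#'   `consensus_labels`, `ami_vs_original`, `within_mean`, `between_mean`,
#'   `n_failed`, `base_labels`.
#' @export
consensus_cluster <- function(loading_mean, loading_sd, n_sim = 5000,
                              drop_frac = 0.2, seed = 1, base_labels = NULL,
                              min_cluster_size = 3, deep_split = 2,
                              linkage = "average") {
  if (n_sim < 100) warning("n_sim < 100: co-occurrence estimates will be noisy")
  m <- nrow(loading_mean)
  stopifnot(all(dim(loading_mean) == dim(loading_sd)))
  cut_pipeline <- function(L) {
    d <- loading_distance(L)
    dynamic_tree_cut(build_tree(d, linkage = linkage),
                     min_cluster_size = min_cluster_size,
                     deep_split = deep_split)$labels
  }
  if (is.null(base_labels)) base_labels <- cut_pipeline(loading_mean)
  rs <- restore_rng_state(); on.exit(rs(), add = TRUE)
  set.seed(seed)
  co <- matrix(0, m, m)
  joint <- matrix(0, m, m)
  n_fail <- 0L
  n_keep <- max(round((1 - drop_frac) * m), min_cluster_size + 1)
  for (s in seq_len(n_sim)) {
    Ls <- loading_mean + loading_sd * matrix(stats::rnorm(length(loading_mean)),
                                             m, ncol(loading_mean))
    rownames(Ls) <- rownames(loading_mean)
    keep <- sort(sample.int(m, n_keep))
    lab <- tryCatch(cut_pipeline(Ls[keep, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(lab)) { n_fail <- n_fail + 1L; next }
    joint[keep, keep] <- joint[keep, keep] + 1
    assigned <- keep[lab != 0L]
    lab_a <- lab[lab != 0L]
    same <- outer(lab_a, lab_a, "==")
    co[assigned, assigned] <- co[assigned, assigned] + same
  }
  if (n_fail > 0.05 * n_sim)
    stop(n_fail, "/", n_sim, " simulated clusterings failed")
  coocc <- ifelse(joint > 0, co / joint, 0)
  diag(coocc) <- 1
  dimnames(coocc) <- list(rownames(loading_mean), rownames(loading_mean))
  cons_labels <- dynamic_tree_cut(
    build_tree(dv_distance(1 - coocc), linkage = linkage),
    min_cluster_size = min_cluster_size, deep_split = deep_split)$labels
  pairs <- upper.tri(coocc)
  same_base <- outer(base_labels, base_labels, "==") &
    outer(base_labels != 0, base_labels != 0, "&")
  structure(list(cooccurrence = coocc, consensus_labels = cons_labels,
                 ami_vs_original = adjusted_mutual_information(cons_labels,
                                                               base_labels),
                 within_mean = mean(coocc[pairs & same_base]),
                 between_mean = mean(coocc[pairs & !same_base]),
                 n_failed = n_fail, base_labels = base_labels),
            class = "consensus_result")
}

# One SMACOF majorization pass: Guttman transform for raw-stress metric MDS.
smacof_mds <- function(D, k = 2, init, maxit = 300, tol = 1e-8) {
  m <- nrow(D)
  X <- init
  dx <- as.matrix(stats::dist(X))
  stress <- sum((D - dx)^2) / 2
  trace <- stress
  for (it in seq_len(maxit)) {
    ratio <- ifelse(dx > 0, D / dx, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / m
    dx <- as.matrix(stats::dist(X))
    new_stress <- sum((D - dx)^2) / 2
    trace <- c(trace, new_stress)
    if (stress - new_stress < tol * max(stress, 1e-12)) { stress <- new_stress; break }
    stress <- new_stress
  }
  list(coords = X, stress = stress, trace = trace)
}

#' 2-D embedding of DVs for visualization
#'
#' Metric multidimensional scaling (SMACOF majorization of raw stress, with
#' a classical-scaling start plus seeded random restarts) of a distance
#' matrix, or a principal-component projection of coordinate data.
#'
#' @param x A `dv_distance` (for `method = "mds"`) or a numeric matrix /
#'   `factor_scores` (for `method = "pca"`).
#' @param method `"mds"` or `"pca"`.
#' @param n_restarts Random restarts for MDS (besides the classical start).
#' @param seed Integer seed for the restarts.
#' @return List with `coords` (m x 2); for MDS also `stress` and
#'   `stress_trace`; for PCA also `var_explained`.
#' @export
embed_2d <- function(x, method = c("mds", "pca"), n_restarts = 4, seed = 1) {
  method <- match.arg(method)
  if (method == "pca") {
    M <- if (inherits(x, "factor_scores")) x$scores else as.matrix(x)
    if (nrow(M) < 3) stop("need at least 3 rows")
    pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    k <- min(2, ncol(pc$x))
    return(list(coords = pc$x[, seq_len(k), drop = FALSE],
                var_explained = sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)))
  }
  stopifnot(inherits(x, "dv_distance"))
  D <- x$d
  m <- nrow(D)
  if (m < 3) stop("need at least 3 DVs for MDS")
  inits <- list(suppressWarnings(stats::cmdscale(D, k = 2)))
  rs <- restore_rng_state(); on.exit(rs(), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_restarts))
    inits[[r + 1]] <- matrix(stats::rnorm(2 * m, sd = stats::sd(D)), m, 2)
  fits <- lapply(inits, function(ini) smacof_mds(D, init = as.matrix(ini)))
  best <- fits[[which.min(vapply(fits, function(f) f$stress, 0))]]
  coords <- best$coords
  rownames(coords) <- x$labels
  list(coords = coords, stress = best$stress, stress_trace = best$trace)
}

#' Write cluster labels to CSV
#'
#' @param solution A `cluster_solution` with labels.
#' @param path Output CSV path.
#' @export
write_cluster_labels <- function(solution, path) {
  stopifnot(!is.null(solution$labels))
  utils::write.table(
    data.frame(dv_name = names(solution$labels),
               cluster_id = as.integer(solution$labels)),
    path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Nested-list (JSON-ready) representation of an hclust tree.
tree_to_nested <- function(hc) {
  build <- function(id) {
    if (id < 0) return(list(leaf = hc$labels[-id]))
    list(height = hc$height[id],
         children = list(build(hc$merge[id, 1]), build(hc$merge[id, 2])))
  }
  build(nrow(hc$merge))
}

#' Serialize a dendrogram as nested JSON
#'
#' @param solution A `cluster_solution`.
#' @param path Output JSON path.
#' @export
write_tree_json <- function(solution, path) {
  jsonlite::write_json(tree_to_nested(solution$tree), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
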