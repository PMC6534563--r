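# Test-retest reliability of DVs and attenuation correction of EFA fit.
# Reliability bounds the variance any factor model can explain (the noise
# ceiling): communality / r^2 estimates the fraction of *stable* variance
# captured by the common factors.

#' Per-DV test-retest Pearson correlation
#'
#' @param pair A [retest_pair()].
#' @return A data frame (class `reliability_table`) with columns `dv_name`,
#'   `pearson_r`, `icc3k`, `n_retest`. `icc3k` is NA here; use [icc3k()] or
#'   [reliability_table()] for both.
#' @export
retest_pearson <- function(pair) {
  stopifnot(inherits(pair, "retest_pair"))
  x1 <- pair$t1$values; x2 <- pair$t2$values
  r <- vapply(seq_len(ncol(x1)), function(j) {
    if (stats::sd(x1[, j]) == 0 || stats::sd(x2[, j]) == 0) return(NA_real_)
    stats::cor(x1[, j], x2[, j])
  }, 0)
  flagged <- colnames(x1)[is.na(r)]
  if (length(flagged))
    warning("retest r undefined (constant session column) for: ",
            paste(flagged, collapse = ", "))
  structure(data.frame(dv_name = colnames(x1), pearson_r = r,
                       icc3k = NA_real_, n_retest = nrow(x1),
                       stringsAsFactors = FALSE),
            class = c("reliability_table", "data.frame"))
}

# ICC(3,k): two-way mixed model, consistency, average of k measurements.
# For k sessions: ICC3k = (MS_rows - MS_error) / MS_rows.
icc3k_one <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  row_means <- rowMeans(mat); col_means <- colMeans(mat); grand <- mean(mat)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows == 0) return(NA_real_)
  (ms_rows - ms_err) / ms_rows
}

#' Per-DV intraclass correlation ICC(3,k)
#'
#' Two-way mixed-effects consistency ICC for the average of the k = 2
#' sessions, computed from the session-by-participant ANOVA decomposition:
#' `(MS_rows - MS_error) / MS_rows`. May be negative for anti-reliable DVs;
#' reported as computed.
#'
#' @param pair A [retest_pair()].
#' @return A `reliability_table` data frame (`pearson_r` column NA).
#' @export
icc3k <- function(pair) {
  stopifnot(inherits(pair, "retest_pair"))
  x1 <- pair$t1$values; x2 <- pair$t2$values
  if (nrow(x1) < 3) stop("need at least 3 retest participants")
  icc <- vapply(seq_len(ncol(x1)), function(j)
    icc3k_one(cbind(x1[, j], x2[, j])), 0)
  structure(data.frame(dv_name = colnames(x1), pearson_r = NA_real_,
                       icc3k = icc, n_retest = nrow(x1),
                       stringsAsFactors = FALSE),
            class = c("reliability_table", "data.frame"))
}

#' Full reliability table (Pearson r and ICC3k per DV)
#'
#' @param pair A [retest_pair()].
#' @return A `reliability_table` data frame with both statistics.
#' @export
reliability_table <- function(pair) {
  tab <- retest_pearson(pair)
  tab$icc3k <- icc3k(pair)$icc3k
  tab
}

#' Attenuation-correct communality for test-retest unreliability
#'
#' Divides the communality of a DV by its squared retest correlation, giving
#' the fraction of *stable* (explainable) variance the factor model captures.
#' The ratio is unbounded above; values above 1 are flagged and clipped to 1
#' for aggregate reporting while the raw ratio is preserved.
#'
#' @param h2 Communality in `[0, 1]` (vectorized).
#' @param r Retest correlation, strictly positive (vectorized).
#' @return Data frame with `raw` (h2 / r^2), `adjusted` (clipped to 1), and
#'   `flagged` (raw > 1).
#' @export
attenuation_correct <- function(h2, r) {
  if (any(r <= 0)) stop("attenuation correction undefined for r <= 0")
  if (any(h2 < 0 | h2 > 1)) stop("communality must be in [0, 1]")
  raw <- h2 / r^2
  data.frame(raw = raw, adjusted = pmin(raw, 1), flagged = raw > 1)
}

#' Correlation between communality and test-retest reliability
#'
#' Restricts to DVs whose retest r exceeds `r_min` (default 0.2), correlates
#' communality with retest r over the survivors, and reports the mean
#' attenuation-adjusted variance explained (clipped aggregate).
#'
#' @param communalities Named numeric vector of communalities (names = DVs).
#' @param reliability A `reliability_table` (or data frame with `dv_name`,
#'   `pearson_r`).
#' @param r_min Reliability filter threshold.
#' @return List with `r` (Pearson correlation h2 vs retest r), `n_dvs`,
#'   `mean_adjusted` (mean clipped h2/r^2), `mean_unadjusted`, and the
#'   per-DV `table`.
#' @export
communality_reliability_corr <- function(communalities, reliability, r_min = 0.2) {
  rel <- reliability$pearson_r[match(names(communalities), reliability$dv_name)]
  keep <- !is.na(rel) & rel > r_min
  if (sum(keep) < 3)
    stop("fewer than 3 DVs survive the retest r > ", r_min, " filter")
  h2 <- communalities[keep]; rr <- rel[keep]
  adj <- attenuation_correct(h2, rr)
  list(r = stats::cor(h2, rr),
       n_dvs = sum(keep),
       mean_adjusted = mean(adj$adjusted),
       mean_unadjusted = mean(h2),
       table = data.frame(dv_name = names(communalities)[keep], h2 = h2,
                          retest_r = rr, adjusted = adj$adjusted,
                          raw = adj$raw, flagged = adj$flagged,
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Write a reliability table to CSV
#'
#' @param tab A `reliability_table`.
#' @param path Output CSV path.
#' @export
write_reliability <- function(tab, path) {
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}
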