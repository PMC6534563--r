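#' Construct a DV matrix
#'
#' The basic data container of the package: a participants x DVs numeric
#' matrix together with per-DV metadata. Each column is one dependent
#' variable (DV) extracted from a behavioral task, a self-report survey, or a
#' real-world outcome item; each row is one participant.
#'
#' @param values Numeric matrix, participants in rows, DVs in columns.
#' @param participant_ids Character vector of unique participant identifiers
#'   (defaults to rownames of `values`).
#' @param dv_meta Data frame with columns `dv_name`, `measure`, `category`;
#'   one row per DV, `category` one of `"task"`, `"survey"`, `"outcome"`.
#' @return An object of class `dv_matrix` with elements `values`,
#'   `participant_ids`, `dv_meta`.
#' @export
dv_matrix <- function(values, participant_ids = rownames(values), dv_meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(participant_ids)) participant_ids <- as.character(seq_len(nrow(values)))
  participant_ids <- as.character(participant_ids)
  if (length(participant_ids) != nrow(values))
    stop("participant_ids length (", length(participant_ids),
         ") does not match number of rows (", nrow(values), ")")
  if (anyDuplicated(participant_ids))
    stop("duplicate participant_ids: ",
         paste(unique(participant_ids[duplicated(participant_ids)]), collapse = ", "))
  dv_meta <- as.data.frame(dv_meta, stringsAsFactors = FALSE)
  req <- c("dv_name", "measure", "category")
  if (!all(req %in% names(dv_meta)))
    stop("dv_meta must have columns: ", paste(req, collapse = ", "))
  dv_meta <- dv_meta[, req]
  dv_meta$dv_name <- as.character(dv_meta$dv_name)
  dv_meta$measure <- as.character(dv_meta$measure)
  dv_meta$category <- as.character(dv_meta$category)
  if (is.null(colnames(values))) colnames(values) <- dv_meta$dv_name
  missing_meta <- setdiff(colnames(values), dv_meta$dv_name)
  if (length(missing_meta))
    stop("DVs missing from metadata: ", paste(missing_meta, collapse = ", "))
  dv_meta <- dv_meta[match(colnames(values), dv_meta$dv_name), , drop = FALSE]
  rownames(dv_meta) <- NULL
  if (anyDuplicated(dv_meta$dv_name))
    stop("duplicate dv_name: ",
         paste(unique(dv_meta$dv_name[duplicated(dv_meta$dv_name)]), collapse = ", "))
  bad_cat <- setdiff(unique(dv_meta$category), c("task", "survey", "outcome"))
  if (length(bad_cat))
    stop("unknown category: ", paste(bad_cat, collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite values in DV matrix (the pipeline consumes imputed data; ",
         "NaN/NA are rejected)")
  rownames(values) <- participant_ids
  structure(list(values = values, participant_ids = participant_ids,
                 dv_meta = dv_meta),
            class = "dv_matrix")
}

#' @export
print.dv_matrix <- function(x, ...) {
  tab <- table(x$dv_meta$category)
  cat("<dv_matrix> ", nrow(x$values), " participants x ", ncol(x$values), " DVs (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.dv_matrix <- function(x) dim(x$values)

#' Subset a DV matrix by column (DV) or row (participant)
#'
#' @param x A `dv_matrix`.
#' @param dvs Character vector of DV names or logical/integer column index.
#' @param participants Character vector of participant ids or index.
#' @return A `dv_matrix` restricted to the selection, order preserved as given.
#' @export
subset_dvs <- function(x, dvs = NULL, participants = NULL) {
  stopifnot(inherits(x, "dv_matrix"))
  vals <- x$values
  meta <- x$dv_meta
  if (!is.null(dvs)) {
    j <- if (is.character(dvs)) match(dvs, colnames(vals)) else seq_len(ncol(vals))[dvs]
    if (anyNA(j)) stop("unknown DVs: ", paste(dvs[is.na(j)], collapse = ", "))
    vals <- vals[, j, drop = FALSE]
    meta <- meta[j, , drop = FALSE]
  }
  ids <- rownames(vals)
  if (!is.null(participants)) {
    i <- if (is.character(participants)) match(participants, ids) else seq_along(ids)[participants]
    if (anyNA(i)) stop("unknown participants")
    vals <- vals[i, , drop = FALSE]
    ids <- ids[i]
  }
  dv_matrix(vals, ids, meta)
}

#' Select the DVs belonging to one measurement category
#'
#' @param x A `dv_matrix`.
#' @param category `"task"`, `"survey"`, or `"outcome"`.
#' @return A `dv_matrix` with only that category's DVs.
#' @export
category_dvs <- function(x, category = c("task", "survey", "outcome")) {
  category <- match.arg(category)
  keep <- x$dv_meta$dv_name[x$dv_meta$category == category]
  if (!length(keep)) stop("no DVs with category '", category, "'")
  subset_dvs(x, dvs = keep)
}

#' Load a DV matrix from CSV/TSV plus sidecar metadata
#'
#' The matrix file must have a header row of DV names and a first column
#' `participant_id`. The metadata file is JSON mapping each `dv_name` to
#' `{measure, category}` (the format `write_matrix()` produces), or a
#' CSV/TSV with columns `dv_name, measure, category`.
#'
#' @param path Path to the matrix CSV/TSV (separator sniffed from extension).
#' @param meta_path Path to the metadata JSON or CSV/TSV.
#' @return A validated [dv_matrix()].
#' @export
load_dv_matrix <- function(path, meta_path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  if (!ncol(df) || names(df)[1] != "participant_id")
    stop("first column of ", path, " must be 'participant_id'")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  if (nrow(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-numeric cell at participant '", ids[bad[1, 1]],
           "', DV '", colnames(vals)[bad[1, 2]], "'")
  }
  meta <- read_dv_meta(meta_path)
  dv_matrix(num, ids, meta)
}

read_dv_meta <- function(meta_path) {
  if (grepl("\\.json$", meta_path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(meta_path)
    data.frame(dv_name = names(m),
               measure = vapply(m, function(e) as.character(e$measure), ""),
               category = vapply(m, function(e) as.character(e$category), ""),
               stringsAsFactors = FALSE)
  } else {
    sep <- if (grepl("\\.tsv$", meta_path, ignore.case = TRUE)) "\t" else ","
    utils::read.table(meta_path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, quote = "\"")
  }
}

#' Write a DV matrix as CSV with sidecar JSON metadata
#'
#' @param x A `dv_matrix`.
#' @param path Output CSV path; metadata is written next to it as
#'   `<path minus extension>_meta.json` unless `meta_path` is given.
#' @param meta_path Optional explicit metadata path.
#' @return Invisibly, the two paths written.
#' @export
write_matrix <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "dv_matrix"))
  if (is.null(meta_path))
    meta_path <- paste0(sub("\\.[^.]+$", "", path), "_meta.json")
  df <- data.frame(participant_id = x$participant_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(x$values, check.names = FALSE)
  df <- if (nrow(df)) cbind(df, vals) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = ncol(x$values) + 1)),
                    c("participant_id", colnames(x$values)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  meta <- lapply(seq_len(nrow(x$dv_meta)), function(i)
    list(measure = x$dv_meta$measure[i], category = x$dv_meta$category[i]))
  names(meta) <- x$dv_meta$dv_name
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, meta_path))
}

#' Column-standardize a DV matrix
#'
#' Centers each DV to mean zero and scales to unit sample variance
#' (denominator n - 1), so the cross-product of the result is the Pearson
#' correlation matrix the factor analysis consumes.
#'
#' @param x A `dv_matrix`.
#' @return A `dv_matrix` with standardized columns.
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "dv_matrix"))
  v <- apply(x$values, 2, stats::var)
  if (any(v <= 0 | !is.finite(v)))
    stop("constant DV column(s): ",
         paste(colnames(x$values)[v <= 0 | !is.finite(v)], collapse = ", "))
  z <- scale(x$values)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  dv_matrix(z, x$participant_ids, x$dv_meta)
}

#' Construct a covariate table
#'
#' @param participant_ids Character vector of ids.
#' @param age Numeric vector (years).
#' @param sex Numeric vector coded 0/1.
#' @return A data frame of class `covariate_table`.
#' @export
covariate_table <- function(participant_ids, age, sex) {
  participant_ids <- as.character(participant_ids)
  stopifnot(length(age) == length(participant_ids),
            length(sex) == length(participant_ids))
  if (anyDuplicated(participant_ids)) stop("duplicate participant_ids")
  if (anyNA(age) || anyNA(sex)) stop("missing covariate values")
  structure(data.frame(participant_id = participant_ids,
                       age = as.numeric(age), sex = as.numeric(sex),
                       stringsAsFactors = FALSE),
            class = c("covariate_table", "data.frame"))
}

#' Regress age and sex out of each outcome DV
#'
#' Each column is regressed on an intercept, age, and sex by ordinary least
#' squares; the returned matrix holds the residuals, which are uncorrelated
#' with both covariates by construction. Participants are aligned by id join.
#'
#' @param x A `dv_matrix` (typically the outcome DVs).
#' @param covariates A [covariate_table()] covering all participants of `x`.
#' @return A `dv_matrix` of residuals, same shape and metadata as `x`.
#' @export
residualize_covariates <- function(x, covariates) {
  stopifnot(inherits(x, "dv_matrix"))
  idx <- match(x$participant_ids, covariates$participant_id)
  if (anyNA(idx))
    stop("covariates missing for participants: ",
         paste(utils::head(x$participant_ids[is.na(idx)], 5), collapse = ", "))
  Z <- cbind(intercept = 1, age = covariates$age[idx], sex = covariates$sex[idx])
  if (stats::var(Z[, "age"]) == 0 || stats::var(Z[, "sex"]) == 0)
    stop("constant covariate column (age or sex)")
  if (qr(Z)$rank < ncol(Z)) stop("collinear covariates")
  res <- stats::lm.fit(Z, x$values)$residuals
  res <- matrix(res, nrow = nrow(x$values), dimnames = dimnames(x$values))
  dv_matrix(res, x$participant_ids, x$dv_meta)
}

#' Pair two sessions of the same battery for retest analysis
#'
#' @param t1,t2 `dv_matrix` objects with identical DV metadata.
#' @return A list of class `retest_pair` with `t1`, `t2` (both restricted to
#'   the shared participants, in matching order) and `shared_ids`.
#' @export
retest_pair <- function(t1, t2) {
  stopifnot(inherits(t1, "dv_matrix"), inherits(t2, "dv_matrix"))
  if (!identical(t1$dv_meta, t2$dv_meta))
    stop("t1 and t2 must have identical dv_meta")
  shared <- intersect(t1$participant_ids, t2$participant_ids)
  if (length(shared) < 3)
    stop("need at least 3 shared participants, got ", length(shared))
  structure(list(t1 = subset_dvs(t1, participants = shared),
                 t2 = subset_dvs(t2, participants = shared),
                 shared_ids = shared),
            class = "retest_pair")
}
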