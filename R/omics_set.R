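#' Multi-omic measurement set
#'
#' The common currency of the pipeline: a features x samples numeric matrix
#' together with an omic tag, per-sample group labels and optional per-feature
#' metadata. Values may contain `NA` (missing / non-detected measurements).
#'
#' @param values numeric matrix, features in rows and samples in columns;
#'   both dimnames are required and feature ids must be unique.
#' @param omic one of `"gene"`, `"metabolite"`, `"cytokine"`.
#' @param groups factor (or coercible) of length `ncol(values)` with exactly
#'   two levels; the *second* level is treated as the case group throughout
#'   (log-fold-changes are case minus control).
#' @param features optional data.frame of per-feature metadata whose first
#'   column `id` matches `rownames(values)`.
#'
#' @return An object of class `omics_set`.
#' @export
omics_set <- function(values, omic, groups, features = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("`values` must be a numeric matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values)))
    .stopf("`values` must carry feature rownames and sample colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    .stopf("duplicate feature ids: %s", paste(dup, collapse = ", "))
  omic <- match.arg(omic, c("gene", "metabolite", "cytokine"))
  if (length(groups) != ncol(values))
    .stopf("need one group label per sample (%d labels for %d samples)",
           length(groups), ncol(values))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    .stopf("exactly two sample groups expected, got: %s",
           paste(levels(droplevels(groups)), collapse = ", "))
  groups <- droplevels(groups)
  names(groups) <- colnames(values)
  if (is.null(features)) {
    features <- data.frame(id = rownames(values) %||% character(0),
                           stringsAsFactors = FALSE)
  }
  if (!identical(as.character(features$id),
                 rownames(values) %||% character(0)))
    .stopf("`features$id` must match rownames(values) in order")
  structure(list(values = values, omic = omic, groups = groups,
                 features = features),
            class = "omics_set")
}

#' @export
print.omics_set <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("omics_set [%s]: %d features x %d samples (%s)\n",
              x$omic, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.omics_set <- function(x) dim(x$values)

#' Subset an omics_set by features and/or samples
#'
#' @param x an `omics_set`.
#' @param i feature index (ids, logical or integer).
#' @param j sample index.
#' @param ... unused.
#' @export
`[.omics_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  feats <- x$features[match(rownames(v), x$features$id), , drop = FALSE]
  rownames(feats) <- NULL
  omics_set(v, x$omic, x$groups[colnames(v)], feats)
}

#' Case-group level of an omics_set
#' @param x an `omics_set`.
#' @return Character scalar, the second group level.
#' @export
case_level <- function(x) levels(x$groups)[2L]

#' Write an omics matrix as TSV
#'
#' Rows are features; the first column (`feature`) holds feature ids and the
#' header carries the sample ids.
#'
#' @param x an `omics_set`.
#' @param path output file.
#' @export
write_omics_tsv <- function(x, path) {
  df <- data.frame(feature = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an omics matrix from TSV
#'
#' @param path TSV file written by [write_omics_tsv()] (first column feature
#'   ids, header sample ids).
#' @param omic omic tag for the resulting set.
#' @param samples data.frame with columns `id` and `group` (as written by
#'   [write_samples_tsv()]), or the path of such a file.
#' @param group_levels optional character vector of length 2 giving the group
#'   level order (reference first).
#' @return An `omics_set`.
#' @export
read_omics_tsv <- function(path, omic, samples, group_levels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("matrix file %s has no sample columns", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (is.character(samples)) samples <- read_samples_tsv(samples)
  miss <- setdiff(colnames(m), samples$id)
  if (length(miss))
    .stopf("samples missing group labels: %s", paste(miss, collapse = ", "))
  grp <- samples$group[match(colnames(m), samples$id)]
  if (!is.null(group_levels)) grp <- factor(grp, levels = group_levels)
  omics_set(m, omic, grp)
}

#' Write sample group labels as TSV
#' @param groups named factor (names = sample ids) or an `omics_set`.
#' @param path output file.
#' @export
write_samples_tsv <- function(groups, path) {
  if (inherits(groups, "omics_set")) groups <- groups$groups
  df <- data.frame(id = names(groups), group = as.character(groups),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample group labels from TSV
#' @param path file written by [write_samples_tsv()].
#' @return data.frame with columns `id`, `group`.
#' @export
read_samples_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
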