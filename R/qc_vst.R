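#' Metabolite quality-control filter
#'
#' A feature is retained iff (1) its fraction of missing values is strictly
#' below `max_missing` in *every* group, and (2) at least `min_above_lod` of
#' all its measured (non-missing) values lie above the limit of detection.
#' The 20% rule uses a strict inequality and the 50% rule an inclusive one;
#' both thresholds are configurable.
#'
#' @param x an `omics_set` on the concentration scale (may contain `NA`).
#' @param lod scalar or per-feature named vector of detection limits
#'   (default 0, so rule 2 passes for strictly positive data).
#' @param max_missing maximum per-group missing fraction (exclusive).
#' @param min_above_lod minimum fraction of measured values above the LOD
#'   (inclusive).
#' @return list with `matrix` (the filtered `omics_set`) and `report`
#'   (data.frame: per-feature missing fraction per group, fraction above LOD,
#'   per-rule flags and the overall `retained` flag).
#' @export
metabolite_qc_filter <- function(x, lod = 0, max_missing = 0.20,
                                 min_above_lod = 0.50) {
  stopifnot(inherits(x, "omics_set"))
  ids <- rownames(x$values)
  if (length(lod) == 1L && is.null(names(lod))) {
    lodv <- stats::setNames(rep(as.numeric(lod), length(ids)), ids)
  } else {
    lodv <- stats::setNames(rep(0, length(ids)), ids)
    lodv[intersect(names(lod), ids)] <- lod[intersect(names(lod), ids)]
  }
  if (any(!is.finite(lodv)) || any(lodv < 0))
    .stopf("`lod` must be finite and non-negative")
  lv <- levels(x$groups)
  miss <- sapply(lv, function(g) {
    rowMeans(is.na(x$values[, x$groups == g, drop = FALSE]))
  })
  if (is.null(dim(miss)))
    miss <- matrix(miss, nrow = length(ids), dimnames = list(ids, lv))
  above <- vapply(seq_along(ids), function(i) {
    v <- x$values[i, ]
    v <- v[!is.na(v)]
    if (!length(v)) return(0)
    mean(v > lodv[i])
  }, numeric(1))
  pass_missing <- apply(miss < max_missing, 1, all)
  pass_lod <- above >= min_above_lod
  retained <- pass_missing & pass_lod
  report <- data.frame(feature = ids, miss,
                       frac_above_lod = above,
                       pass_missing = pass_missing, pass_lod = pass_lod,
                       retained = retained,
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(report)[2:(1 + length(lv))] <- paste0("missing_", lv)
  rownames(report) <- NULL
  if (!any(retained)) {
    .warnf("all %d features removed by QC; returning an empty matrix",
           length(ids))
    empty <- x$values[0, , drop = FALSE]
    return(list(matrix = omics_set(empty, x$omic, x$groups,
                                   x$features[0, , drop = FALSE]),
                report = report))
  }
  list(matrix = x[retained, ], report = report)
}

#' Generalized log2 transform
#'
#' `glog2(x, b) = log2((x + sqrt(x^2 + b^2)) / 2)`; behaves like `log2(x)`
#' for `x >> b` and is defined (and variance-flattening) near and below zero.
#'
#' @param x numeric.
#' @param b calibration constant (>= 0).
#' @return numeric of the same shape.
#' @export
glog2 <- function(x, b = 0) log2((x + sqrt(x^2 + b^2)) / 2)

# slope of per-feature SD against the rank of the per-feature mean
.sd_trend_slope <- function(m) {
  mu <- rowMeans(m, na.rm = TRUE)
  sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  ok <- is.finite(mu) & is.finite(sd)
  if (sum(ok) < 3) return(0)
  r <- rank(mu[ok])
  sl <- unname(stats::coef(stats::lm(sd[ok] ~ r))[2])
  if (!is.finite(sl)) 0 else sl
}

#' Variance-stabilizing normalization
#'
#' A simplified deterministic variance-stabilizing transform for intensity /
#' concentration data: each sample is affinely calibrated (gain and offset,
#' ordinary least squares) against the across-sample median feature profile,
#' then a common generalized-log transform [glog2()] is applied with the
#' calibration constant `b` chosen by grid search to flatten the trend of the
#' per-feature standard deviation against the rank of the per-feature mean.
#' Normalization is blind to group labels.
#'
#' @param x an `omics_set` with non-negative values (raw scale).
#' @param b optional fixed glog constant; `NULL` (default) selects it by grid
#'   search.
#' @param grid_size number of candidate `b` values.
#' @return The transformed `omics_set` (same shape); the chosen `b` and the
#'   residual SD-trend slope are stored as attributes `"b"` and `"sd_slope"`.
#' @export
vst_normalize <- function(x, b = NULL, grid_size = 40L) {
  stopifnot(inherits(x, "omics_set"))
  v <- x$values
  if (any(v < 0, na.rm = TRUE))
    .stopf("vst_normalize expects non-negative intensities")
  ref <- apply(v, 1, stats::median, na.rm = TRUE)
  const <- stats::sd(ref, na.rm = TRUE)
  cal <- v
  if (!is.finite(const) || const == 0) {
    .warnf("constant reference profile; applying glog without calibration")
  } else {
    # weighted least squares with weights ~ 1/ref^2: intensity noise is
    # predominantly multiplicative, and unweighted OLS would let the
    # high-abundance tail induce spurious offsets for low-abundance features
    for (j in seq_len(ncol(v))) {
      ok <- !is.na(v[, j]) & is.finite(ref)
      if (sum(ok) < 3 || stats::sd(v[ok, j]) == 0) next
      w <- 1 / pmax(ref[ok], max(ref[ok], 0) * 1e-6 + 1e-12)^2
      fit <- stats::lm.wfit(cbind(1, ref[ok]), v[ok, j], w)
      gain <- fit$coefficients[2]
      offset <- fit$coefficients[1]
      if (!is.finite(gain) || gain <= 0) {
        .warnf("sample %s: non-positive calibration gain, left uncalibrated",
               colnames(v)[j])
        next
      }
      cal[, j] <- (v[, j] - offset) / gain
    }
  }
  if (is.null(b)) {
    pos <- cal[is.finite(cal) & cal > 0]
    if (!length(pos)) {
      b <- 1
    } else {
      # log-spaced candidates from well below the low quantiles (glog ~ log2)
      # up to the bulk of the data
      lo <- stats::quantile(pos, 0.001, names = FALSE) / 4
      hi <- stats::quantile(pos, 0.99, names = FALSE)
      lo <- max(lo, hi * 1e-9, .Machine$double.xmin)
      grid <- exp(seq(log(lo), log(max(hi, lo * 2)), length.out = grid_size))
      slopes <- vapply(grid, function(bb) abs(.sd_trend_slope(glog2(cal, bb))),
                       numeric(1))
      b <- grid[which.min(slopes)]
      if (!length(b) || !is.finite(b)) b <- 1
    }
  }
  out <- glog2(cal, b)
  res <- omics_set(out, x$omic, x$groups, x$features)
  attr(res, "b") <- b
  attr(res, "sd_slope") <- .sd_trend_slope(out)
  res
}

# log2 for strictly positive small panels; glog2 with b = smallest positive
# value when zeros or missing entries are present
.stabilize_small_panel <- function(v) {
  if (all(v > 0, na.rm = TRUE) && !anyNA(v)) return(log2(v))
  b <- min(v[v > 0], na.rm = TRUE)
  glog2(v, b)
}
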