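#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment; the output order matches the input order. `NA`
#' p-values propagate as `NA` and are excluded from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    .stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# Newton inversion of the trigamma function (y = trigamma(x), solve for x)
.trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1))
}

# method-of-moments estimate of the variance prior (d0, s0sq) from the
# observed log residual variances, Smyth-style; d0 capped for stability
.estimate_variance_prior <- function(s2, df, d0_cap = 1e6) {
  ok <- is.finite(s2) & df > 0 & s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s0sq = stats::median(s2[ok]) %||% NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  n <- length(e)
  evar <- mean((e - mean(e))^2) * n / (n - 1) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    d0 <- min(d0, d0_cap)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- d0_cap
    s0sq <- exp(mean(e))
  }
  if (!is.finite(s0sq) || s0sq <= 0) s0sq <- 1e-8
  list(d0 = d0, s0sq = s0sq)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-feature two-group contrast on a variance-stabilized matrix. Residual
#' variances are shrunk towards a common prior,
#' `s2_post = (d0 * s0sq + df * s2) / (d0 + df)`, with the prior degrees of
#' freedom `d0` and prior variance `s0sq` estimated by the method of moments
#' on `log(s2)` (capped at `1e6` for stability) unless supplied. The
#' moderated statistic `t = logFC / (s_post * sqrt(1/n1 + 1/n2))` is referred
#' to a t distribution on `d0 + df` degrees of freedom; two-sided p-values
#' are BH-adjusted. Missing values are allowed; per-feature sample sizes and
#' degrees of freedom are adjusted accordingly.
#'
#' @param x an `omics_set` (already variance-stabilized); the second group
#'   level is the case group and `logFC` is case minus control.
#' @param alpha FDR level for the `significant` flag.
#' @param d0,s0sq optional fixed prior; `d0 = 0` gives the ordinary t-test.
#' @param weights optional per-sample non-negative weights used in the group
#'   means and residual variances (default uniform).
#' @return A data.frame of class `diffexp_table` with columns `feature`,
#'   `logFC`, `s2`, `df`, `s2_post`, `t`, `p`, `fdr`, `significant`;
#'   attributes `d0`, `s0sq`, `alpha`.
#' @export
moderated_ttest <- function(x, alpha = 0.05, d0 = NULL, s0sq = NULL,
                            weights = NULL) {
  stopifnot(inherits(x, "omics_set"))
  v <- x$values
  g2 <- x$groups == levels(x$groups)[2L]
  if (sum(g2) < 2 || sum(!g2) < 2)
    .stopf("each group needs >= 2 samples for the two-group test")
  if (is.null(weights)) weights <- rep(1, ncol(v))
  if (length(weights) != ncol(v) || any(weights < 0))
    .stopf("`weights` must be non-negative, one per sample")

  wmean <- function(vals, w) {
    ok <- !is.na(vals) & w > 0
    if (!any(ok)) return(c(mean = NA_real_, n = 0, ss = NA_real_))
    m <- sum(w[ok] * vals[ok]) / sum(w[ok])
    c(mean = m, n = sum(ok), ss = sum(w[ok] * (vals[ok] - m)^2))
  }
  nfeat <- nrow(v)
  stats_case <- t(apply(v[, g2, drop = FALSE], 1, wmean, w = weights[g2]))
  stats_ctrl <- t(apply(v[, !g2, drop = FALSE], 1, wmean, w = weights[!g2]))
  n1 <- stats_ctrl[, "n"]; n2 <- stats_case[, "n"]
  logFC <- stats_case[, "mean"] - stats_ctrl[, "mean"]
  df <- pmax(n1 + n2 - 2, 0)
  s2 <- ifelse(df > 0, (stats_case[, "ss"] + stats_ctrl[, "ss"]) / df, NA_real_)

  if (is.null(d0) || is.null(s0sq)) {
    prior <- .estimate_variance_prior(s2, df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0sq)) s0sq <- prior$s0sq
  }
  if (!is.finite(s0sq) || s0sq <= 0) s0sq <- 1e-8
  s2_post <- (d0 * s0sq + df * ifelse(is.na(s2), 0, s2)) / (d0 + df)
  s2_post <- pmax(s2_post, 1e-12)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- logFC / se
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[df_total <= 0 | n1 < 2 | n2 < 2] <- NA_real_
  fdr <- bh_adjust(p)
  out <- data.frame(feature = rownames(v), logFC = logFC, s2 = s2, df = df,
                    s2_post = s2_post, t = tstat, p = p, fdr = fdr,
                    significant = !is.na(fdr) & fdr < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  attr(out, "alpha") <- alpha
  class(out) <- c("diffexp_table", "data.frame")
  out
}

#' Exact Wilcoxon rank-sum tests for a cytokine panel
#'
#' Per-feature two-sided rank-sum test on the raw (untransformed) values:
#' exact enumeration when the total sample size is at most `exact_max` and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity correction. Group medians and interquartile ranges are reported
#' on the raw scale, along with a non-gating Fligner-Killeen homoscedasticity
#' diagnostic. P-values are BH-adjusted across the panel.
#'
#' @param x an `omics_set` on the raw concentration scale.
#' @param alpha FDR level for the `significant` flag.
#' @param exact_max largest total sample size for exact enumeration.
#' @return A data.frame of class `cytokine_test_table` with columns
#'   `feature`, `median_control`, `iqr_control`, `median_case`, `iqr_case`,
#'   `W`, `p`, `fdr`, `significant`, `fligner_p`.
#' @export
wilcoxon_panel <- function(x, alpha = 0.05, exact_max = 20L) {
  stopifnot(inherits(x, "omics_set"))
  v <- x$values
  g2 <- x$groups == levels(x$groups)[2L]
  if (sum(g2) < 2 || sum(!g2) < 2)
    .stopf("each group needs >= 2 samples for the rank-sum test")
  res <- lapply(seq_len(nrow(v)), function(i) {
    a <- v[i, g2]; b <- v[i, !g2]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(unique(c(a, b))) == 1L) {
      .warnf("feature %s: all values tied; p set to 1", rownames(v)[i])
      return(data.frame(W = length(a) * length(b) / 2, p = 1))
    }
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- (length(a) + length(b)) <= exact_max && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    data.frame(W = unname(wt$statistic), p = wt$p.value)
  })
  res <- do.call(rbind, res)
  flig <- vapply(seq_len(nrow(v)), function(i) {
    tryCatch(stats::fligner.test(v[i, ], x$groups)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  med <- function(sel, f) apply(v[, sel, drop = FALSE], 1, f, na.rm = TRUE)
  fdr <- bh_adjust(res$p)
  out <- data.frame(feature = rownames(v),
                    median_control = med(!g2, stats::median),
                    iqr_control = med(!g2, stats::IQR),
                    median_case = med(g2, stats::median),
                    iqr_case = med(g2, stats::IQR),
                    W = res$W, p = res$p, fdr = fdr,
                    significant = !is.na(fdr) & fdr < alpha,
                    fligner_p = flig,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("cytokine_test_table", "data.frame")
  out
}

#' Significant features of a test table
#'
#' @param table a `diffexp_table` or `cytokine_test_table` (any data.frame
#'   with `feature` and `fdr` columns).
#' @param alpha FDR threshold (exclusive).
#' @return Character vector of feature ids with `fdr < alpha`, ordered by
#'   increasing q-value (ties by id).
#' @export
significant_features <- function(table, alpha = 0.05) {
  stopifnot(all(c("feature", "fdr") %in% names(table)))
  sel <- !is.na(table$fdr) & table$fdr < alpha
  tab <- table[sel, , drop = FALSE]
  tab$feature[order(tab$fdr, tab$feature)]
}

#' Write a differential-test table as TSV
#' @param table a `diffexp_table`.
#' @param path output file.
#' @export
write_diffexp_tsv <- function(table, path) {
  df <- data.frame(feature = table$feature, logFC = table$logFC,
                   t = table$t, p = table$p, fdr = table$fdr,
                   significant = table$significant, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
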