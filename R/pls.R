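#' Fit a PLS2 regression model (NIPALS)
#'
#' Two-block partial least squares in regression mode: components are
#' extracted to maximize the covariance between linear combinations of the
#' predictor block X and the response block Y, with X deflated per component.
#' The score iteration is initialized deterministically with the Y column of
#' maximal variance and converges on the X-score vector (tolerance `tol`,
#' at most `max_iter` iterations). Weight vectors are unit-norm and X-scores
#' of successive components are orthogonal.
#'
#' @param X numeric matrix, samples x predictors.
#' @param Y numeric matrix (or vector), samples x responses.
#' @param A number of components, `A <= min(n - 1, ncol(X))`.
#' @param scale `"autoscale"` (center and scale both blocks to unit variance,
#'   the default, suited to heterogeneous units) or `"center"` (centering
#'   only). Zero-variance predictors are dropped with a warning under
#'   autoscaling.
#' @param tol convergence tolerance on the relative change of the score
#'   vector.
#' @param max_iter maximal NIPALS iterations per component.
#' @return An object of class `pls_fit`: weights `W`, X-loadings `P`,
#'   Y-loadings `Q` (all per component), X-scores `T_scores`, centering /
#'   scaling vectors of both blocks, per-component cumulative `R2` on the
#'   scaled response block, and bookkeeping (`A`, ids, iterations).
#' @export
fit_pls <- function(X, Y, A = 2, scale = c("autoscale", "center"),
                    tol = 1e-10, max_iter = 500L) {
  scale <- match.arg(scale)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) .stopf("X and Y must share samples")
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))

  x_center <- colMeans(X); y_center <- colMeans(Y)
  x_scale <- rep(1, ncol(X)); y_scale <- rep(1, ncol(Y))
  if (scale == "autoscale") {
    x_scale <- apply(X, 2, stats::sd)
    zero <- !is.finite(x_scale) | x_scale == 0
    if (any(zero)) {
      .warnf("dropping %d zero-variance predictor(s): %s", sum(zero),
             paste(utils::head(colnames(X)[zero], 5), collapse = ", "))
      X <- X[, !zero, drop = FALSE]
      x_center <- x_center[!zero]; x_scale <- x_scale[!zero]
    }
    y_scale <- apply(Y, 2, stats::sd)
    y_scale[!is.finite(y_scale) | y_scale == 0] <- 1
  }
  if (ncol(X) == 0) .stopf("no usable predictors left")
  if (A > min(n - 1, ncol(X)))
    .stopf("A = %d exceeds min(n - 1, predictors) = %d", A, min(n - 1, ncol(X)))
  names(x_scale) <- colnames(X); names(y_scale) <- colnames(Y)

  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  Ys <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")
  ss_y_total <- sum(Ys^2)

  W <- P <- matrix(0, ncol(X), A, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, ncol(Y), A, dimnames = list(colnames(Y), NULL))
  Tm <- U <- matrix(0, n, A)
  R2 <- numeric(A)
  iters <- integer(A)
  Xa <- Xs; Ya <- Ys
  for (a in seq_len(A)) {
    u <- Ya[, which.max(apply(Ya, 2, stats::var))]
    if (all(u == 0)) u <- Ya[, 1]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xa, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw == 0) .stopf("component %d: degenerate weight vector", a)
      w <- w / nw
      tt <- Xa %*% w
      q <- crossprod(Ya, tt)[, 1] / sum(tt^2)
      u <- if (sum(q^2) > 0) (Ya %*% q) / sum(q^2) else tt
      delta <- sqrt(sum((tt - t_old)^2)) / max(sqrt(sum(tt^2)), .Machine$double.eps)
      t_old <- tt
      if (delta < tol) break
    }
    iters[a] <- it
    p <- crossprod(Xa, tt)[, 1] / sum(tt^2)
    W[, a] <- w; P[, a] <- p; Q[, a] <- q
    Tm[, a] <- tt; U[, a] <- as.numeric(u)
    Xa <- Xa - tcrossprod(tt, p)
    Ya <- Ya - tcrossprod(tt, q)
    R2[a] <- 1 - sum(Ya^2) / ss_y_total
  }
  structure(list(W = W, P = P, Q = Q, T_scores = Tm, U = U,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 A = A, scale = scale, R2 = R2, iterations = iters,
                 predictors = colnames(X), responses = colnames(Y)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("pls_fit: %d predictors -> %d response(s), A = %d (%s)\n",
              length(x$predictors), length(x$responses), x$A, x$scale))
  cat("cumulative R2:", paste(sprintf("%.4f", x$R2), collapse = ", "), "\n")
  invisible(x)
}

#' Regression coefficients of a PLS fit (scaled blocks)
#' @param object a `pls_fit`.
#' @param ncomp number of components to use.
#' @param ... unused.
#' @return Matrix of coefficients (predictors x responses) on the scaled
#'   blocks.
#' @export
coef.pls_fit <- function(object, ncomp = object$A, ...) {
  W <- object$W[, seq_len(ncomp), drop = FALSE]
  P <- object$P[, seq_len(ncomp), drop = FALSE]
  Q <- object$Q[, seq_len(ncomp), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  R %*% t(Q)
}

#' Predict responses from a PLS fit
#' @param object a `pls_fit`.
#' @param newdata samples x predictors matrix (original units; columns must
#'   cover the fit's predictors).
#' @param ncomp number of components.
#' @param ... unused.
#' @return Matrix of predicted responses in original units.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$A, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) colnames(newdata) <- object$predictors
  newdata <- newdata[, object$predictors, drop = FALSE]
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  B <- coef.pls_fit(object, ncomp)
  Yhat <- Xs %*% B
  sweep(sweep(Yhat, 2, object$y_scale, "*"), 2, object$y_center, "+")
}

#' Leave-one-out Q2 of a PLS model
#'
#' Strict leave-one-out cross-validation: for each left-out sample the model
#' is refit from scratch on the remaining samples (including re-centering and
#' re-scaling on the training fold) and the held-out responses are predicted
#' with 1..A components. `Q2 = 1 - PRESS / TSS`, cumulative over components,
#' with both PRESS and TSS accumulated in training-fold-standardized response
#' units and TSS taken around the training-fold means.
#'
#' @inheritParams fit_pls
#' @return An object of class `pls_cv`: `Q2` (cumulative, per component),
#'   `PRESS`, `TSS`, and `failed_folds` (indices where refitting failed; Q2
#'   is `NA` if any fold failed).
#' @export
q_squared_loo <- function(X, Y, A = 2, scale = c("autoscale", "center")) {
  scale <- match.arg(scale)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X)
  if (n < 4) .stopf("leave-one-out Q2 needs n >= 4 samples")
  press <- matrix(0, n, A)
  tss <- numeric(n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_pls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], A = A,
              scale = scale),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, i)
      next
    }
    ysd <- fit$y_scale
    ytrain_mean <- fit$y_center
    yobs <- Y[i, fit$responses]
    tss[i] <- sum(((yobs - ytrain_mean) / ysd)^2)
    for (a in seq_len(A)) {
      yhat <- predict.pls_fit(fit, X[i, , drop = FALSE], ncomp = a)
      press[i, a] <- sum(((yobs - yhat[1, ]) / ysd)^2)
    }
  }
  if (length(failed)) {
    .warnf("leave-one-out refit failed on fold(s): %s",
           paste(failed, collapse = ", "))
    q2 <- rep(NA_real_, A)
  } else {
    q2 <- 1 - colSums(press) / sum(tss)
  }
  structure(list(Q2 = q2, PRESS = colSums(press), TSS = sum(tss),
                 failed_folds = failed, A = A, scale = scale),
            class = "pls_cv")
}

#' Gene ranking from first-component loadings
#'
#' Orders the predictors by their signed X-loading on the chosen component
#' (largest first); ties are broken by id for determinism.
#'
#' @param model a `pls_fit`.
#' @param component component number (default 1).
#' @return data.frame of class `gene_ranking` with columns `gene`,
#'   `loading`, `rank`.
#' @export
gene_loadings <- function(model, component = 1L) {
  stopifnot(inherits(model, "pls_fit"))
  if (component > model$A)
    .stopf("component %d not available (A = %d)", component, model$A)
  load <- model$P[, component]
  ord <- order(-load, names(load))
  out <- data.frame(gene = names(load)[ord], loading = unname(load[ord]),
                    rank = seq_along(load), stringsAsFactors = FALSE)
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Fit one PLS model per compound module
#'
#' For every module, the variance-stabilized serum levels of its member
#' compounds form the joint response block and the (FDR-significant) genes
#' the predictor block; each model is scored by cumulative R2 and
#' leave-one-out Q2 and summarized with its first-component gene ranking.
#'
#' @param genes an `omics_set` of variance-stabilized gene expression.
#' @param modules named list of member id vectors, a `module_clustering`, or
#'   a list of `module_spec` objects.
#' @param serum features x samples numeric matrix of variance-stabilized
#'   serum levels covering the module members (e.g. `rbind` of the
#'   metabolite and cytokine blocks).
#' @param sig_genes character vector of predictor gene ids (typically
#'   [significant_features()] of the gene test); `NULL` uses all genes.
#' @param A number of components.
#' @param scale scaling mode, see [fit_pls()].
#' @param ranking_component component whose loadings define each module's
#'   gene ranking (default 1). When the case-control contrast dominates every
#'   response block -- as in the synthetic cohorts, where all modules share
#'   one group axis -- the first component is common to all modules and the
#'   module-specific covariation sits on component 2.
#' @return An object of class `module_pls`: per-module list of `fit`, `cv`,
#'   `ranking`, plus a `summary` data.frame (module, n_compounds, A, R2_cum,
#'   Q2_cum).
#' @export
fit_all_modules <- function(genes, modules, serum, sig_genes = NULL,
                            A = 2, scale = "autoscale",
                            ranking_component = 1L) {
  stopifnot(inherits(genes, "omics_set"))
  if (inherits(modules, "module_clustering")) {
    labels <- modules$labels
    modules <- split(names(labels), labels)
    names(modules) <- paste0("module_", names(modules))
  } else if (length(modules) && inherits(modules[[1]], "module_spec")) {
    modules <- stats::setNames(lapply(modules, function(m) m$members$id),
                               vapply(modules, `[[`, "", "name"))
  }
  if (is.null(sig_genes)) sig_genes <- rownames(genes$values)
  if (!length(sig_genes))
    .stopf(paste("no predictor genes: the upstream differential test",
                 "returned an empty significant-gene list"))
  X <- t(genes$values[sig_genes, , drop = FALSE])
  fits <- list()
  for (m in names(modules)) {
    members <- intersect(modules[[m]], rownames(serum))
    if (length(members) < 1) {
      .warnf("module %s skipped: no member compounds in the serum matrix", m)
      next
    }
    Y <- t(serum[members, , drop = FALSE])
    Am <- min(A, nrow(X) - 1, ncol(X))
    fit <- fit_pls(X, Y, A = Am, scale = scale)
    cv <- q_squared_loo(X, Y, A = Am, scale = scale)
    fits[[m]] <- list(fit = fit, cv = cv,
                      ranking = gene_loadings(fit, min(ranking_component, Am)),
                      members = members)
  }
  if (!length(fits)) .stopf("no module could be fitted")
  summary <- data.frame(
    module = names(fits),
    n_compounds = vapply(fits, function(f) length(f$members), integer(1)),
    A = vapply(fits, function(f) f$fit$A, numeric(1)),
    R2_cum = vapply(fits, function(f) f$fit$R2[f$fit$A], numeric(1)),
    Q2_cum = vapply(fits, function(f) f$cv$Q2[f$cv$A], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(models = fits, summary = summary), class = "module_pls")
}

#' @export
print.module_pls <- function(x, ...) {
  cat("module_pls:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write PLS summaries and per-module loadings as TSV
#' @param x a `module_pls`.
#' @param dir output directory.
#' @export
write_pls_tsv <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$summary, file.path(dir, "pls_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(x$models)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", m)
    utils::write.table(x$models[[m]]$ranking,
                       file.path(dir, sprintf("loadings_%s.tsv", safe)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
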