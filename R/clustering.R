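#' Absolute Spearman correlation matrix
#'
#' Pairwise absolute Spearman correlations (average-rank tie handling, as in
#' [stats::cor()]) between the feature profiles of an omics set or a plain
#' features x samples matrix. Constant features get correlation 0 with a
#' warning.
#'
#' @param x an `omics_set`, or a numeric matrix (features in rows).
#' @return Symmetric matrix of |r| values with unit diagonal.
#' @export
spearman_abs_corr <- function(x) {
  v <- if (inherits(x, "omics_set")) x$values else x
  if (ncol(v) < 3) .stopf("need >= 3 samples for rank correlations")
  cm <- suppressWarnings(stats::cor(t(v), method = "spearman",
                                    use = "pairwise.complete.obs"))
  if (anyNA(cm)) {
    .warnf("undefined correlations (constant features?) set to 0")
    cm[is.na(cm)] <- 0
  }
  cm <- abs(cm)
  diag(cm) <- 1
  cm
}

#' Correlation-based distance
#'
#' Elementwise `d = sqrt(2 * (1 - r^2))`, mapping |r| = 1 to distance 0 and
#' r = 0 to `sqrt(2)`.
#'
#' @param corr matrix of absolute correlations in \[0, 1\].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
corr_distance <- function(corr) {
  if (any(corr < 0 | corr > 1, na.rm = TRUE))
    .stopf("correlation entries must lie in [0, 1]")
  d <- sqrt(2 * (1 - corr^2))
  d <- pmax(d, 0)
  diag(d) <- 0
  d
}

.clustering_result <- function(method, k, labels, medoids, dist) {
  sil <- silhouette_width(dist, labels)
  structure(list(method = method, k = k, labels = labels, medoids = medoids,
                 sil_widths = sil$widths, mean_sil = sil$mean),
            class = "module_clustering")
}

#' @export
print.module_clustering <- function(x, ...) {
  cat(sprintf("module_clustering: %s, k = %d, mean silhouette = %.3f\n",
              x$method, x$k, x$mean_sil))
  print(table(x$labels))
  invisible(x)
}

#' Partitioning Around Medoids on a precomputed distance
#'
#' Deterministic BUILD + SWAP k-medoids ([cluster::pam()]) on the distance
#' matrix; the swap phase never increases the objective (total distance to
#' medoids).
#'
#' @param dist symmetric distance matrix with feature ids as dimnames.
#' @param k number of clusters, `2 <= k < n`.
#' @param seed unused by PAM itself (BUILD is deterministic); kept for
#'   interface symmetry with [alt_cluster()].
#' @return An object of class `module_clustering`: method, k, per-feature
#'   labels, medoid ids, silhouette widths and their mean.
#' @export
pam_cluster <- function(dist, k, seed = 0L) {
  n <- nrow(dist)
  if (k < 2 || k >= n) .stopf("need 2 <= k < n (k = %d, n = %d)", k, n)
  fit <- cluster::pam(stats::as.dist(dist), k = k, diss = TRUE)
  labels <- fit$clustering
  names(labels) <- rownames(dist)
  .clustering_result("pam", k, labels, fit$medoids, dist)
}

#' Alternative clustering methods on a precomputed distance
#'
#' `kmeans` operates on a classical multidimensional-scaling embedding of the
#' distance (up to `min(n - 1, 10)` dimensions); `hierarchical` is
#' average-linkage agglomeration cut at `k`.
#'
#' @inheritParams pam_cluster
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param seed RNG seed for the k-means restarts.
#' @return A `module_clustering` (no medoids).
#' @export
alt_cluster <- function(dist, k, method = c("kmeans", "hierarchical"),
                        seed = 0L) {
  method <- match.arg(method)
  n <- nrow(dist)
  if (k < 2 || k > n) .stopf("need 2 <= k <= n (k = %d, n = %d)", k, n)
  if (method == "kmeans") {
    ndim <- min(n - 1, 10)
    emb <- suppressWarnings(stats::cmdscale(stats::as.dist(dist), k = ndim))
    with_preserved_seed(seed, {
      fit <- stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100)
    })
    labels <- fit$cluster
  } else {
    hc <- stats::hclust(stats::as.dist(dist), method = "average")
    labels <- stats::cutree(hc, k = k)
  }
  names(labels) <- rownames(dist)
  if (k == n) {
    # singletons: silhouette undefined in the usual sense; widths are 0
    sil <- list(widths = stats::setNames(rep(0, n), rownames(dist)), mean = 0)
    return(structure(list(method = method, k = k, labels = labels,
                          medoids = NULL, sil_widths = sil$widths,
                          mean_sil = sil$mean),
                     class = "module_clustering"))
  }
  .clustering_result(method, k, labels, NULL, dist)
}

#' Silhouette widths for a clustering
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance to
#' the own cluster and `b(i)` the smallest mean distance to another cluster;
#' members of singleton clusters get width 0.
#'
#' @param dist symmetric distance matrix.
#' @param labels integer cluster labels (named or in row order).
#' @return list with `widths` (named numeric) and `mean`.
#' @export
silhouette_width <- function(dist, labels) {
  if (length(unique(labels)) < 2)
    .stopf("silhouette needs >= 2 clusters")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dmatrix = as.matrix(dist))
  widths <- stats::setNames(sil[, "sil_width"],
                            rownames(dist) %||% seq_along(labels))
  list(widths = widths, mean = mean(widths))
}

#' Silhouette-guided method and k selection
#'
#' Evaluates every clustering method over `k_range` and returns the candidate
#' with the largest mean silhouette width; ties are broken by smaller k, then
#' by method order (PAM first).
#'
#' @param dist symmetric distance matrix.
#' @param k_range candidate cluster counts (clamped to `[2, n - 1]`).
#' @param methods subset of `c("pam", "kmeans", "hierarchical")`.
#' @param seed RNG seed for the k-means restarts.
#' @param warn_below mean-silhouette level under which a weak-structure
#'   warning is emitted.
#' @return list with `method`, `k`, `result` (the winning
#'   `module_clustering`) and `candidates` (data.frame of method, k,
#'   mean_sil).
#' @export
select_modules <- function(dist, k_range = 2:10,
                           methods = c("pam", "kmeans", "hierarchical"),
                           seed = 0L, warn_below = 0.25) {
  n <- nrow(dist)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range))
    .stopf("empty k range after clamping to [2, %d]", n - 1)
  methods <- match.arg(methods, several.ok = TRUE)
  cand <- expand.grid(k = k_range, method = methods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  results <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    results[[i]] <- if (cand$method[i] == "pam") {
      pam_cluster(dist, cand$k[i], seed)
    } else {
      alt_cluster(dist, cand$k[i], cand$method[i], seed)
    }
  }
  cand$mean_sil <- vapply(results, `[[`, numeric(1), "mean_sil")
  ord <- order(-cand$mean_sil, cand$k,
               match(cand$method, c("pam", "kmeans", "hierarchical")))
  best <- ord[1]
  if (cand$mean_sil[best] < warn_below)
    .warnf("weak cluster structure: best mean silhouette %.3f < %.2f",
           cand$mean_sil[best], warn_below)
  list(method = cand$method[best], k = cand$k[best],
       result = results[[best]],
       candidates = cand[, c("method", "k", "mean_sil")])
}

#' Signed module profiles
#'
#' Per module, features are z-scored across samples and averaged; members
#' whose profile correlates negatively with the running average get sign -1
#' and are flipped before re-averaging (two refinement passes). The returned
#' profile is the z-scored average.
#'
#' @param x an `omics_set` on the scale used for clustering.
#' @param clustering a `module_clustering` (or any named label vector).
#' @return list of `module_profile` objects: `name`, `members`, `signs`
#'   (+1/-1 per member) and `profile` (named per-sample vector).
#' @export
module_profiles <- function(x, clustering) {
  labels <- if (inherits(clustering, "module_clustering")) clustering$labels
            else clustering
  v <- x$values[names(labels), , drop = FALSE]
  z <- .zscore_rows(v)
  lapply(sort(unique(labels)), function(cl) {
    members <- names(labels)[labels == cl]
    zm <- z[members, , drop = FALSE]
    signs <- stats::setNames(rep(1, length(members)), members)
    for (pass in 1:2) {
      avg <- colMeans(zm * signs)
      # perfectly cancelling members leave a flat average; fall back to the
      # first member as the reference orientation
      if (!is.finite(stats::sd(avg)) || stats::sd(avg) == 0) avg <- zm[1, ]
      cc <- suppressWarnings(apply(zm, 1, stats::cor, y = avg))
      cc[is.na(cc)] <- 1
      signs <- stats::setNames(ifelse(cc < 0, -1, 1), members)
    }
    avg <- colMeans(zm * signs)
    s <- stats::sd(avg)
    profile <- if (is.finite(s) && s > 0) (avg - mean(avg)) / s else avg
    structure(list(name = paste0("module_", cl), members = members,
                   signs = signs, profile = profile),
              class = "module_profile")
  })
}

#' Write module assignments and profiles as TSV
#'
#' @param clustering a `module_clustering`.
#' @param profiles output of [module_profiles()].
#' @param dir output directory.
#' @return `dir`, invisibly; writes `modules.tsv` (feature, module, sign,
#'   silhouette) and `profiles.tsv` (module x sample).
#' @export
write_modules_tsv <- function(clustering, profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  signs <- unlist(lapply(profiles, `[[`, "signs"))
  feats <- names(clustering$labels)
  df <- data.frame(feature = feats,
                   module = unname(clustering$labels[feats]),
                   sign = unname(signs[feats]),
                   silhouette = unname(clustering$sil_widths[feats]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$module, df$feature), ]
  utils::write.table(df, file.path(dir, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof <- do.call(rbind, lapply(profiles, `[[`, "profile"))
  rownames(prof) <- vapply(profiles, `[[`, "", "name")
  utils::write.table(data.frame(module = rownames(prof), prof,
                                check.names = FALSE),
                     file.path(dir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
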