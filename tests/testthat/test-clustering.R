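# brute-force silhouette straight from the definition
brute_silhouette <- function(d, labels) {
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

euclid <- function(x) {
  d <- as.matrix(dist(x))
  dimnames(d) <- list(names(x), names(x))
  d
}

test_that("absolute Spearman correlation matches hand-ranked values", {
  v <- rbind(x = 1:5, y = c(1, 3, 2, 5, 4), z = 5:1)
  xs <- toy_set(v, n_case = 3)
  r <- spearman_abs_corr(xs)
  expect_equal(diag(r), c(x = 1, y = 1, z = 1))
  expect_equal(r["x", "y"], 0.8)   # 1 - 6*4/(5*24)
  expect_equal(r["x", "z"], 1)     # perfectly decreasing -> |r| = 1
  vc <- rbind(v, const = rep(2, 5))
  expect_warning(r2 <- spearman_abs_corr(toy_set(vc, n_case = 3)), "constant")
  expect_equal(unname(r2["const", "x"]), 0)
})

test_that("correlation distance follows sqrt(2(1 - r^2))", {
  r <- matrix(c(1, 0.5, 0, 0.5, 1, 1, 0, 1, 1), 3, 3)
  d <- corr_distance(r)
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d[1, 2], sqrt(1.5))
  expect_equal(d[1, 3], sqrt(2))
  expect_equal(d[2, 3], 0)
  expect_error(corr_distance(matrix(c(1, 2, 2, 1), 2)), "\\[0, 1\\]")
})

test_that("PAM agrees with exhaustive medoid search on a 1-D toy", {
  pts <- c(a = 0, b = 1, c = 10, d = 11)
  d <- euclid(pts)
  # exhaustive: best pair of medoids by total distance
  best <- NULL
  for (pair in asplit(combn(4, 2), 2)) {
    obj <- sum(apply(d[, pair, drop = FALSE], 1, min))
    if (is.null(best) || obj < best$obj) best <- list(pair = pair, obj = obj)
  }
  labs <- apply(d[, best$pair], 1, which.min)
  res <- pam_cluster(d, 2)
  # compare partitions (cluster labels and tied medoids are arbitrary)
  expect_setequal(unname(lapply(split(names(labs), labs), sort)),
                  unname(lapply(split(names(res$labels), res$labels), sort)))
  expect_equal(sum(apply(d[, res$medoids], 1, min)), best$obj)

  # k = n - 1 forces exactly one 2-point cluster
  res3 <- pam_cluster(d, 3)
  expect_equal(as.integer(sort(table(res3$labels))), c(1L, 1L, 2L))
  expect_error(pam_cluster(d, 4), "k < n")
})

test_that("silhouette widths match the brute-force definition", {
  pts <- c(a = 0, b = 0.1, c = 10, d = 10.1)
  d <- euclid(pts)
  sil <- silhouette_width(d, c(1, 1, 2, 2))
  expect_equal(sil$mean, 0.98995, tolerance = 1e-4)

  set.seed(41)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    x <- rnorm(n); names(x) <- paste0("p", seq_len(n))
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    d <- euclid(x)
    expect_equal(unname(silhouette_width(d, labels)$widths),
                 brute_silhouette(d, labels), tolerance = 1e-12)
  }
  expect_error(silhouette_width(euclid(x), rep(1, length(x))), ">= 2")
})

test_that("random labels on i.i.d. points give near-zero mean silhouette", {
  set.seed(43)
  means <- replicate(60, {
    x <- matrix(rnorm(20 * 5), 20)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("p", 1:20), paste0("p", 1:20))
    silhouette_width(d, sample(1:3, 20, replace = TRUE))$mean
  })
  expect_lt(abs(mean(means)), 0.1)
})

test_that("silhouette-guided selection finds planted block counts", {
  make_blocks <- function(k, per = 5, n = 40, noise = 0.08, seed = 44) {
    set.seed(seed)
    f <- matrix(rnorm(k * n), k, n)
    v <- do.call(rbind, lapply(seq_len(k), function(m) {
      t(sapply(seq_len(per), function(i) f[m, ] + rnorm(n, sd = noise)))
    }))
    rownames(v) <- sprintf("f%02d", seq_len(nrow(v)))
    colnames(v) <- sprintf("s%02d", seq_len(n))
    corr_distance(spearman_abs_corr(v))
  }
  sel2 <- select_modules(make_blocks(2), methods = "pam")
  expect_equal(sel2$k, 2L)
  sel6 <- select_modules(make_blocks(6), methods = "pam")
  expect_equal(sel6$k, 6L)
  expect_equal(sel6$method, "pam")

  set.seed(45)
  noise <- matrix(rnorm(15 * 30), 15,
                  dimnames = list(sprintf("f%02d", 1:15), NULL))
  colnames(noise) <- sprintf("s%02d", 1:30)
  expect_warning(seln <- select_modules(corr_distance(spearman_abs_corr(noise)),
                                        methods = "pam"),
                 "weak cluster structure")
  expect_lt(seln$result$mean_sil, 0.25)
})

test_that("all methods agree on well-separated blobs; hierarchical singletons", {
  skip_if_not_installed("mclust")
  set.seed(46)
  x <- c(rnorm(6, 0, 0.1), rnorm(6, 50, 0.1))
  names(x) <- paste0("p", 1:12)
  d <- euclid(x)
  truth <- rep(1:2, each = 6)
  for (m in c("kmeans", "hierarchical")) {
    res <- alt_cluster(d, 2, m)
    expect_equal(mclust::adjustedRandIndex(res$labels, truth), 1, label = m)
  }
  expect_equal(mclust::adjustedRandIndex(pam_cluster(d, 2)$labels, truth), 1)
  singles <- alt_cluster(d, 12, "hierarchical")
  expect_equal(length(unique(singles$labels)), 12L)
})

test_that("PAM partition is invariant under feature reordering", {
  skip_if_not_installed("mclust")
  st <- shared_study()
  sig <- c(st$sig_metab, st$sig_cyto)
  d <- corr_distance(spearman_abs_corr(st$serum[sig, ]))
  res <- pam_cluster(d, 6)
  set.seed(47)
  perm <- sample(nrow(d))
  res_p <- pam_cluster(d[perm, perm], 6)
  expect_equal(mclust::adjustedRandIndex(res$labels[rownames(d)],
                                         res_p$labels[rownames(d)]), 1)
})

test_that("module profiles carry signs and separate the groups", {
  # identical features: profile is the scaled feature, signs +1
  v <- rbind(a = 1:8, b = 1:8, c = 1:8)
  xs <- toy_set(v, n_case = 4)
  # anti-correlated pair: signs split, profile follows the positive member
  v2 <- rbind(up = 1:8, down = -(1:8), other = rep(c(1, 2), 4),
              other2 = rep(c(2, 1), 4))
  xs2 <- toy_set(v2, n_case = 4)
  labels <- c(up = 1, down = 1, other = 2, other2 = 2)
  prof <- module_profiles(xs2, labels)
  expect_equal(unname(prof[[1]]$signs), c(1, -1))
  expect_equal(abs(cor(prof[[1]]$profile, 1:8)), 1)

  labels1 <- c(a = 1, b = 1, c = 2)
  prof1 <- module_profiles(xs, labels1)
  expect_equal(unname(prof1[[1]]$signs), c(1, 1))
  expect_equal(abs(cor(prof1[[1]]$profile, 1:8)), 1)

  # default cohort: the cytokine module profile separates the groups
  st <- shared_study()
  sig <- c(st$sig_metab, st$sig_cyto)
  d <- corr_distance(spearman_abs_corr(st$serum[sig, ]))
  sel <- suppressWarnings(select_modules(d, methods = "pam"))
  serum_set <- omics_set(st$serum[sig, ], "metabolite", st$metab_v$groups)
  profs <- module_profiles(serum_set, sel$result)
  cyto_mod <- which(vapply(profs, function(p) "IL-6" %in% p$members,
                           logical(1)))
  pb <- abs(cor(profs[[cyto_mod]]$profile,
                as.numeric(st$metab_v$groups == "MHE")))
  expect_gte(pb, 0.6)
})
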