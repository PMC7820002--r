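test_that("a proportional response is fit perfectly by one component", {
  x <- matrix(rnorm(10), dimnames = list(NULL, "g1"))
  fit <- fit_pls(x, 3 * x[, 1], A = 1)
  expect_equal(fit$R2[1], 1, tolerance = 1e-10)
  expect_equal(abs(unname(fit$W[1, 1])), 1, tolerance = 1e-10)
  expect_equal(gene_loadings(fit)$gene, "g1")
})

test_that("full-rank PLS on a single response equals least squares", {
  set.seed(51)
  X <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, paste0("g", 1:3)))
  y <- rnorm(8)
  fit <- fit_pls(X, y, A = 3)
  yhat <- predict(fit, X)[, 1]
  ols <- fitted(lm(y ~ X))
  expect_equal(unname(yhat), unname(ols), tolerance = 1e-6)
})

test_that("scores are orthogonal, weights unit-norm, R2 non-decreasing", {
  set.seed(52)
  X <- matrix(rnorm(11 * 30), 11, 30)
  Y <- matrix(rnorm(11 * 4), 11, 4)
  fit <- fit_pls(X, Y, A = 5)
  G <- crossprod(fit$T_scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  expect_equal(unname(colSums(fit$W^2)), rep(1, 5), tolerance = 1e-10)
  expect_true(all(diff(fit$R2) >= -1e-12))
  # overfit limit: A = n - 1 components on generic data explain everything
  full <- fit_pls(X, Y, A = 10)
  expect_equal(full$R2[10], 1, tolerance = 1e-6)
})

test_that("autoscaling makes fits invariant to predictor rescaling", {
  set.seed(53)
  X <- matrix(rnorm(9 * 5), 9, 5)
  Y <- matrix(rnorm(9 * 2), 9, 2)
  fit1 <- fit_pls(X, Y, A = 2)
  X2 <- X; X2[, 3] <- X2[, 3] * 7
  fit2 <- fit_pls(X2, Y, A = 2)
  expect_equal(predict(fit1, X), predict(fit2, X2), tolerance = 1e-8)
  # zero-variance predictor dropped with warning
  X3 <- X; X3[, 2] <- 5
  expect_warning(fit3 <- fit_pls(X3, Y, A = 2), "zero-variance")
  expect_equal(length(fit3$predictors), 4L)
  expect_error(fit_pls(X, Y, A = 9), "exceeds")
})

test_that("leave-one-out Q2 equals an independently coded CV loop", {
  set.seed(54)
  X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("g", 1:4)))
  Y <- matrix(rnorm(6 * 2), 6, 2, dimnames = list(NULL, c("y1", "y2")))
  cv <- q_squared_loo(X, Y, A = 2)
  press <- matrix(0, 6, 2); tss <- numeric(6)
  for (i in 1:6) {
    f <- fit_pls(X[-i, ], Y[-i, ], A = 2)
    sc <- f$y_scale; ctr <- f$y_center
    tss[i] <- sum(((Y[i, ] - ctr) / sc)^2)
    for (a in 1:2) {
      pr <- predict(f, X[i, , drop = FALSE], ncomp = a)
      press[i, a] <- sum(((Y[i, ] - pr[1, ]) / sc)^2)
    }
  }
  expect_equal(cv$Q2, 1 - colSums(press) / sum(tss), tolerance = 1e-12)
  expect_equal(cv$PRESS, colSums(press), tolerance = 1e-12)
})

test_that("Q2 is high for predictable responses, non-positive under the null", {
  set.seed(55)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- X %*% c(1, -2, 0.5) + rnorm(12, sd = 0.05)
  expect_gt(q_squared_loo(X, y, A = 2)$Q2[2], 0.9)

  q2null <- replicate(100, {
    q_squared_loo(X, y[sample(12)], A = 2)$Q2[2]
  })
  expect_lte(mean(q2null), 0)
})

test_that("flipping the response sign reverses the loading ranking", {
  set.seed(56)
  X <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- X %*% rnorm(6) + rnorm(10, sd = 0.2)
  f1 <- fit_pls(X, y, A = 1)
  f2 <- fit_pls(X, -y, A = 1)
  expect_equal(unname(f1$P[, 1]), -unname(f2$P[, 1]), tolerance = 1e-8)
  r1 <- gene_loadings(f1); r2 <- gene_loadings(f2)
  expect_equal(r1$gene, rev(r2$gene))
})

test_that("NIPALS matches the reference multivariate PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(57)
  X <- matrix(rnorm(11 * 20), 11, 20, dimnames = list(NULL, paste0("g", 1:20)))
  Y <- matrix(rnorm(11 * 3), 11, 3, dimnames = list(NULL, paste0("y", 1:3)))
  mine <- fit_pls(X, Y, A = 2)
  ref <- mixOmics::pls(X, Y, ncomp = 2, scale = TRUE, mode = "regression")
  for (a in 1:2) {
    expect_gt(abs(cor(mine$T_scores[, a], ref$variates$X[, a])), 0.999)
  }
})

test_that("per-module fits report one model per module with gene rankings", {
  st <- shared_study()
  pls <- shared_pls()
  expect_equal(nrow(pls$summary), 6L)
  expect_true(all(pls$summary$n_compounds ==
                    lengths(lapply(st$cohort$truth$modules,
                                   function(m) m$members$id))))
  rk <- pls$models[[1]]$ranking
  expect_setequal(rk$gene, st$sig_genes)
  expect_equal(rk$rank, seq_len(nrow(rk)))

  # coupled genes concentrate in the extreme deciles of the ranking on the
  # module-specific component (the shared case-control contrast occupies
  # component 1, so module identity sits on component 2); the theoretical
  # ceiling of the fold enrichment is 1 / 0.2 = 5
  coupled <- intersect(st$cohort$truth$modules$M1_cytokines$coupled_genes,
                       st$sig_genes)
  rk2 <- gene_loadings(pls$models$M1_cytokines$fit, component = 2L)
  G <- nrow(rk2)
  extreme <- c(rk2$gene[seq_len(ceiling(0.1 * G))],
               rk2$gene[seq(floor(0.9 * G), G)])
  obs <- mean(coupled %in% extreme)
  expect_gte(obs / 0.2, 4)

  expect_error(fit_all_modules(st$genes_v, list(m = "Met"),
                               st$serum, sig_genes = character(0)),
               "upstream")
  expect_warning(
    fit_all_modules(st$genes_v,
                    list(ok = st$cohort$truth$modules$M1_cytokines$members$id,
                         gone = "not_a_compound"),
                    st$serum, sig_genes = st$sig_genes[1:50]),
    "skipped")
})
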