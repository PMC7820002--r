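test_that("metabolite catalog matches the targeted-panel composition", {
  cat <- default_metabolite_catalog()
  expect_equal(nrow(cat), 143L)
  expect_equal(anyDuplicated(cat$id), 0L)
  counts <- table(cat$class)
  expect_equal(unname(counts[c("acylcarnitine", "amino acid",
                               "biogenic amine", "hexose", "sphingomyelin",
                               "glycerophospholipid")]),
               c(8L, 21L, 17L, 1L, 15L, 81L), ignore_attr = TRUE)
  # catalog baselines are stable regardless of the caller's RNG state
  set.seed(1); a <- default_metabolite_catalog()
  set.seed(999); b <- default_metabolite_catalog()
  expect_identical(a, b)
})

test_that("lipid side-chain notation parses carbons and double bonds", {
  p <- parse_lipid_notation(c("PC aa C36:4", "SM (OH) C14:1", "C18:2",
                              "lysoPC a C20:3", "Met"))
  expect_equal(p$carbons, c(36L, 14L, 18L, 20L, NA))
  expect_equal(p$double_bonds, c(4L, 1L, 2L, 3L, NA))
  expect_equal(p$bond_type, c("aa", NA, NA, "a", NA))
})

test_that("cohort has the study design and is seed-deterministic", {
  st <- shared_study()
  co <- st$cohort
  expect_equal(length(co$groups), 11L)
  expect_equal(unname(table(co$groups)[c("MHE", "noMHE")]), c(6L, 5L),
               ignore_attr = TRUE)
  expect_equal(length(co$truth$modules), 6L)
  expect_identical(colnames(co$genes$values), colnames(co$metabolites$values))
  expect_identical(colnames(co$genes$values), colnames(co$cytokines$values))
  co2 <- generate_full_cohort(default_cohort_config(seed = 101))
  expect_identical(co$genes$values, co2$genes$values)
  expect_identical(co$metabolites$values, co2$metabolites$values)
  co3 <- generate_full_cohort(default_cohort_config(seed = 202))
  expect_false(identical(co$genes$values, co3$genes$values))
})

test_that("written cohorts are byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  small <- function() default_cohort_config(seed = 7, n_genes = 200,
                                            n_gene_effects = 60,
                                            coupled_per_module = 10)
  write_cohort(generate_full_cohort(small()), d1)
  write_cohort(generate_full_cohort(small()), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("gene generator: null cohorts are centered, planted effects unbiased", {
  design <- cohort_design(6, 5, seed = 11)
  null <- generate_gene_matrix(design, n_genes = 500, planted = NULL)
  g2 <- null$groups == "MHE"
  diffs <- rowMeans(null$values[, g2]) - rowMeans(null$values[, !g2])
  expect_equal(dim(null$values), c(500L, 11L))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(500))

  # 2000 Monte-Carlo replicates of a unit planted effect in one call
  planted <- data.frame(id = sprintf("G%05d", 1:2000), logFC = 1.0)
  x <- generate_gene_matrix(cohort_design(6, 5, seed = 12), n_genes = 2000,
                            planted = planted)
  est <- rowMeans(x$values[, g2]) - rowMeans(x$values[, !g2])
  expect_lt(abs(mean(est) - 1.0), 3 * sd(est) / sqrt(length(est)))
})

test_that("generator rejects ids outside the catalog and overlapping modules", {
  design <- cohort_design(6, 5, seed = 1)
  expect_error(generate_gene_matrix(design, n_genes = 10,
                                    planted = data.frame(id = "G99999", logFC = 1)),
               "G99999")
  cat <- default_metabolite_catalog()
  expect_error(generate_serum_panel(design, cat,
                                    planted = data.frame(id = "nope", logFC = 1)),
               "nope")
  m1 <- module_spec("a", data.frame(id = "Met", sign = 1, magnitude = 0.2), 2)
  m2 <- module_spec("b", data.frame(id = "Met", sign = 1, magnitude = 0.2), 2)
  expect_error(generate_serum_panel(design, cat, modules = list(a = m1, b = m2)),
               "more than one module")
})

test_that("LOD censoring is deterministic and hits the analytic fraction", {
  x <- toy_set(matrix(abs(rnorm(50, 10)), nrow = 5))
  expect_identical(censor_below_lod(x, 0)$values, x$values)
  lodv <- c(f001 = 1e6)
  cens <- censor_below_lod(x, lodv)
  expect_true(all(is.na(cens$values["f001", ])))
  expect_true(!anyNA(cens$values[-1, ]))
  expect_error(censor_below_lod(x, -1), "non-negative")

  # normal feature censored at its 30th-percentile threshold
  set.seed(42)
  n <- 4000
  v <- matrix(rnorm(n, mean = 10, sd = 2), nrow = 1,
              dimnames = list("f", sprintf("s%04d", 1:n)))
  xs <- omics_set(v, "metabolite",
                  factor(rep(c("a", "b"), n / 2), levels = c("a", "b")))
  lod <- 10 + qnorm(0.30) * 2
  frac <- mean(is.na(censor_below_lod(xs, c(f = lod))$values))
  expect_lt(abs(frac - 0.30), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("module members co-vary within modules more than between", {
  st <- shared_study()
  tm <- truth_membership(st$cohort)
  r <- spearman_abs_corr(log2(st$cohort$metabolites$values[
    intersect(tm$id, rownames(st$cohort$metabolites$values)), ]))
  mod <- tm$module[match(rownames(r), tm$id)]
  same <- outer(mod, mod, "==") & upper.tri(r)
  diff <- !outer(mod, mod, "==") & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff]))
  expect_gt(mean(r[same]), 0.9)
})

test_that("zero loadings leave members uncorrelated beyond chance", {
  cat <- default_metabolite_catalog()
  ids <- c("Ala", "Gly", "Ser", "Thr", "Pro")
  m <- module_spec("flat", data.frame(id = ids, sign = 1, magnitude = 0),
                   group_shift = 3.5)
  design <- cohort_design(6, 5, seed = 33)
  out <- generate_serum_panel(design, cat, modules = list(flat = m))
  r <- spearman_abs_corr(log2(out$metabolites$values[ids, ]))
  expect_lt(mean(r[upper.tri(r)]), 0.6)
})
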