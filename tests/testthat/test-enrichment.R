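write_toy_gmt <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}

test_that("GMT parsing keeps descriptions, dedups members, flags bad lines", {
  f <- write_toy_gmt(c("SET_A\tfirst set\tg1\tg2\tg3",
                       "SET_B\tsecond set\tg2\tg4\tg4"))
  gs <- read_gmt(f)
  expect_equal(names(gs$sets), c("SET_A", "SET_B"))
  expect_equal(gs$sets$SET_B, c("g2", "g4"))
  expect_equal(unname(gs$description["SET_A"]), "first set")

  expect_error(read_gmt(write_toy_gmt(c("SET_A\tdesc\tg1", "BAD_LINE\tonly2"))),
               "line 2")
  expect_warning(empty <- read_gmt(write_toy_gmt(character(0))), "empty")
  expect_equal(length(empty$sets), 0L)
  expect_warning(gene_set_collection(list(a = character(), b = "g1")), "empty")
})

test_that("GMT reader agrees with the reference parser", {
  skip_if_not_installed("fgsea")
  st <- shared_study()
  f <- tempfile(fileext = ".gmt")
  write_gmt(st$cohort$gene_sets, f)
  mine <- read_gmt(f)
  ref <- fgsea::gmtPathways(f)
  expect_equal(mine$sets, ref[names(mine$sets)], ignore_attr = TRUE)
})

test_that("over-representation p-values match hypergeometric enumeration", {
  universe <- paste0("g", 1:8)
  sets <- gene_set_collection(list(S = paste0("g", 1:4)))
  res <- fisher_ora(paste0("g", c(1, 2, 3, 5)), universe, sets)
  expect_equal(res$p, 17 / 70, tolerance = 1e-12)
  expect_equal(res$overlap, 3L)

  # zero overlap and saturated selection are degenerate
  res0 <- fisher_ora(paste0("g", 5:8), universe,
                     gene_set_collection(list(S = paste0("g", 1:4))))
  expect_equal(res0$p, 1)
  resall <- fisher_ora(universe, universe, sets)
  expect_equal(resall$p, 1)
  expect_warning(fisher_ora(character(0), universe, sets), "empty")
  expect_error(fisher_ora("zz", universe, sets), "outside")

  # random small instances against an explicit enumeration oracle
  set.seed(61)
  for (rep in 1:12) {
    N <- sample(8:20, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(2:(N - 1), 1); n <- sample(2:(N - 1), 1)
    members <- sample(uni, K); sel <- sample(uni, n)
    k <- length(intersect(members, sel))
    oracle <- sum(vapply(k:min(K, n), function(j) {
      choose(K, j) * choose(N - K, n - j)
    }, numeric(1))) / choose(N, n)
    res <- fisher_ora(sel, uni, gene_set_collection(list(S = members)))
    expect_equal(res$p, oracle, tolerance = 1e-10)
  }
})

test_that("ranked enrichment detects extreme placement and is antisymmetric", {
  G <- 200
  ranking <- data.frame(gene = paste0("g", 1:G),
                        loading = seq(1, -1, length.out = G), rank = 1:G)
  class(ranking) <- c("gene_ranking", "data.frame")
  top_set <- gene_set_collection(list(TOP = paste0("g", 1:10)))
  res_top <- ranked_enrichment(ranking, top_set)
  expect_gt(res_top$coef, 0)
  expect_equal(res_top$direction, "top")

  set.seed(62)
  random_p <- replicate(400, {
    s <- gene_set_collection(list(R = sample(ranking$gene, 10)))
    ranked_enrichment(ranking, s)$p
  })
  expect_lt(res_top$p, min(random_p))

  rev_ranking <- ranking
  rev_ranking$gene <- rev(ranking$gene)
  res_rev <- ranked_enrichment(rev_ranking, top_set)
  expect_equal(res_rev$coef, -res_top$coef, tolerance = 1e-8)
  expect_warning(ranked_enrichment(ranking,
                                   gene_set_collection(list(tiny = "g1"))),
                 "skipped")
})

test_that("pathway crosstalk edges follow the Jaccard rule", {
  uni <- paste0("g", 1:40)
  sets <- gene_set_collection(list(
    A = paste0("g", 1:10), B = paste0("g", 6:15), C = paste0("g", 30:35),
    Adup = paste0("g", 1:10)))
  res <- fisher_ora(paste0("g", 1:12), uni, sets, alpha = 1.1, relaxed = 1.2)
  # alpha > 1 marks every set significant so the graph covers all four
  g <- pathway_network(res, sets, jaccard_min = 0.1)
  el <- igraph::as_data_frame(g)
  ab <- el[(el$from == "A" & el$to == "B") | (el$from == "B" & el$to == "A"), ]
  expect_equal(ab$weight, 5 / 15, tolerance = 1e-12)
  dup <- el[(el$from == "A" & el$to == "Adup") | (el$from == "Adup" & el$to == "A"), ]
  expect_equal(dup$weight, 1)
  expect_false(any((el$from == "A" & el$to == "C") |
                     (el$from == "C" & el$to == "A")))
  expect_false(any(el$from == el$to))
})

test_that("term-module network flags shared terms central", {
  mk <- function(sets, ps) {
    out <- data.frame(set = sets, size = 5, coef = 1, z = 1, p = ps,
                      direction = "top", penalized = FALSE)
    out$fdr <- bh_adjust(out$p)
    out$significant <- out$fdr < 0.05
    class(out) <- c("ranked_enrich_result", "data.frame")
    out
  }
  per_module <- list(m1 = mk(c("T1", "T2"), c(1e-4, 1e-4)),
                     m2 = mk(c("T1", "T3"), c(1e-4, 0.9)))
  g <- multi_enrichment_network(per_module)
  role <- igraph::V(g)$role
  names(role) <- igraph::V(g)$name
  expect_equal(unname(role["T1"]), "central")
  expect_equal(unname(role["T2"]), "peripheral")
  expect_false("T3" %in% igraph::V(g)$name)
  expect_equal(unname(igraph::degree(g, "T1")), 2)

  expect_warning(empty <- multi_enrichment_network(
    list(m1 = mk("T1", 0.99))), "no significant")
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("network writers are deterministic and order-invariant", {
  uni <- paste0("g", 1:30)
  sets <- gene_set_collection(list(A = paste0("g", 1:10), B = paste0("g", 6:15),
                                   C = paste0("g", 8:20)))
  sel <- paste0("g", 1:12)
  res1 <- fisher_ora(sel, uni, sets, alpha = 1.01, relaxed = 1.02)
  sets_perm <- gene_set_collection(sets$sets[c("C", "A", "B")])
  res2 <- fisher_ora(sel, uni, sets_perm, alpha = 1.01, relaxed = 1.02)
  f1 <- tempfile(); f2 <- tempfile()
  write_network(pathway_network(res1, sets), f1)
  write_network(pathway_network(res2, sets_perm), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a gene set coupled to one module links only to that module", {
  st <- shared_study()
  mods <- stats::setNames(
    lapply(st$cohort$truth$modules, function(m) m$members$id),
    names(st$cohort$truth$modules))
  # rank on the module-specific component (the shared group contrast fills
  # component 1 in the synthetic geometry)
  pls <- suppressWarnings(
    fit_all_modules(st$genes_v, mods, st$serum, sig_genes = st$sig_genes,
                    A = 2, ranking_component = 2L))
  sets <- gene_set_collection(
    list(M1_coupled = st$cohort$truth$modules$M1_cytokines$coupled_genes))
  per_module <- lapply(pls$models, function(m) {
    suppressWarnings(ranked_enrichment(m$ranking, sets))
  })
  g <- multi_enrichment_network(per_module)
  el <- igraph::as_data_frame(g)
  # the set must link to its own module, and most strongly there; weaker
  # secondary links through the shared case-control axis are expected
  # (as in the central/peripheral layering of multi-enrichment graphs)
  expect_true("M1_cytokines" %in% el$to)
  pvals <- vapply(per_module, function(r) r$p[r$set == "M1_coupled"],
                  numeric(1))
  expect_equal(names(which.min(pvals)), "M1_cytokines")
})
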