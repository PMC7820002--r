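#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, member genes. Ids are
#' case-preserving; duplicate members within a set are deduplicated; empty
#' sets are dropped with a warning.
#'
#' @param path GMT file.
#' @return An object of class `gene_set_collection`: named list `sets` of
#'   member id vectors and a parallel named character vector `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    .warnf("empty GMT file: %s", path)
    return(gene_set_collection(list()))
  }
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      .stopf("malformed GMT line %d in %s: expected >= 3 tab-separated fields",
             i, path)
    nm <- f[1]
    if (nm %in% names(sets)) {
      .warnf("duplicate set name '%s' at line %d; keeping the first", nm, i)
      next
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#' @param sets named list of member id vectors.
#' @param description optional named descriptions.
#' @return A `gene_set_collection`; empty sets are dropped with a warning.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(description))
    description <- stats::setNames(rep("", length(sets)), names(sets))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    .warnf("dropping %d empty gene set(s)", sum(empty))
    sets <- sets[!empty]; description <- description[names(sets)]
  }
  structure(list(sets = sets, description = description),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets a `gene_set_collection` or named list of id vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher over-representation analysis
#'
#' One-sided hypergeometric over-representation test of a selected gene list
#' against each set, after harmonizing set members to the universe. Two
#' significance tiers are flagged: `primary` (`p < alpha`) and `relaxed`
#' (`p < relaxed`); BH q-values across sets are also reported.
#'
#' @param selected character vector of selected genes (subset of universe).
#' @param universe character vector of all tested genes.
#' @param sets a `gene_set_collection`.
#' @param alpha primary p-value tier.
#' @param relaxed relaxed p-value tier.
#' @param alternative `"over"` (default, one-sided over-representation) or
#'   `"two.sided"` (Fisher exact).
#' @return data.frame of class `ora_result`: per set the 2x2 counts, odds
#'   ratio, p, BH q and tier; the universe is kept as an attribute.
#' @export
fisher_ora <- function(selected, universe, sets, alpha = 0.05, relaxed = 0.1,
                       alternative = c("over", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  selected <- unique(selected)
  bad <- setdiff(selected, universe)
  if (length(bad))
    .stopf("selected genes outside the universe: %s",
           paste(utils::head(bad, 5), collapse = ", "))
  if (!length(selected))
    .warnf("empty selected list: all enrichment p-values are 1")
  N <- length(universe); n <- length(selected)
  res <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- if (n == 0 || K == 0) 1 else if (alternative == "over") {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      m2 <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
      stats::fisher.test(m2)$p.value
    }
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
    data.frame(set = nm, set_size = K, overlap = k, selected = n,
               universe = N, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out$tier <- ifelse(out$p < alpha, "primary",
                     ifelse(out$p < relaxed, "relaxed", "ns"))
  attr(out, "universe") <- universe
  class(out) <- c("ora_result", "data.frame")
  out
}

# logistic regression with optional ridge penalty via IRLS;
# returns coef, se and convergence/separation flags
.logistic_fit <- function(x, y, lambda = 0) {
  Xm <- cbind(1, x)
  beta <- c(log(max(mean(y), 1e-3) / max(1 - mean(y), 1e-3)), 0)
  pen <- diag(c(0, lambda))
  ok <- TRUE
  for (it in 1:100) {
    eta <- Xm %*% beta
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xm * as.numeric(w))
    H <- XtW %*% Xm + pen
    beta_new <- tryCatch(solve(H, XtW %*% z), error = function(e) NULL)
    if (is.null(beta_new)) { ok <- FALSE; break }
    step <- max(abs(beta_new - beta))
    beta <- as.numeric(beta_new)
    if (step < 1e-8) break
  }
  eta <- Xm %*% beta
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- t(Xm * as.numeric(w)) %*% Xm + pen
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, 2))
  separated <- abs(beta[2]) > 15 || all(mu[y == 1] > 1 - 1e-6) ||
    all(mu[y == 0] < 1e-6)
  list(coef = beta[2], se = se[2], converged = ok, separated = separated)
}

#' Ranked gene-set enrichment of a loading ordering
#'
#' Logistic-regression gene-set test on a ranked gene list: per set, set
#' membership is regressed on the standardized ranking index (gene ranks
#' mapped to centered normal quantiles, with the top of the ranking mapped to
#' large positive values). The Wald z and two-sided p are reported with BH
#' adjustment across sets; the coefficient sign gives the enrichment
#' direction (`"top"` / `"bottom"` of the ranking). On quasi-separation the
#' fit falls back to a weak ridge penalty and is flagged.
#'
#' @param ranking a `gene_ranking` (see [gene_loadings()]); its genes define
#'   the universe.
#' @param sets a `gene_set_collection`.
#' @param alpha FDR level for the `significant` flag.
#' @param min_size sets with fewer members in the universe are skipped with a
#'   warning.
#' @param ridge ridge penalty used by the separation fallback.
#' @return data.frame of class `ranked_enrich_result`: `set`, `size`,
#'   `coef`, `z`, `p`, `fdr`, `direction`, `penalized`, `significant`.
#' @export
ranked_enrichment <- function(ranking, sets, alpha = 0.05, min_size = 3L,
                              ridge = 1) {
  stopifnot(is.data.frame(ranking), all(c("gene", "rank") %in% names(ranking)))
  G <- nrow(ranking)
  idx <- stats::qnorm((G - ranking$rank + 0.5) / G)
  skipped <- character()
  res <- lapply(names(sets$sets), function(nm) {
    y <- as.numeric(ranking$gene %in% sets$sets[[nm]])
    K <- sum(y)
    if (K < min_size || K > G - min_size) {
      skipped <<- c(skipped, nm)
      return(NULL)
    }
    fit <- .logistic_fit(idx, y)
    penal <- FALSE
    if (fit$separated || !fit$converged || !is.finite(fit$se)) {
      fit <- .logistic_fit(idx, y, lambda = ridge)
      penal <- TRUE
    }
    z <- fit$coef / fit$se
    data.frame(set = nm, size = K, coef = fit$coef, z = z,
               p = 2 * stats::pnorm(-abs(z)),
               direction = ifelse(fit$coef > 0, "top", "bottom"),
               penalized = penal, stringsAsFactors = FALSE)
  })
  if (length(skipped))
    .warnf("skipped %d set(s) with < %d members in the universe: %s",
           length(skipped), min_size,
           paste(utils::head(skipped, 5), collapse = ", "))
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    out <- data.frame(set = character(), size = integer(), coef = numeric(),
                      z = numeric(), p = numeric(), direction = character(),
                      penalized = logical(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    class(out) <- c("ranked_enrich_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out$significant <- !is.na(out$fdr) & out$fdr < alpha
  class(out) <- c("ranked_enrich_result", "data.frame")
  out
}

#' Pathway-pathway crosstalk network
#'
#' Nodes are the terms flagged significant by [fisher_ora()] (both tiers,
#' with the tier as a node attribute); an edge joins two terms when the
#' Jaccard index of their member sets (within the test universe) reaches
#' `jaccard_min`, weighted by that index. Node and edge tables are sorted
#' canonically, so the graph is invariant to input ordering.
#'
#' @param results an `ora_result`.
#' @param sets the `gene_set_collection` the results were computed on.
#' @param jaccard_min minimal Jaccard index for an edge.
#' @return An [igraph::igraph] with vertex attribute `tier` and edge
#'   attributes `type = "term-term"` and `weight`.
#' @export
pathway_network <- function(results, sets, jaccard_min = 0.1) {
  stopifnot(inherits(results, "ora_result"))
  universe <- attr(results, "universe")
  keep <- results$tier != "ns"
  terms <- sort(results$set[keep])
  members <- lapply(sets$sets[terms], intersect, y = universe)
  edges <- NULL
  if (length(terms) >= 2) {
    cmb <- utils::combn(terms, 2)
    jac <- apply(cmb, 2, function(pr) {
      a <- members[[pr[1]]]; b <- members[[pr[2]]]
      u <- length(union(a, b))
      if (u == 0) 0 else length(intersect(a, b)) / u
    })
    sel <- jac >= jaccard_min
    if (any(sel))
      edges <- data.frame(from = cmb[1, sel], to = cmb[2, sel],
                          type = "term-term", weight = jac[sel],
                          stringsAsFactors = FALSE)
  }
  vertices <- data.frame(name = terms,
                         tier = results$tier[match(terms, results$set)],
                         stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        type = character(), weight = numeric())
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Term-module multi-enrichment network
#'
#' Bipartite graph over the per-module ranked-enrichment results: term nodes
#' are connected to the modules in which they are significant. Terms of
#' degree >= 2 are flagged `"central"` (shared across modules), degree-1
#' terms `"peripheral"` (module-specific).
#'
#' @param per_module named list of `ranked_enrich_result` objects, one per
#'   module.
#' @param alpha per-module BH-FDR significance level.
#' @return An [igraph::igraph] with vertex attributes `type`
#'   (`"term"`/`"module"`) and `role` (`"central"`/`"peripheral"` for terms),
#'   and edge attribute `type = "term-module"`. Empty when nothing is
#'   significant (with a warning).
#' @export
multi_enrichment_network <- function(per_module, alpha = 0.05) {
  if (!length(per_module)) .stopf("need >= 1 module result")
  edges <- NULL
  for (m in names(per_module)) {
    r <- per_module[[m]]
    sig <- r$set[!is.na(r$fdr) & r$fdr < alpha]
    if (length(sig))
      edges <- rbind(edges, data.frame(from = sort(sig), to = m,
                                       type = "term-module", weight = 1,
                                       stringsAsFactors = FALSE))
  }
  if (is.null(edges)) {
    .warnf("no significant terms in any module; returning an empty graph")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  terms <- sort(unique(edges$from))
  mods <- sort(unique(edges$to))
  deg <- table(edges$from)
  vertices <- data.frame(
    name = c(terms, mods),
    type = c(rep("term", length(terms)), rep("module", length(mods))),
    role = c(ifelse(deg[terms] >= 2, "central", "peripheral"),
             rep(NA_character_, length(mods))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param graph an igraph object.
#' @param edge_path TSV output (columns source, target, type, weight).
#' @param graphml_path optional GraphML output.
#' @export
write_network <- function(graph, edge_path, graphml_path = NULL) {
  el <- igraph::as_data_frame(graph, what = "edges")
  if (!nrow(el)) {
    el <- data.frame(source = character(), target = character(),
                     type = character(), weight = numeric())
  } else {
    el <- data.frame(source = el$from, target = el$to,
                     type = el$type %||% NA_character_,
                     weight = el$weight %||% NA_real_,
                     stringsAsFactors = FALSE)
    el <- el[order(el$source, el$target), ]
  }
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  invisible(edge_path)
}
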