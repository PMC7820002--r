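#' Cohort design
#'
#' @param n_case number of case (MHE) samples, >= 2.
#' @param n_control number of control samples, >= 2.
#' @param seed integer RNG seed; a fixed seed makes every generated cohort
#'   byte-identical.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_case = 6L, n_control = 5L, seed = 101L) {
  if (n_case < 2 || n_control < 2)
    .stopf("each group needs at least 2 samples (got %d case / %d control)",
           n_case, n_control)
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# sample ids and group factor for a design; cases listed first,
# reference (control) level first so logFC = case - control
.design_groups <- function(design) {
  n <- design$n_case + design$n_control
  ids <- sprintf("P%02d", seq_len(n))
  grp <- factor(rep(c("MHE", "noMHE"), c(design$n_case, design$n_control)),
                levels = c("noMHE", "MHE"))
  names(grp) <- ids
  grp
}

# latent factor realizations: one row per module, one column per sample.
# factor = shift * centered group indicator + within-group noise (sample
# sd 1), so the factor's between-group mean difference is exactly
# `group_shift`. The within-group parts are orthogonalized against the group
# contrast and against each other in-sample, so the planted modules are
# mutually identifiable even at small n (real cohorts carry no such
# guarantee; see the methods vignette).
.draw_factors <- function(modules, groups) {
  n <- length(groups)
  z <- as.numeric(groups == levels(groups)[2L])
  zc <- z - mean(z)
  M <- length(modules)
  f <- matrix(0, nrow = M, ncol = n,
              dimnames = list(names(modules), names(groups)))
  basis <- cbind(rep(1 / sqrt(n), n), zc / sqrt(sum(zc^2)))
  for (m in seq_len(M)) {
    u <- stats::rnorm(n)
    if (ncol(basis) < n) {
      u <- u - basis %*% crossprod(basis, u)
      u <- as.numeric(u)
    }
    su <- stats::sd(u)
    if (is.finite(su) && su > 0) u <- u / su
    if (ncol(basis) < n && sum(u^2) > 0) {
      basis <- cbind(basis, u / sqrt(sum(u^2)))
    }
    f[m, ] <- modules[[m]]$group_shift * zc + u
  }
  f
}

#' Generate a synthetic gene expression matrix
#'
#' Per-gene baselines are log2-normal with means drawn uniformly from
#' `baseline_mean_range`; per-gene variances follow a scaled-inverse-chi-square
#' prior with `d0` degrees of freedom and scale `s0sq`, matching the
#' hierarchical model assumed by the moderated t-test so that parameter
#' recovery is a fair test. Case samples are shifted by the planted log2 fold
#' changes; genes listed as coupled to a latent module instead receive their
#' shift through the module's factor (coefficient = logFC / group_shift),
#' which also gives them correlated within-group variation.
#'
#' @param design a [cohort_design()].
#' @param n_genes number of genes.
#' @param planted data.frame with columns `id`, `logFC` (may be `NULL`).
#' @param variance_prior list with elements `d0` (> 0) and `s0sq` (> 0).
#' @param baseline_mean_range range of log2 baseline means.
#' @param modules optional named list of [module_spec()] objects supplying
#'   gene-module coupling.
#' @param factors optional precomputed factor matrix (modules x samples) as
#'   drawn inside [generate_full_cohort()]; when `NULL` and `modules` are
#'   given, factors are drawn here.
#' @param seed RNG seed; defaults to the design seed. Pass `NULL` to use the
#'   current RNG stream (as [generate_full_cohort()] does).
#' @return An `omics_set` of log2-scale intensities with attribute
#'   `"planted"`.
#' @export
generate_gene_matrix <- function(design, n_genes = 5000L, planted = NULL,
                                 variance_prior = list(d0 = 4, s0sq = 0.05),
                                 baseline_mean_range = c(6, 14),
                                 modules = NULL, factors = NULL,
                                 seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  d0 <- variance_prior$d0; s0sq <- variance_prior$s0sq
  if (is.null(d0) || is.null(s0sq) || d0 <= 0 || s0sq <= 0)
    .stopf("variance_prior needs d0 > 0 and s0sq > 0")
  if (!is.null(seed)) set.seed(seed)
  groups <- .design_groups(design)
  n <- length(groups)
  ids <- sprintf("G%05d", seq_len(n_genes))
  if (!is.null(planted)) {
    if (nrow(planted) > n_genes)
      .stopf("more planted effects (%d) than genes (%d)", nrow(planted), n_genes)
    bad <- setdiff(planted$id, ids)
    if (length(bad))
      .stopf("planted gene ids not in catalog: %s", paste(bad, collapse = ", "))
  }
  base_mean <- stats::runif(n_genes, baseline_mean_range[1], baseline_mean_range[2])
  # scaled-inverse-chi-square(d0, s0sq) variances
  sigma2 <- d0 * s0sq / stats::rchisq(n_genes, df = d0)
  z <- as.numeric(groups == levels(groups)[2L])
  zc <- z - mean(z)

  vals <- matrix(stats::rnorm(n_genes * n, sd = sqrt(sigma2)),
                 nrow = n_genes, ncol = n,
                 dimnames = list(ids, names(groups)))
  vals <- vals + base_mean

  coupled_map <- list()
  if (!is.null(modules)) {
    bad <- setdiff(unlist(lapply(modules, `[[`, "coupled_genes")), ids)
    if (length(bad))
      .stopf("coupled gene ids not in catalog: %s", paste(bad, collapse = ", "))
    if (is.null(factors)) factors <- .draw_factors(modules, groups)
    for (m in names(modules)) {
      cg <- modules[[m]]$coupled_genes
      if (!length(cg)) next
      gamma <- modules[[m]]$coupled_logFC / modules[[m]]$group_shift
      vals[cg, ] <- vals[cg, , drop = FALSE] + outer(gamma, factors[m, ])
      coupled_map[[m]] <- cg
    }
  }
  coupled_ids <- unlist(coupled_map, use.names = FALSE)
  if (!is.null(planted) && nrow(planted)) {
    direct <- planted[!(planted$id %in% coupled_ids), , drop = FALSE]
    if (nrow(direct))
      vals[direct$id, ] <- vals[direct$id, , drop = FALSE] +
        outer(direct$logFC, zc)
  }
  out <- omics_set(vals, "gene", groups)
  attr(out, "planted") <- planted
  attr(out, "coupled") <- coupled_map
  out
}

#' Generate synthetic serum metabolite and cytokine panels
#'
#' Features belonging to a latent module are generated as
#' `baseline + sign * magnitude * factor + noise`, where the module factor
#' carries the group shift, so module profiles separate the groups and the
#' planted log2FC of each member is delivered exactly. Features outside any
#' module are independent with class-typical baselines; planted effects on
#' non-members are applied as direct group shifts. Values are returned on the
#' concentration scale (`2^log2value`, uM for metabolites, pg/ml for
#' cytokines).
#'
#' @param design a [cohort_design()].
#' @param catalog feature catalog covering both omics (rows with
#'   `omic == "metabolite"` and `"cytokine"`), see
#'   [default_metabolite_catalog()].
#' @param modules named list of [module_spec()] objects; members must be
#'   catalog features and may not overlap between modules.
#' @param planted data.frame (`id`, `logFC`) of direct effects for features
#'   outside any module (effects on module members are carried by the factor).
#' @param member_noise_ratio member-specific distortion of the shared
#'   factor: each member sees `factor + e` with `e ~ N(0, ratio^2)`, so its
#'   residual log2 noise is `ratio * |loading|` and within-module correlation
#'   is uniform across members.
#' @param class_cor within-class correlation loading of non-module features:
#'   features of one chemical class share a latent class factor (with no
#'   group shift) with loading `class_cor`, mirroring the strong
#'   within-class co-variation of targeted serum panels. Set 0 for
#'   independent features.
#' @param factors optional precomputed factor matrix (modules x samples).
#' @param seed RNG seed; defaults to the design seed, `NULL` uses the current
#'   stream.
#' @return list with elements `metabolites` and `cytokines` (both
#'   `omics_set`) and `factors`.
#' @export
generate_serum_panel <- function(design, catalog, modules = list(),
                                 planted = NULL, member_noise_ratio = 0.22,
                                 class_cor = 0, factors = NULL,
                                 seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  .check_modules_disjoint(modules)
  mem <- .module_membership(modules)
  if (!is.null(mem)) {
    bad <- setdiff(mem$id, catalog$id)
    if (length(bad))
      .stopf("module members not in catalog: %s", paste(bad, collapse = ", "))
  }
  if (!is.null(planted)) {
    bad <- setdiff(planted$id, catalog$id)
    if (length(bad))
      .stopf("planted ids not in catalog: %s", paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  groups <- .design_groups(design)
  n <- length(groups)
  z <- as.numeric(groups == levels(groups)[2L])
  zc <- z - mean(z)
  if (is.null(factors) && length(modules)) factors <- .draw_factors(modules, groups)

  # non-module features co-vary within their chemical class through a
  # latent class factor (no group shift)
  classes <- sort(unique(catalog$class))
  gclass <- matrix(stats::rnorm(length(classes) * n), nrow = length(classes),
                   dimnames = list(classes, names(groups)))
  eps <- matrix(stats::rnorm(nrow(catalog) * n), nrow = nrow(catalog))
  shared <- gclass[catalog$class, , drop = FALSE]
  vals <- (class_cor * shared + sqrt(1 - class_cor^2) * eps) * catalog$base_sd
  dimnames(vals) <- list(catalog$id, names(groups))
  vals <- vals + catalog$base_mean
  if (!is.null(mem)) {
    for (i in seq_len(nrow(mem))) {
      f <- mem$id[i]
      lam <- mem$sign[i] * mem$magnitude[i]
      # loading-proportional factor distortion plus a small absolute
      # analytic noise floor (keeps zero-loading members non-degenerate)
      vals[f, ] <- catalog$base_mean[match(f, catalog$id)] +
        lam * (factors[mem$module[i], ] +
                 stats::rnorm(n, sd = member_noise_ratio)) +
        stats::rnorm(n, sd = 0.01)
    }
  }
  if (!is.null(planted) && nrow(planted)) {
    direct <- planted[is.null(mem) | !(planted$id %in% mem$id), , drop = FALSE]
    if (nrow(direct))
      vals[direct$id, ] <- vals[direct$id, , drop = FALSE] +
        outer(direct$logFC, zc)
  }
  conc <- 2^vals
  out <- list()
  for (om in c("metabolite", "cytokine")) {
    sel <- catalog$omic == om
    if (!any(sel)) next
    out[[paste0(om, "s")]] <- omics_set(conc[sel, , drop = FALSE], om, groups,
                                        catalog[sel, , drop = FALSE])
  }
  out$factors <- factors
  out
}

#' Censor values below a limit of detection
#'
#' Replaces values strictly below the (per-feature) limit of detection with
#' `NA`, emulating non-detectable peaks. The censoring pattern is a
#' deterministic function of the matrix and the thresholds.
#'
#' @param x an `omics_set`.
#' @param lod scalar or per-feature named numeric vector of detection limits
#'   (same concentration scale as the values); finite and non-negative.
#' @return The `omics_set` with censored entries set to `NA` and the used
#'   thresholds stored in `attr(, "lod")`.
#' @export
censor_below_lod <- function(x, lod) {
  stopifnot(inherits(x, "omics_set"))
  ids <- rownames(x$values)
  if (length(lod) == 1L && is.null(names(lod))) {
    lodv <- stats::setNames(rep(as.numeric(lod), length(ids)), ids)
  } else {
    if (is.null(names(lod))) .stopf("per-feature `lod` must be named")
    lodv <- stats::setNames(rep(0, length(ids)), ids)
    lodv[intersect(names(lod), ids)] <- lod[intersect(names(lod), ids)]
  }
  if (any(!is.finite(lodv)) || any(lodv < 0))
    .stopf("`lod` must be finite and non-negative")
  x$values[x$values < lodv[rownames(x$values)]] <- NA_real_
  attr(x, "lod") <- lodv
  x
}

#' Default synthetic cohort configuration
#'
#' Bundles the study-scale defaults: an 11-sample design (6 case / 5
#' control), a 143-metabolite catalog, a 14-cytokine panel, 847 planted gene
#' effects, the 29 planted metabolite and 6 planted cytokine effects, six
#' latent modules with a group shift of 3.5 within-group SD units, and 40
#' module-coupled genes per module. The desk-scale gene count is 5000; pass
#' `full_scale = TRUE` for the 60000-feature array scale.
#'
#' @param seed integer seed driving all cohort randomness (which gene ids are
#'   planted, effect magnitudes, noise).
#' @param n_genes number of genes (overridden by `full_scale`).
#' @param full_scale use 60000 genes.
#' @param n_gene_effects number of planted gene effects.
#' @param gene_effect_range range of |log2FC| for planted genes.
#' @param coupled_per_module planted genes coupled to each module's factor.
#' @param group_shift latent factor group shift magnitude.
#' @param member_noise_ratio member-level factor distortion, in factor-SD
#'   units (residual noise scales with the member loading).
#' @param class_cor within-class correlation loading of non-module serum
#'   features (see [generate_serum_panel()]).
#' @param variance_prior gene variance prior, list(d0, s0sq).
#' @param n_background_sets number of random background gene sets written to
#'   the synthetic annotation, in addition to one set per module made of its
#'   coupled genes.
#' @return A named list (class `cohort_config`).
#' @export
default_cohort_config <- function(seed = 101L, n_genes = 5000L,
                                  full_scale = FALSE,
                                  n_gene_effects = 847L,
                                  gene_effect_range = c(0.7, 2),
                                  coupled_per_module = 40L,
                                  group_shift = 3.5,
                                  member_noise_ratio = 0.22,
                                  class_cor = 0,
                                  variance_prior = list(d0 = 4, s0sq = 0.05),
                                  n_background_sets = 30L) {
  if (full_scale) n_genes <- 60000L
  cfg <- list(
    design = cohort_design(6L, 5L, seed),
    n_genes = as.integer(n_genes),
    n_gene_effects = as.integer(n_gene_effects),
    gene_effect_range = gene_effect_range,
    coupled_per_module = as.integer(coupled_per_module),
    group_shift = group_shift,
    member_noise_ratio = member_noise_ratio,
    class_cor = class_cor,
    variance_prior = variance_prior,
    n_background_sets = as.integer(n_background_sets),
    catalog = rbind(default_metabolite_catalog(), default_cytokine_catalog()),
    metabolite_effects = default_metabolite_effects(),
    cytokine_effects = default_cytokine_effects(),
    modules = default_module_specs(group_shift))
  class(cfg) <- "cohort_config"
  cfg
}

#' Null cohort configuration
#'
#' Same structure as [default_cohort_config()] but with no planted effects
#' and no latent modules, for type-I-error / calibration studies.
#'
#' @inheritParams default_cohort_config
#' @export
null_cohort_config <- function(seed = 101L, n_genes = 2000L) {
  cfg <- default_cohort_config(seed = seed, n_genes = n_genes,
                               n_gene_effects = 0L, coupled_per_module = 0L)
  cfg$metabolite_effects <- cfg$metabolite_effects[0, , drop = FALSE]
  cfg$cytokine_effects <- cfg$cytokine_effects[0, , drop = FALSE]
  cfg$modules <- list()
  cfg
}

#' Generate a full synthetic multi-omic cohort
#'
#' Draws the planted gene effects, assigns module-coupled genes, realizes the
#' latent module factors once (shared between the serum panel and the coupled
#' genes), and generates all three omic matrices plus ground truth and a
#' synthetic gene-set annotation (one set per module consisting of its
#' coupled genes, plus random background sets).
#'
#' @param config a `cohort_config`, see [default_cohort_config()].
#' @return An object of class `synthetic_cohort`: list with elements
#'   `genes`, `metabolites`, `cytokines` (`omics_set`s), `groups`,
#'   `gene_sets` (named list of gene id vectors), and `truth` (planted
#'   effects, module specs, coupled genes, factor matrix).
#' @export
generate_full_cohort <- function(config = default_cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  design <- config$design
  set.seed(design$seed)
  groups <- .design_groups(design)

  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  n_eff <- config$n_gene_effects
  if (n_eff > config$n_genes)
    .stopf("config$n_gene_effects (%d) exceeds config$n_genes (%d)",
           n_eff, config$n_genes)
  planted_genes <- if (n_eff > 0) {
    data.frame(id = sort(sample(gene_ids, n_eff)),
               logFC = sample(c(-1, 1), n_eff, replace = TRUE) *
                 stats::runif(n_eff, config$gene_effect_range[1],
                              config$gene_effect_range[2]),
               stringsAsFactors = FALSE)
  } else data.frame(id = character(), logFC = numeric())

  modules <- config$modules
  if (length(modules) && config$coupled_per_module > 0) {
    need <- config$coupled_per_module * length(modules)
    if (need > nrow(planted_genes))
      .stopf("not enough planted genes (%d) for %d coupled genes",
             nrow(planted_genes), need)
    pool <- sample(planted_genes$id, need)
    for (m in seq_along(modules)) {
      idx <- ((m - 1) * config$coupled_per_module + 1):(m * config$coupled_per_module)
      cg <- pool[idx]
      # genes co-regulated with a module change in the module's direction:
      # align the planted sign with the factor's group shift so the coupling
      # coefficients (logFC / shift) are positive and the coupled set is
      # direction-coherent in the loading ranking
      rows <- match(cg, planted_genes$id)
      planted_genes$logFC[rows] <- sign(modules[[m]]$group_shift) *
        abs(planted_genes$logFC[rows])
      modules[[m]]$coupled_genes <- cg
      modules[[m]]$coupled_logFC <- planted_genes$logFC[rows]
    }
  }

  factors <- if (length(modules)) .draw_factors(modules, groups) else NULL

  genes <- generate_gene_matrix(design, config$n_genes, planted_genes,
                                config$variance_prior, modules = modules,
                                factors = factors, seed = NULL)
  serum_planted <- rbind(config$metabolite_effects[, c("id", "logFC")],
                         config$cytokine_effects[, c("id", "logFC")])
  serum <- generate_serum_panel(design, config$catalog, modules,
                                serum_planted, config$member_noise_ratio,
                                class_cor = config$class_cor %||% 0,
                                factors = factors, seed = NULL)

  gene_sets <- list()
  for (m in seq_along(modules)) {
    if (length(modules[[m]]$coupled_genes))
      gene_sets[[paste0(modules[[m]]$name, "_coupled")]] <-
        sort(modules[[m]]$coupled_genes)
  }
  if (config$n_background_sets > 0) {
    sizes <- sample(15:60, config$n_background_sets, replace = TRUE)
    for (b in seq_len(config$n_background_sets)) {
      gene_sets[[sprintf("BG_SET_%02d", b)]] <- sort(sample(gene_ids, sizes[b]))
    }
  }

  truth <- list(
    planted_genes = planted_genes,
    planted_metabolites = config$metabolite_effects[, c("id", "logFC")],
    planted_cytokines = config$cytokine_effects[, c("id", "logFC")],
    modules = modules,
    coupled_genes = lapply(modules, `[[`, "coupled_genes"),
    factors = factors)

  structure(list(genes = genes, metabolites = serum$metabolites,
                 cytokines = serum$cytokines, groups = groups,
                 gene_sets = gene_sets, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf(paste0("synthetic_cohort: %d samples (%s); %d genes, ",
                     "%d metabolites, %d cytokines; %d latent modules\n"),
              length(x$groups),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(x$genes$values), nrow(x$metabolites$values),
              nrow(x$cytokines$values), length(x$truth$modules)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `genes.tsv`, `metabolites.tsv`, `cytokines.tsv`, `samples.tsv`,
#' `gene_sets.gmt` and `truth.json`. Output is byte-identical for a fixed
#' config seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_tsv(cohort$genes, file.path(dir, "genes.tsv"))
  write_omics_tsv(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  write_omics_tsv(cohort$cytokines, file.path(dir, "cytokines.tsv"))
  write_samples_tsv(cohort$groups, file.path(dir, "samples.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- cohort$truth
  truth$modules <- lapply(truth$modules, unclass)
  truth$factors <- if (!is.null(truth$factors)) {
    list(modules = rownames(truth$factors), samples = colnames(truth$factors),
         values = unname(apply(truth$factors, 1, identity, simplify = FALSE)))
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
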