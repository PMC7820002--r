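#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Inputs are either a
#' synthetic-cohort block (`synthetic`) or paths to the four TSV inputs plus
#' an optional GMT annotation.
#'
#' @param synthetic a `cohort_config` (see [default_cohort_config()]), or
#'   `NULL` for file inputs.
#' @param genes,metabolites,cytokines,samples input TSV paths (ignored for
#'   synthetic runs).
#' @param gene_sets optional GMT path (synthetic runs default to the
#'   generated annotation).
#' @param alpha FDR level for all per-omic tests.
#' @param lod limit of detection passed to the metabolite QC filter.
#' @param k_range candidate module counts.
#' @param cluster_methods clustering methods compared by silhouette.
#' @param pls_components,pls_scale PLS settings, see [fit_pls()].
#' @param ranking_component component used for the per-module gene rankings
#'   fed to the ranked enrichment (see [fit_all_modules()]).
#' @param enrich_alpha,enrich_relaxed,jaccard_min enrichment thresholds.
#' @param seed integer seed for the run.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = default_cohort_config(),
                            genes = NULL, metabolites = NULL,
                            cytokines = NULL, samples = NULL,
                            gene_sets = NULL,
                            alpha = 0.05, lod = 0,
                            k_range = 2:10,
                            cluster_methods = c("pam", "kmeans", "hierarchical"),
                            pls_components = 2, pls_scale = "autoscale",
                            ranking_component = 1L,
                            enrich_alpha = 0.05, enrich_relaxed = 0.1,
                            jaccard_min = 0.1,
                            seed = 101L) {
  structure(list(synthetic = synthetic, genes = genes,
                 metabolites = metabolites, cytokines = cytokines,
                 samples = samples, gene_sets = gene_sets,
                 alpha = alpha, lod = lod, k_range = k_range,
                 cluster_methods = cluster_methods,
                 pls_components = pls_components, pls_scale = pls_scale,
                 ranking_component = as.integer(ranking_component),
                 enrich_alpha = enrich_alpha, enrich_relaxed = enrich_relaxed,
                 jaccard_min = jaccard_min, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a JSON or YAML configuration file
#'
#' Settings files for pipeline runs may be written in JSON or YAML; the
#' format is chosen by file extension.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return A named list of settings.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Validate a pipeline configuration
#'
#' Collects *all* problems (missing files, inconsistent sample ids,
#' undersized groups, out-of-range thresholds) before failing, rather than
#' stopping at the first.
#'
#' @param config a `pipeline_config`.
#' @return The validated config (with loaded inputs attached as attribute
#'   `"inputs"` for file-based runs), or an error listing every problem.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  errs <- character()
  for (a in c("alpha", "enrich_alpha", "enrich_relaxed")) {
    v <- config[[a]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      errs <- c(errs, sprintf("%s must lie in (0, 1), got %s", a, v))
  }
  inputs <- NULL
  if (!is.null(config$synthetic)) {
    if (!inherits(config$synthetic, "cohort_config"))
      errs <- c(errs, "`synthetic` must be a cohort_config")
  } else {
    paths <- c(genes = config$genes, metabolites = config$metabolites,
               cytokines = config$cytokines, samples = config$samples)
    missing_paths <- names(paths)[!file.exists(paths)]
    if (length(paths) < 4)
      errs <- c(errs, "file-based runs need genes, metabolites, cytokines and samples paths")
    if (length(missing_paths))
      errs <- c(errs, sprintf("input file not found: %s",
                              paste(missing_paths, collapse = ", ")))
    if (!length(errs)) {
      samples <- read_samples_tsv(config$samples)
      inputs <- list(samples = samples)
      for (om in c("genes", "metabolites", "cytokines")) {
        omic <- sub("s$", "", om)
        set <- tryCatch(read_omics_tsv(config[[om]], omic, samples),
                        error = function(e) conditionMessage(e))
        if (is.character(set)) {
          errs <- c(errs, sprintf("%s: %s", om, set))
        } else {
          inputs[[om]] <- set
          mism <- setdiff(colnames(set$values), inputs[[1]]$id %||% samples$id)
          if (length(mism))
            errs <- c(errs, sprintf("%s: samples not in samples.tsv: %s",
                                    om, paste(mism, collapse = ", ")))
        }
      }
      ids <- lapply(inputs[c("genes", "metabolites", "cytokines")],
                    function(s) if (!is.null(s)) colnames(s$values))
      ids <- ids[!vapply(ids, is.null, logical(1))]
      if (length(ids) > 1) {
        common <- Reduce(intersect, ids)
        extra <- setdiff(unique(unlist(ids)), common)
        if (length(extra))
          errs <- c(errs, sprintf("sample ids differ across matrices: %s",
                                  paste(extra, collapse = ", ")))
      }
      if (!is.null(inputs$genes)) {
        tab <- table(inputs$genes$groups)
        if (any(tab < 2))
          errs <- c(errs, sprintf(
            "group '%s' has %d sample(s); the two-group tests need >= 2 per group",
            names(tab)[which.min(tab)], min(tab)))
      }
    }
    if (!is.null(config$gene_sets) && !file.exists(config$gene_sets))
      errs <- c(errs, sprintf("gene_sets file not found: %s", config$gene_sets))
  }
  if (length(errs))
    .stopf("invalid pipeline configuration:\n- %s", paste(errs, collapse = "\n- "))
  attr(config, "inputs") <- inputs
  config
}

# md5 of the canonical JSON rendering of the config (for the run report)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  stripped <- rapply(unclass(config), function(x) x, how = "replace")
  jsonlite::write_json(stripped, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full four-step integration pipeline
#'
#' Step 1: metabolite QC, variance stabilization and per-omic differential
#' testing (moderated t for genes and metabolites, exact Wilcoxon for
#' cytokines). Step 2: correlation-module discovery over the union of
#' FDR-significant serum features. Step 3: one PLS2 model per module with
#' significant genes as predictors, scored by R2 and leave-one-out Q2.
#' Step 4: Fisher over-representation of the differential gene list, ranked
#' enrichment of per-module PLS loadings, and the pathway-pathway and
#' term-module networks. All artifacts are written under `outdir`; a fixed
#' seed makes outputs byte-identical across runs.
#'
#' When too few serum features are significant to cluster (< 3), the run
#' terminates gracefully after Step 1 with status `"no_modules"`.
#'
#' @param config a `pipeline_config` (validated here if not already).
#' @param outdir output directory.
#' @return A `run_report`: per-step counts, chosen clustering, per-module
#'   R2/Q2, enrichment summaries, warnings, software version and config
#'   hash. Also written as `report.json`.
#' @export
run_pipeline <- function(config, outdir = tempfile("momint_run_")) {
  config <- validate_inputs(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  t0 <- Sys.time()
  warnings_log <- character()
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  report <- list(package = "momint",
                 version = as.character(utils::packageVersion("momint")),
                 seed = config$seed, config_hash = .config_hash(config),
                 steps = list())

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    cohort <- generate_full_cohort(config$synthetic)
    write_cohort(cohort, file.path(outdir, "cohort"))
    genes_raw <- cohort$genes
    metab_raw <- cohort$metabolites
    cyto_raw <- cohort$cytokines
    sets <- gene_set_collection(cohort$gene_sets)
  } else {
    inputs <- attr(config, "inputs")
    genes_raw <- inputs$genes; metab_raw <- inputs$metabolites
    cyto_raw <- inputs$cytokines
    sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets) else NULL
  }
  report$samples <- list(n = ncol(genes_raw$values),
                         groups = as.list(table(genes_raw$groups)))

  # ---- step 1: QC, normalization, differential testing --------------------
  qc <- withCallingHandlers(
    metabolite_qc_filter(metab_raw, lod = config$lod), warning = log_warn)
  utils::write.table(qc$report, file.path(outdir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  metab_f <- qc$matrix
  if (nrow(metab_f$values) == 0)
    .stopf("QC removed every metabolite; nothing to analyze downstream")

  # gene intensities are generated / delivered on the log2 scale; the glog
  # calibration is applied on the linear scale for all omics
  genes_v <- withCallingHandlers(
    vst_normalize(omics_set(2^genes_raw$values, "gene", genes_raw$groups,
                            genes_raw$features)),
    warning = log_warn)
  metab_v <- withCallingHandlers(vst_normalize(metab_f), warning = log_warn)
  # the cytokine panel is too small (14 features) for a reliable glog
  # calibration fit; strictly positive pg/ml values get the asymptotic
  # log2 transform instead
  cyto_v <- omics_set(.stabilize_small_panel(cyto_raw$values), "cytokine",
                      cyto_raw$groups, cyto_raw$features)

  de_genes <- moderated_ttest(genes_v, alpha = config$alpha)
  de_metab <- moderated_ttest(metab_v, alpha = config$alpha)
  de_cyto <- withCallingHandlers(wilcoxon_panel(cyto_raw, alpha = config$alpha),
                                 warning = log_warn)
  write_diffexp_tsv(de_genes, file.path(outdir, "diffexp_genes.tsv"))
  write_diffexp_tsv(de_metab, file.path(outdir, "diffexp_metabolites.tsv"))
  utils::write.table(de_cyto, file.path(outdir, "cytokine_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig_genes <- significant_features(de_genes, config$alpha)
  sig_metab <- significant_features(de_metab, config$alpha)
  sig_cyto <- significant_features(de_cyto, config$alpha)
  report$steps$step1 <- list(
    n_genes = nrow(de_genes), n_metabolites_prefilter = nrow(qc$report),
    n_metabolites = nrow(de_metab), n_cytokines = nrow(de_cyto),
    significant = list(genes = length(sig_genes),
                       metabolites = length(sig_metab),
                       cytokines = length(sig_cyto)))

  # ---- step 2: module discovery ------------------------------------------
  serum_v <- rbind(metab_v$values, cyto_v$values)
  sig_serum <- c(sig_metab, sig_cyto)
  if (length(sig_serum) < 3) {
    report$status <- "no_modules"
    report$message <- sprintf(
      "only %d significant serum feature(s); module discovery needs >= 3",
      length(sig_serum))
    report$warnings <- warnings_log
    report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    class(report) <- "run_report"
    .write_report(report, outdir)
    return(report)
  }
  corr <- withCallingHandlers(spearman_abs_corr(serum_v[sig_serum, , drop = FALSE]),
                              warning = log_warn)
  dist <- corr_distance(corr)
  sel <- withCallingHandlers(
    select_modules(dist, k_range = config$k_range,
                   methods = config$cluster_methods, seed = config$seed),
    warning = log_warn)
  serum_set <- omics_set(serum_v[sig_serum, , drop = FALSE], "metabolite",
                         metab_v$groups)
  profiles <- module_profiles(serum_set, sel$result)
  write_modules_tsv(sel$result, profiles, outdir)
  jsonlite::write_json(
    list(method = sel$method, k = sel$k, mean_sil = sel$result$mean_sil,
         candidates = sel$candidates),
    file.path(outdir, "clustering_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  report$steps$step2 <- list(n_serum_features = length(sig_serum),
                             method = sel$method, k = sel$k,
                             mean_silhouette = sel$result$mean_sil)

  # ---- step 3: per-module PLS --------------------------------------------
  pls <- withCallingHandlers(
    fit_all_modules(genes_v, sel$result, serum_v, sig_genes = sig_genes,
                    A = config$pls_components, scale = config$pls_scale,
                    ranking_component = config$ranking_component %||% 1L),
    warning = log_warn)
  write_pls_tsv(pls, outdir)
  report$steps$step3 <- list(n_models = nrow(pls$summary),
                             summary = pls$summary)

  # ---- step 4: enrichment and networks -----------------------------------
  if (!is.null(sets) && length(sets$sets)) {
    ora <- withCallingHandlers(
      fisher_ora(sig_genes, rownames(genes_v$values), sets,
                 alpha = config$enrich_alpha, relaxed = config$enrich_relaxed),
      warning = log_warn)
    utils::write.table(ora, file.path(outdir, "ora.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pnet <- pathway_network(ora, sets, jaccard_min = config$jaccard_min)
    write_network(pnet, file.path(outdir, "pathway_network.tsv"),
                  file.path(outdir, "pathway_network.graphml"))
    ranked <- list()
    for (m in names(pls$models)) {
      r <- withCallingHandlers(
        ranked_enrichment(pls$models[[m]]$ranking, sets,
                          alpha = config$enrich_alpha),
        warning = log_warn)
      ranked[[m]] <- r
      safe <- gsub("[^A-Za-z0-9_.-]", "_", m)
      utils::write.table(r, file.path(outdir, sprintf("ranked_enrichment_%s.tsv", safe)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    mnet <- withCallingHandlers(
      multi_enrichment_network(ranked, alpha = config$enrich_alpha),
      warning = log_warn)
    write_network(mnet, file.path(outdir, "multi_enrichment_network.tsv"),
                  file.path(outdir, "multi_enrichment_network.graphml"))
    report$steps$step4 <- list(
      n_sets = length(sets$sets),
      ora_primary = sum(ora$tier == "primary"),
      ora_relaxed = sum(ora$tier == "relaxed"),
      ranked_significant = vapply(ranked, function(r) sum(r$significant),
                                  integer(1)))
  } else {
    report$steps$step4 <- list(skipped = "no gene-set annotation provided")
  }

  report$status <- "complete"
  report$warnings <- warnings_log
  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"
  .write_report(report, outdir)
  .reconcile_report(report, outdir)
  report
}

.write_report <- function(report, outdir) {
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       force = TRUE)
}

# counts in the report must equal the rows of the corresponding output files
.reconcile_report <- function(report, outdir) {
  checks <- list(
    c("diffexp_genes.tsv", report$steps$step1$n_genes),
    c("diffexp_metabolites.tsv", report$steps$step1$n_metabolites),
    c("cytokine_tests.tsv", report$steps$step1$n_cytokines),
    c("modules.tsv", report$steps$step2$n_serum_features),
    c("pls_summary.tsv", report$steps$step3$n_models))
  for (ch in checks) {
    f <- file.path(outdir, ch[[1]])
    if (is.null(ch[[2]]) || !file.exists(f)) next
    nr <- nrow(utils::read.delim(f))
    if (nr != as.integer(ch[[2]]))
      .warnf("report count for %s (%s) does not match file rows (%d)",
             ch[[1]], ch[[2]], nr)
  }
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("momint run report (v%s, seed %d): %s\n",
              x$version, x$seed, x$status))
  if (!is.null(x$steps$step1))
    cat(sprintf("  step1: significant genes %d, metabolites %d, cytokines %d\n",
                x$steps$step1$significant$genes,
                x$steps$step1$significant$metabolites,
                x$steps$step1$significant$cytokines))
  if (!is.null(x$steps$step2))
    cat(sprintf("  step2: %s clustering, k = %d (mean silhouette %.3f)\n",
                x$steps$step2$method, x$steps$step2$k,
                x$steps$step2$mean_silhouette))
  if (!is.null(x$steps$step3)) {
    cat("  step3: per-module PLS\n")
    print(x$steps$step3$summary, row.names = FALSE)
  }
  if (!is.null(x$steps$step4$n_sets))
    cat(sprintf("  step4: %d sets; ORA primary %d, relaxed %d\n",
                x$steps$step4$n_sets, x$steps$step4$ora_primary,
                x$steps$step4$ora_relaxed))
  if (length(x$warnings))
    cat(sprintf("  warnings: %d (see report.json)\n", length(x$warnings)))
  invisible(x)
}
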