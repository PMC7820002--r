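# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default desk-scale cohort plus its step-1 results
shared_study <- function() memo("study", function() {
  cohort <- generate_full_cohort(default_cohort_config(seed = 101))
  genes_v <- suppressWarnings(
    vst_normalize(omics_set(2^cohort$genes$values, "gene",
                            cohort$genes$groups)))
  metab_v <- suppressWarnings(vst_normalize(cohort$metabolites))
  cyto_v <- log2(cohort$cytokines$values)
  de_genes <- moderated_ttest(genes_v)
  de_metab <- moderated_ttest(metab_v)
  de_cyto <- suppressWarnings(wilcoxon_panel(cohort$cytokines))
  list(cohort = cohort, genes_v = genes_v, metab_v = metab_v,
       cyto_v = cyto_v, de_genes = de_genes, de_metab = de_metab,
       de_cyto = de_cyto,
       sig_genes = significant_features(de_genes),
       sig_metab = significant_features(de_metab),
       sig_cyto = significant_features(de_cyto),
       serum = rbind(metab_v$values, cyto_v))
})

# PLS fits on the ground-truth modules of the shared cohort
shared_pls <- function() memo("pls", function() {
  st <- shared_study()
  mods <- stats::setNames(
    lapply(st$cohort$truth$modules, function(m) m$members$id),
    names(st$cohort$truth$modules))
  suppressWarnings(fit_all_modules(st$genes_v, mods, st$serum,
                                   sig_genes = st$sig_genes, A = 2))
})

# 10-seed recovery suite (clustering only; PLS handled separately)
shared_recovery_suite <- function() memo("recovery", function() {
  lapply(101:110, function(s) {
    evaluate_synthetic_recovery(default_cohort_config(seed = s),
                                fit_pls_models = FALSE)
  })
})

truth_membership <- function(cohort) {
  do.call(rbind, lapply(cohort$truth$modules, function(m) {
    data.frame(id = m$members$id, module = m$name, stringsAsFactors = FALSE)
  }))
}

# small two-group omics_set from a plain matrix
toy_set <- function(values, omic = "metabolite",
                    n_case = ceiling(ncol(values) / 2)) {
  n <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(n))
  grp <- factor(rep(c("case", "ctrl"), c(n_case, n - n_case)),
                levels = c("ctrl", "case"))
  omics_set(values, omic, grp)
}
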