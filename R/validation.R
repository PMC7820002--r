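#' Run the integration analysis on a synthetic cohort and score recovery
#'
#' Convenience driver for parameter-recovery studies: generates the cohort,
#' runs QC / variance stabilization / differential testing, clusters the
#' union of FDR-significant serum features with silhouette-selected PAM, and
#' (optionally) fits the per-module PLS models. Recovery is scored against
#' the cohort's ground truth: the selected number of modules `k`, the
#' adjusted Rand index between the recovered partition and the planted
#' module memberships (computed over the clustered features that carry a
#' ground-truth membership; requires the `mclust` package), and the
#' per-module cumulative R2 / leave-one-out Q2.
#'
#' @param config a `cohort_config` (see [default_cohort_config()]).
#' @param methods clustering methods passed to [select_modules()] (default
#'   PAM only, the method the silhouette comparison selects).
#' @param k_range candidate module counts.
#' @param fit_pls_models also fit the per-module PLS models (on the planted
#'   ground-truth module memberships) and report R2/Q2.
#' @param A PLS components.
#' @return list with elements `k`, `ari`, `n_significant` (serum),
#'   `mean_silhouette`, `clustering`, `sig_genes`, and when
#'   `fit_pls_models = TRUE` also `pls_summary`, `recovered_pls_summary`
#'   (models on the recovered clusters) and `models` (the ground-truth
#'   module fits).
#' @export
evaluate_synthetic_recovery <- function(config = default_cohort_config(),
                                        methods = "pam", k_range = 2:10,
                                        fit_pls_models = TRUE, A = 2) {
  cohort <- generate_full_cohort(config)
  genes_v <- suppressWarnings(
    vst_normalize(omics_set(2^cohort$genes$values, "gene",
                            cohort$genes$groups)))
  metab_v <- suppressWarnings(vst_normalize(cohort$metabolites))
  cyto_v <- .stabilize_small_panel(cohort$cytokines$values)

  sig_genes <- significant_features(moderated_ttest(genes_v))
  sig_metab <- significant_features(moderated_ttest(metab_v))
  sig_cyto <- significant_features(
    suppressWarnings(wilcoxon_panel(cohort$cytokines)))
  sig_serum <- c(sig_metab, sig_cyto)
  serum <- rbind(metab_v$values, cyto_v)

  out <- list(n_significant = length(sig_serum), sig_genes = sig_genes,
              cohort = cohort)
  if (length(sig_serum) >= 3) {
    dist <- corr_distance(spearman_abs_corr(serum[sig_serum, , drop = FALSE]))
    sel <- suppressWarnings(select_modules(dist, k_range = k_range,
                                           methods = methods,
                                           seed = config$design$seed))
    out$k <- sel$k
    out$mean_silhouette <- sel$result$mean_sil
    out$clustering <- sel$result
    truth <- .module_membership(cohort$truth$modules)
    if (!is.null(truth)) {
      common <- intersect(sig_serum, truth$id)
      if (length(common) >= 2 && requireNamespace("mclust", quietly = TRUE)) {
        out$ari <- mclust::adjustedRandIndex(
          sel$result$labels[common], truth$module[match(common, truth$id)])
      }
    }
  }
  if (fit_pls_models && length(cohort$truth$modules) && length(sig_genes)) {
    mods <- stats::setNames(
      lapply(cohort$truth$modules, function(m) m$members$id),
      names(cohort$truth$modules))
    fits <- suppressWarnings(
      fit_all_modules(genes_v, mods, serum, sig_genes = sig_genes, A = A))
    out$pls_summary <- fits$summary
    out$pls_summary$coupled <- vapply(
      cohort$truth$modules[fits$summary$module],
      function(m) length(m$coupled_genes) > 0, logical(1))
    out$models <- fits
    if (!is.null(out$clustering)) {
      rec <- suppressWarnings(
        fit_all_modules(genes_v, out$clustering, serum,
                        sig_genes = sig_genes, A = A))
      out$recovered_pls_summary <- rec$summary
    }
  }
  out
}
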