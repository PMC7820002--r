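#' Latent-module specification
#'
#' Describes one latent correlation module of serum compounds: its members
#' with signed loadings, the group shift of the shared latent factor, and the
#' gene ids coupled to the same factor.
#'
#' @param name module name.
#' @param members data.frame with columns `id`, `sign` (+1/-1) and
#'   `magnitude` (non-negative loading).
#' @param group_shift shift of the latent factor mean in the case group,
#'   in within-group standard-deviation units of the factor (may be negative).
#' @param coupled_genes character vector of gene ids driven by the same
#'   latent factor.
#' @param coupled_logFC numeric vector (same length as `coupled_genes`) of
#'   gene log2 fold changes delivered through the factor.
#' @return An object of class `module_spec`.
#' @export
module_spec <- function(name, members, group_shift, coupled_genes = character(),
                        coupled_logFC = numeric()) {
  stopifnot(is.data.frame(members),
            all(c("id", "sign", "magnitude") %in% names(members)))
  if (!all(members$sign %in% c(-1, 1)))
    .stopf("module '%s': member signs must be +1 or -1", name)
  if (any(members$magnitude < 0))
    .stopf("module '%s': loading magnitudes must be non-negative", name)
  if (length(coupled_genes) != length(coupled_logFC))
    .stopf("module '%s': coupled_genes and coupled_logFC lengths differ", name)
  structure(list(name = name, members = members, group_shift = group_shift,
                 coupled_genes = coupled_genes, coupled_logFC = coupled_logFC),
            class = "module_spec")
}

#' Build a module spec from planted effects
#'
#' Signed member loadings are chosen so that the latent factor delivers each
#' member's planted log2FC exactly: loading = logFC / group_shift.
#'
#' @param name module name.
#' @param effects data.frame with columns `id`, `logFC` for the members.
#' @param group_shift latent factor group shift (signed).
#' @return A `module_spec`.
#' @export
module_spec_from_effects <- function(name, effects, group_shift) {
  lam <- effects$logFC / group_shift
  module_spec(name,
              data.frame(id = effects$id, sign = ifelse(lam < 0, -1, 1),
                         magnitude = abs(lam), stringsAsFactors = FALSE),
              group_shift)
}

#' Default latent-module layout
#'
#' Six modules over the default planted serum effects, mirroring the observed
#' co-abundance structure: one cytokine module, three glycerophospholipid
#' modules split by side-chain mass and saturation (<= 40 carbons with <= 5 /
#' > 5 double bonds; > 40 carbons with >= 5 double bonds), a sphingomyelin /
#' small-compound module carrying the remaining increased metabolites, and a
#' decreased amino-compound module (Val, alpha-AAA, spermine). Lipid
#' assignment follows the carbon / double-bond rules and is approximate for
#' compounds those rules do not cover.
#'
#' @param group_shift magnitude of the latent factor group shift (default
#'   3.5 within-group SD units); the sign per module follows the direction of
#'   its members' planted effects.
#' @param metabolite_effects,cytokine_effects planted effect tables, defaults
#'   [default_metabolite_effects()] and [default_cytokine_effects()].
#' @return Named list of 6 `module_spec` objects.
#' @export
default_module_specs <- function(group_shift = 3.5,
                                 metabolite_effects = default_metabolite_effects(),
                                 cytokine_effects = default_cytokine_effects()) {
  me <- metabolite_effects
  lip <- parse_lipid_notation(me$id)
  is_glyc <- grepl("^(PC|lysoPC)", me$id)
  short_low <- is_glyc & lip$carbons <= 40 & lip$double_bonds <= 5
  short_high <- is_glyc & lip$carbons <= 40 & lip$double_bonds > 5
  long_soft <- is_glyc & lip$carbons > 40 & lip$double_bonds >= 5
  amine_down <- me$id %in% c("Val", "alpha-AAA", "Spermine")
  rest <- !(short_low | short_high | long_soft | amine_down)

  specs <- list(
    module_spec_from_effects("M1_cytokines", cytokine_effects[, c("id", "logFC")],
                             +group_shift),
    module_spec_from_effects("M2_pc_short_lowunsat", me[short_low, ],
                             -group_shift),
    module_spec_from_effects("M3_pc_short_polyunsat", me[short_high, ],
                             -group_shift),
    module_spec_from_effects("M4_pc_long_unsat", me[long_soft, ],
                             +group_shift),
    module_spec_from_effects("M5_sm_axis", me[rest, ], +group_shift),
    module_spec_from_effects("M6_amines_down", me[amine_down, ],
                             -group_shift))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# flat membership table for a list of module specs
.module_membership <- function(modules) {
  do.call(rbind, lapply(modules, function(m) {
    data.frame(module = m$name, id = m$members$id, sign = m$members$sign,
               magnitude = m$members$magnitude, stringsAsFactors = FALSE)
  }))
}

.check_modules_disjoint <- function(modules) {
  mem <- .module_membership(modules)
  if (is.null(mem)) return(invisible(NULL))
  dup <- unique(mem$id[duplicated(mem$id)])
  if (length(dup))
    .stopf("features assigned to more than one module: %s",
           paste(dup, collapse = ", "))
  invisible(NULL)
}
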