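#' Parse lipid side-chain notation
#'
#' Extracts the "C x:y" side-chain descriptor used for acylcarnitines,
#' sphingomyelins and glycerophospholipids, where `x` is the total number of
#' carbon atoms and `y` the number of double bonds in the fatty-acid residues.
#'
#' @param ids character vector of feature ids (e.g. `"PC aa C36:4"`,
#'   `"SM (OH) C14:1"`, `"C18:2"`).
#' @return data.frame with columns `id`, `carbons`, `double_bonds` (`NA` for
#'   ids without the notation) and `bond_type` (`"aa"`, `"ae"`, `"a"`, `"e"`
#'   or `NA`).
#' @export
parse_lipid_notation <- function(ids) {
  m <- regmatches(ids, regexpr("C[0-9]+:[0-9]+", ids))
  has <- grepl("C[0-9]+:[0-9]+", ids)
  carbons <- double_bonds <- rep(NA_integer_, length(ids))
  parts <- strsplit(sub("^C", "", m), ":", fixed = TRUE)
  carbons[has] <- as.integer(vapply(parts, `[`, "", 1L))
  double_bonds[has] <- as.integer(vapply(parts, `[`, "", 2L))
  bond <- rep(NA_character_, length(ids))
  bond[grepl(" aa ", ids)] <- "aa"
  bond[grepl(" ae ", ids)] <- "ae"
  bond[is.na(bond) & grepl(" a ", ids)] <- "a"
  bond[is.na(bond) & grepl(" e ", ids)] <- "e"
  data.frame(id = ids, carbons = carbons, double_bonds = double_bonds,
             bond_type = bond, stringsAsFactors = FALSE)
}

.aa21 <- c("Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His",
           "Ile", "Leu", "Lys", "Met", "Orn", "Phe", "Pro", "Ser", "Thr",
           "Trp", "Tyr", "Val")

.amines17 <- c("ADMA", "alpha-AAA", "Carnosine", "Creatinine", "DOPA",
               "Histamine", "Kynurenine", "Met-SO", "Nitro-Tyr", "PEA",
               "Putrescine", "Sarcosine", "Serotonin", "Spermidine",
               "Spermine", "t4-OH-Pro", "Taurine")

.acylcarn8 <- c("C0", "C2", "C3", "C10", "C16", "C18", "C18:1", "C18:2")

.sm15 <- c("SM C16:0", "SM C16:1", "SM C18:0", "SM C18:1", "SM C20:2",
           "SM C22:3", "SM C24:0", "SM C24:1", "SM C26:0", "SM C26:1",
           "SM (OH) C14:1", "SM (OH) C16:1", "SM (OH) C22:1",
           "SM (OH) C22:2", "SM (OH) C24:1")

.glycero81 <- c(
  # phosphatidylcholines, diacyl
  paste("PC aa", c("C24:0", "C26:0", "C28:1", "C30:0", "C30:2", "C32:0",
                   "C32:1", "C32:2", "C32:3", "C34:1", "C34:2", "C34:3",
                   "C34:4", "C36:0", "C36:1", "C36:2", "C36:3", "C36:4",
                   "C36:5", "C36:6", "C38:0", "C38:1", "C38:3", "C38:4",
                   "C38:5", "C38:6", "C40:1", "C40:2", "C40:3", "C40:4",
                   "C40:5", "C40:6", "C42:0", "C42:1", "C42:2", "C42:4",
                   "C42:5", "C42:6")),
  # phosphatidylcholines, acyl-alkyl
  paste("PC ae", c("C30:0", "C30:1", "C30:2", "C32:1", "C32:2", "C34:0",
                   "C34:1", "C34:2", "C34:3", "C36:0", "C36:1", "C36:2",
                   "C36:3", "C36:4", "C36:5", "C38:0", "C38:1", "C38:2",
                   "C38:3", "C38:4", "C40:1", "C40:2", "C42:1", "C42:2",
                   "C42:3", "C42:5", "C44:3", "C44:5", "C44:6")),
  # lysophosphatidylcholines
  paste("lysoPC a", c("C14:0", "C16:0", "C16:1", "C17:0", "C18:0", "C18:1",
                      "C18:2", "C20:3", "C20:4", "C24:0", "C26:0", "C26:1",
                      "C28:0", "C28:1")))

# log2 baseline concentration ranges (uM) per class, desk realism for a
# targeted serum panel: amino acids tens-hundreds uM, amines/acylcarnitines
# sub-uM to tens, one summed hexose ~5 mM, lipids spread over decades.
.metab_class_log2_range <- list(
  `acylcarnitine`      = log2(c(0.03, 40)),
  `amino acid`         = log2(c(20, 600)),
  `biogenic amine`     = log2(c(0.05, 10)),
  `hexose`             = log2(c(4000, 5500)),
  `sphingomyelin`      = log2(c(5, 250)),
  `glycerophospholipid` = log2(c(0.5, 500)))

#' Default serum metabolite catalog
#'
#' A 143-metabolite targeted panel modelled on a standard quantitative
#' serum kit: 8 acylcarnitines, 21 amino acids, 17 biogenic amines, 1 summed
#' hexose, 15 sphingomyelins and 81 glycerophospholipids (lysoPC and PC).
#' Baseline log2 means are drawn once from class-typical concentration
#' ranges under a fixed internal seed, so the catalog is identical across
#' sessions and independent of the caller's RNG stream.
#'
#' @param baseline_seed integer seed for the baseline draws (fixed default).
#' @return data.frame with columns `id`, `omic`, `class`, `carbons`,
#'   `double_bonds`, `base_mean` (log2 concentration), `base_sd` (log2 scale).
#' @export
default_metabolite_catalog <- function(baseline_seed = 20L) {
  ids <- c(.acylcarn8, .aa21, .amines17, "H1", .sm15, .glycero81)
  cls <- rep(c("acylcarnitine", "amino acid", "biogenic amine", "hexose",
               "sphingomyelin", "glycerophospholipid"),
             times = c(8L, 21L, 17L, 1L, 15L, 81L))
  lip <- parse_lipid_notation(ids)
  with_preserved_seed(baseline_seed, {
    base_mean <- vapply(cls, function(cl) {
      rng <- .metab_class_log2_range[[cl]]
      stats::runif(1, rng[1], rng[2])
    }, numeric(1))
    base_sd <- stats::runif(length(ids), 0.15, 0.35)
  })
  data.frame(id = ids, omic = "metabolite", class = cls,
             carbons = lip$carbons, double_bonds = lip$double_bonds,
             base_mean = unname(base_mean), base_sd = base_sd,
             stringsAsFactors = FALSE)
}

#' Default cytokine panel catalog
#'
#' A 14-cytokine serum panel (pg/ml). Baseline medians for the six
#' MHE-responsive cytokines follow the control-group values of the study
#' design; the remaining baselines are typical serum levels.
#'
#' @return data.frame with columns `id`, `omic`, `class`, `base_mean`
#'   (log2 pg/ml), `base_sd`.
#' @export
default_cytokine_catalog <- function() {
  base <- c(`IL-4` = 0.35, `IL-6` = 1.15, `IL-10` = 1.9, `IL-12` = 1.6,
            `IL-13` = 1.3, `IL-15` = 4.66, `IL-17` = 1.4, `IL-18` = 160,
            `IL-22` = 56.04, `TGFb` = 1800, `TNFa` = 6.1,
            `CXCL13` = 109.37, `CCL20` = 58.37, `CX3CL1` = 603.38)
  data.frame(id = names(base), omic = "cytokine", class = "cytokine",
             carbons = NA_integer_, double_bonds = NA_integer_,
             base_mean = log2(unname(base)), base_sd = 0.4,
             stringsAsFactors = FALSE)
}

#' Default planted serum metabolite effects
#'
#' The 29 metabolites with significant case-control differences and their
#' log2 fold changes (case minus control) used as default planted effects.
#'
#' @return data.frame with columns `id`, `logFC`.
#' @export
default_metabolite_effects <- function() {
  eff <- c(
    "PC aa C36:4"   = -0.7436, "PC aa C38:4"   = -0.7106,
    "PC aa C38:5"   = -0.6788, "PC aa C40:5"   = -0.6272,
    "PC aa C34:4"   = -0.8185, "lysoPC a C20:4" = -0.5669,
    "PC aa C40:6"   = -0.7801, "PC aa C38:6"   = -0.8598,
    "PC ae C38:0"   = -0.5767, "Met"           = 0.6004,
    "PC aa C36:5"   = -0.8773, "SM (OH) C14:1" = 0.5611,
    "PC ae C44:6"   = 0.6000,  "Spermine"      = -0.3971,
    "PC aa C38:3"   = -0.5105, "alpha-AAA"     = -0.4547,
    "PC aa C40:4"   = -0.4155, "PC aa C36:6"   = -0.6148,
    "lysoPC a C20:3" = -0.6249, "PC aa C34:3"  = -0.5725,
    "Val"           = -0.4825, "SM C22:3"      = 1.1125,
    "PC aa C32:3"   = -0.3489, "PC aa C42:1"   = 0.3616,
    "SM C16:0"      = 0.3501,  "PC ae C30:0"   = 0.4426,
    "PC ae C42:5"   = 0.5168,  "PC ae C44:5"   = 0.5536,
    "C18:2"         = 0.4845)
  data.frame(id = names(eff), logFC = unname(eff), stringsAsFactors = FALSE)
}

#' Default planted cytokine effects
#'
#' Log2 fold changes for the six responsive cytokines, derived from the
#' case / control median serum concentrations (pg/ml) of the study design.
#'
#' @return data.frame with columns `id`, `logFC`, `median_control`,
#'   `median_case`.
#' @export
default_cytokine_effects <- function() {
  med <- data.frame(
    id = c("IL-6", "IL-15", "IL-22", "CXCL13", "CCL20", "CX3CL1"),
    median_control = c(1.15, 4.66, 56.04, 109.37, 58.37, 603.38),
    median_case = c(3.70, 9.71, 81.05, 194.48, 90.20, 833.42),
    stringsAsFactors = FALSE)
  med$logFC <- log2(med$median_case / med$median_control)
  med[, c("id", "logFC", "median_control", "median_case")]
}
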