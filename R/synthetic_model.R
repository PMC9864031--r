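# Synthetic two-cell cerebellum model generator.
#
# A deliberately small but topologically faithful stand-in for the full
# medulloblastoma reconstruction: two cell compartments (neuron N, astrocyte
# A) plus an extracellular cerebellum pool (C), shared uptake bounds split
# 97/3 between the cells, and the pathway repertoire of the analysis
# (glycolysis, PPP, TCA, OXPHOS, glutamate/GABA cycle, taurine, glycogen,
# fatty acid, mevalonate/cholesterol, sphingolipid/ganglioside,
# cardiolipin). Stoichiometry is lumped (one reaction per pathway segment)
# and the biomass composition uses uniform placeholder precursor demands.
#
# The healthy and MB variants share all ids and differ only in bounds:
#   - MB forces avid glucose and glutamine uptake (exchange lb = ub),
#   - MB caps OXPHOS capacity (mitochondrial impairment),
#   - the healthy variant instead carries a small ATP maintenance demand.
# Together with the NADH balance this pins the designed MB phenotype:
# lactate excretion at least twice the glucose uptake, glucose-dependent
# growth, glutamine-independent growth.

#' Specification for the synthetic two-cell model
#'
#' @param gaba,taurine,glycogen Toggles for the three optional side
#'   branches (each controlled by a single gene, so they can be planted as
#'   Absent-only prunable branches for GIMME).
#' @param tca Toggle for the TCA lumped reaction.
#' @param neuron_fraction Tissue fraction of neurons (default 0.97; the
#'   astrocyte fraction is the complement).
#' @param uptakes Named uptake magnitudes (mmol/gDW/h); defaults are the
#'   scenario-context bounds of [scenario_config()].
#' @param oxphos_cap Total OXPHOS capacity (NADH flux) of the MB variant.
#' @param atp_maintenance Healthy-variant ATP maintenance demand (total).
#' @param branch_cap Capacity of each optional side branch (total).
#' @param ppp_cap Capacity of the pentose phosphate shunt (total).
#' @return An object of class `toy_model_spec`.
#' @export
toy_model_spec <- function(gaba = TRUE, taurine = TRUE, glycogen = TRUE,
                           tca = TRUE, glycolysis = TRUE, oxphos = TRUE,
                           ppp = TRUE, fatty_acid = TRUE,
                           cholesterol = TRUE, sphingolipid = TRUE,
                           cardiolipin = TRUE, neuron_fraction = 0.97,
                           uptakes = NULL, oxphos_cap = 1.0,
                           atp_maintenance = 0.1, branch_cap = 0.002,
                           ppp_cap = 0.01) {
  required <- c(glycolysis = glycolysis, oxphos = oxphos, ppp = ppp,
                fatty_acid = fatty_acid, cholesterol = cholesterol,
                sphingolipid = sphingolipid, cardiolipin = cardiolipin)
  if (any(!required)) {
    stop("inconsistent toggles: pathway(s) ",
         paste(names(required)[!required], collapse = ", "),
         " supply biomass precursors (or dispose of their by-products)",
         " and cannot be disabled")
  }
  cfg <- scenario_config(uptake_bounds = uptakes,
                         neuron_fraction = neuron_fraction)
  structure(list(gaba = gaba, taurine = taurine, glycogen = glycogen,
                 tca = tca, neuron_fraction = neuron_fraction,
                 uptakes = cfg$uptake_bounds, oxphos_cap = oxphos_cap,
                 atp_maintenance = atp_maintenance, branch_cap = branch_cap,
                 ppp_cap = ppp_cap),
            class = "toy_model_spec")
}

# SMILES for the metabolites entering the antimetabolite screen.
TOY_SMILES <- c(
  glc = "OCC1OC(O)C(O)C(O)C1O",
  gln = "C(CC(=O)N)C(C(=O)O)N",
  glu = "C(CC(=O)O)C(C(=O)O)N",
  mev = "CC(CCO)(CC(=O)O)O",
  sph = "CCCCCCCCCCCCCCCC(C(CO)N)O",
  lac = "CC(O)C(=O)O"
)

#' Generate the paired healthy / MB synthetic models
#'
#' Builds the two-cell cerebellum toy model in its healthy and
#' medulloblastoma variants plus a ground-truth report of every planted
#' property: biomass-essential genes, isoenzyme synthetic-lethal pairs,
#' Absent-only prunable side branches, the pan-essential but
#' healthy-dispensable genes, the antimetabolite hits, and the designed
#' phenotype targets. The report is sufficient to predict the outputs of
#' the GIMME, deletion and antimetabolite analyses on the fixture without
#' running them.
#'
#' @param spec A [toy_model_spec()].
#' @return List with `healthy`, `mb` (both `metabolic_model`) and
#'   `ground_truth`.
#' @export
generate_toy_models <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  up <- spec$uptakes
  wN <- spec$neuron_fraction
  wA <- 1 - wN
  if (wN <= 0 || wN >= 1) stop("neuron_fraction must lie strictly in (0,1)")
  BIG <- 1000

  mets <- list(); rxns <- list(); stoich <- list()
  add_met <- function(base, tag, name, smiles = NA_character_) {
    id <- paste0(base, tag)
    mets[[id]] <<- data.frame(id = id, name = paste(name, tag),
                              formula = NA_character_, smiles = smiles,
                              stringsAsFactors = FALSE)
    id
  }
  add_rxn <- function(id, name, sto, lb, ub, gpr = "", pathway,
                      exch = FALSE, atp = 0L, paper_id = NA_character_) {
    rxns[[id]] <<- data.frame(id = id, name = name, lower_bound = lb,
                              upper_bound = ub, gpr = gpr, pathway = pathway,
                              is_exchange = exch, atp_yield = atp,
                              paper_id = paper_id, stringsAsFactors = FALSE)
    stoich[[id]] <<- sto
  }

  cells <- c(N = wN, A = wA)
  for (tag in names(cells)) {
    w <- cells[[tag]]
    m <- function(base) paste0(base, tag)
    for (base in c("glc", "gln", "o2", "leu", "trp", "tyr", "met", "pyr",
                   "nadh", "atp", "lac", "r5p", "accoa", "glu", "palm",
                   "mev", "chol", "sph", "cer", "gang", "clpn")) {
      add_met(base, tag, base, smiles = unname(TOY_SMILES[base]))
    }
    if (spec$gaba) add_met("gaba", tag, "gaba")
    if (spec$taurine) add_met("tau", tag, "taurine")
    if (spec$glycogen) add_met("glyg", tag, "glycogen")

    ex <- function(base, nutrient, gpr = "") {
      add_rxn(paste0("EX_", base, "_", tag),
              paste0(nutrient, " uptake (", tag, ")"),
              stats::setNames(1, m(base)), 0, up[[nutrient]] * w,
              gpr = gpr, pathway = "exchange", exch = TRUE)
    }
    ex("glc", "glucose", gpr = "SLC2A1")
    ex("gln", "glutamine", gpr = "SLC1A5")
    ex("o2", "oxygen")
    ex("leu", "leucine", gpr = "LAT1")
    ex("trp", "tryptophan", gpr = "LAT1")
    ex("tyr", "tyrosine", gpr = "LAT1")
    ex("met", "methionine")

    add_rxn(paste0("GLYC_", tag), "glycolysis (lumped)",
            stats::setNames(c(-1, 2, 2, 2),
                            c(m("glc"), m("pyr"), m("nadh"), m("atp"))),
            0, BIG, gpr = "(HK1 or HK2) and GAPDH", pathway = "glycolysis",
            atp = 2L)
    add_rxn(paste0("LDH_", tag), "lactate dehydrogenase",
            stats::setNames(c(-1, -1, 1),
                            c(m("pyr"), m("nadh"), m("lac"))),
            0, BIG, gpr = "LDHA or LDHB", pathway = "glycolysis")
    add_rxn(paste0("LACT_", tag), "lactate export to cerebellum",
            stats::setNames(c(-1, 1), c(m("lac"), "lacC")),
            0, BIG, pathway = "transport")
    add_rxn(paste0("PPP_", tag), "pentose phosphate shunt (lumped)",
            stats::setNames(c(-1, 1), c(m("glc"), m("r5p"))),
            0, spec$ppp_cap * w, gpr = "G6PD", pathway = "PPP")
    add_rxn(paste0("PDH_", tag), "pyruvate dehydrogenase",
            stats::setNames(c(-1, 1, 1),
                            c(m("pyr"), m("accoa"), m("nadh"))),
            0, BIG, gpr = "PDHA1", pathway = "TCA")
    if (spec$tca) {
      add_rxn(paste0("TCA_", tag), "TCA cycle (lumped)",
              stats::setNames(c(-1, 3, 1),
                              c(m("accoa"), m("nadh"), m("atp"))),
              0, BIG, gpr = "CS", pathway = "TCA", atp = 1L)
    }
    add_rxn(paste0("OXPHOS_", tag), "oxidative phosphorylation (lumped)",
            stats::setNames(c(-1, -0.05, 2),
                            c(m("nadh"), m("o2"), m("atp"))),
            0, BIG, gpr = "NDUFS1 and ATP5F1", pathway = "OXPHOS",
            atp = 2L)
    add_rxn(paste0("ATPM_", tag), "ATP maintenance",
            stats::setNames(-1, m("atp")), 0, BIG,
            pathway = "maintenance", atp = -1L)
    add_rxn(paste0("GLS_", tag), "glutaminase",
            stats::setNames(c(-1, 1), c(m("gln"), m("glu"))),
            0, BIG, gpr = "GLS", pathway = "glutamate_gaba",
            paper_id = if (tag == "N") "R96" else NA_character_)
    add_rxn(paste0("GDH_", tag), "glutaminolysis (lumped)",
            stats::setNames(c(-1, 1, 1, 1),
                            c(m("glu"), m("pyr"), m("nadh"), m("atp"))),
            0, BIG, gpr = "GLUD1", pathway = "glutamate_gaba", atp = 1L)
    if (spec$gaba) {
      add_rxn(paste0("GAD_", tag), "glutamate decarboxylase",
              stats::setNames(c(-1, 1), c(m("glu"), m("gaba"))),
              0, spec$branch_cap * w, gpr = "GAD1",
              pathway = "glutamate_gaba")
      add_rxn(paste0("GABAX_", tag), "GABA release",
              stats::setNames(c(-1, 1), c(m("gaba"), "gabaC")),
              0, BIG, pathway = "transport")
    }
    if (spec$taurine) {
      add_rxn(paste0("TAUS_", tag), "taurine synthesis (lumped)",
              stats::setNames(c(-1, 1), c(m("glu"), m("tau"))),
              0, spec$branch_cap * w, gpr = "CDO1", pathway = "taurine")
      add_rxn(paste0("TAUX_", tag), "taurine release",
              stats::setNames(c(-1, 1), c(m("tau"), "tauC")),
              0, BIG, pathway = "transport")
    }
    if (spec$glycogen) {
      add_rxn(paste0("GYS_", tag), "glycogen synthase",
              stats::setNames(c(-1, 1), c(m("glc"), m("glyg"))),
              0, spec$branch_cap * w, gpr = "GYS1", pathway = "glycogen")
      add_rxn(paste0("GLYGX_", tag), "glycogen storage",
              stats::setNames(c(-1, 1), c(m("glyg"), "glygC")),
              0, BIG, pathway = "transport")
    }
    add_rxn(paste0("FAS_", tag), "fatty acid synthesis (lumped)",
            stats::setNames(c(-4, 1), c(m("accoa"), m("palm"))),
            0, BIG, gpr = "FASN", pathway = "fatty_acid")
    add_rxn(paste0("HMGCR_", tag), "mevalonate synthesis (lumped)",
            stats::setNames(c(-1, 1), c(m("accoa"), m("mev"))),
            0, BIG, gpr = "HMGCR", pathway = "cholesterol")
    add_rxn(paste0("CHOL_", tag), "cholesterol synthesis (lumped)",
            stats::setNames(c(-1, 1), c(m("mev"), m("chol"))),
            0, BIG, gpr = "MVK and SQLE", pathway = "cholesterol")
    add_rxn(paste0("SPHS_", tag), "sphinganine synthesis (lumped)",
            stats::setNames(c(-1, 1), c(m("palm"), m("sph"))),
            0, BIG, gpr = "SPTLC1", pathway = "sphingolipid")
    add_rxn(paste0("CERS_", tag), "ceramide synthase",
            stats::setNames(c(-1, 1), c(m("sph"), m("cer"))),
            0, BIG, gpr = "CERS1", pathway = "sphingolipid")
    add_rxn(paste0("GANG_", tag), "ganglioside synthesis (GM3)",
            stats::setNames(c(-1, 1), c(m("cer"), m("gang"))),
            0, BIG, gpr = "ST3GAL5", pathway = "sphingolipid")
    add_rxn(paste0("CLS_", tag), "cardiolipin synthase (lumped)",
            stats::setNames(c(-1, -1, 1),
                            c(m("palm"), m("accoa"), m("clpn"))),
            0, BIG, gpr = "CRLS1", pathway = "cardiolipin")
  }

  add_met("lac", "C", "lactate", smiles = unname(TOY_SMILES[["lac"]]))
  add_rxn("EX_lac_C", "lactate excretion",
          stats::setNames(-1, "lacC"), 0, BIG, pathway = "exchange",
          exch = TRUE)
  if (spec$gaba) {
    add_met("gaba", "C", "gaba")
    add_rxn("EX_gaba_C", "GABA excretion", stats::setNames(-1, "gabaC"),
            0, BIG, pathway = "exchange", exch = TRUE)
  }
  if (spec$taurine) {
    add_met("tau", "C", "taurine")
    add_rxn("EX_tau_C", "taurine excretion", stats::setNames(-1, "tauC"),
            0, BIG, pathway = "exchange", exch = TRUE)
  }
  if (spec$glycogen) {
    add_met("glyg", "C", "glycogen")
    add_rxn("EX_glyg_C", "glycogen sink", stats::setNames(-1, "glygC"),
            0, BIG, pathway = "exchange", exch = TRUE)
  }

  precursors <- c("r5p", "palm", "chol", "gang", "clpn", "leu", "trp",
                  "tyr", "met")
  bm <- c(stats::setNames(rep(-wN, length(precursors)),
                          paste0(precursors, "N")),
          stats::setNames(rep(-wA, length(precursors)),
                          paste0(precursors, "A")))
  add_rxn("BIOMASS", "cerebellum biomass", bm, 0, BIG,
          pathway = "biomass", paper_id = "R25")

  met_df <- do.call(rbind, mets)
  rxn_df <- do.call(rbind, rxns)
  healthy <- metabolic_model(met_df, rxn_df, stoich,
                             biomass_id = "BIOMASS")

  # healthy variant: ATP maintenance demand forces oxidative activity
  for (tag in names(cells)) {
    i <- match(paste0("ATPM_", tag), healthy$reactions$id)
    healthy$reactions$lower_bound[i] <- spec$atp_maintenance * cells[[tag]]
  }
  validate_model(healthy)

  # MB variant: avid (forced) glucose/glutamine uptake, capped OXPHOS
  mb <- metabolic_model(met_df, rxn_df, stoich, biomass_id = "BIOMASS")
  for (tag in names(cells)) {
    w <- cells[[tag]]
    i <- match(paste0("EX_glc_", tag), mb$reactions$id)
    mb$reactions$lower_bound[i] <- up[["glucose"]] * w
    i <- match(paste0("EX_gln_", tag), mb$reactions$id)
    mb$reactions$lower_bound[i] <- up[["glutamine"]] * w
    i <- match(paste0("OXPHOS_", tag), mb$reactions$id)
    mb$reactions$upper_bound[i] <- spec$oxphos_cap * w
  }
  validate_model(mb)

  branch <- c(if (spec$gaba) "GAD1", if (spec$taurine) "CDO1",
              if (spec$glycogen) "GYS1")
  branch_rxn <- c(if (spec$gaba) c("GAD_N", "GAD_A"),
                  if (spec$taurine) c("TAUS_N", "TAUS_A"),
                  if (spec$glycogen) c("GYS_N", "GYS_A"))
  ground_truth <- list(
    essential_genes_biomass = sort(c(
      "SLC2A1", "LAT1", "GAPDH", "G6PD", "PDHA1", "NDUFS1", "ATP5F1",
      "GLS", "GLUD1", "FASN", "HMGCR", "MVK", "SQLE", "SPTLC1", "CERS1",
      "ST3GAL5", "CRLS1")),
    synthetic_lethal_pairs = list(c("HK1", "HK2"), c("LDHA", "LDHB")),
    pan_essential_healthy_safe = c("GLS", "GLUD1"),
    gimme_absent_genes = branch,
    gimme_removed_reactions = sort(branch_rxn),
    antimetabolite_hit_metabolites = c("glnN", "glnA"),
    planted_up_genes = c("HK2", "LDHA", "FASN", "GLS", "GLUD1"),
    designed = list(
      lactate_glucose_ratio_min = 2,
      biomass_requires_glucose = TRUE,
      glutamine_dispensable_for_biomass = TRUE,
      bound_delta_reactions = sort(c(
        paste0("EX_glc_", names(cells)), paste0("EX_gln_", names(cells)),
        paste0("OXPHOS_", names(cells)), paste0("ATPM_", names(cells))))
    ))
  list(healthy = healthy, mb = mb, ground_truth = ground_truth)
}
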