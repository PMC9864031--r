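# Antimetabolite screening: molecular-fingerprint Tanimoto similarity plus
# competitive-inhibition simulation on the paired disease/healthy models.

#' Molecular fingerprint from SMILES
#'
#' Hashed circular-substructure (extended-connectivity, radius 2)
#' fingerprint folded to `n_bits` bits, computed through Open Babel. The
#' path-based `"fp2"` and the structural-key `"maccs"` families are
#' available as alternates; similarity values depend on the family, so
#' compared fingerprints must share parameters.
#'
#' @param smiles SMILES string (non-empty).
#' @param n_bits Folded width (default 2048).
#' @param family `"ecfp4"`, `"fp2"` or `"maccs"`.
#' @return An object of class `fingerprint`: logical bit vector with
#'   `family`/`n_bits` attributes.
#' @export
fingerprint <- function(smiles, n_bits = 2048L,
                        family = c("ecfp4", "fp2", "maccs")) {
  family <- match.arg(family)
  if (is.null(smiles) || is.na(smiles) || !nzchar(trimws(smiles))) {
    stop("empty structure: cannot fingerprint")
  }
  ob_name <- c(ecfp4 = "ECFP4", fp2 = "FP2", maccs = "MACCS")[[family]]
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  raw <- ChemmineOB::fingerprint_OB(mol, ob_name)
  if (!any(raw > 0)) stop("fingerprint of '", smiles, "' is empty; ",
                          "check the SMILES")
  idx <- which(raw > 0) %% n_bits
  idx[idx == 0L] <- n_bits
  bits <- logical(n_bits)
  bits[unique(idx)] <- TRUE
  structure(bits, family = family, n_bits = n_bits, class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a intersect b| / |a union b|` over the set bits. Fingerprints must
#' share family and width; empty fingerprints are rejected upstream, so the
#' 0/0 case cannot silently score.
#'
#' @param a,b `fingerprint` objects.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!identical(attr(a, "family"), attr(b, "family")) ||
      !identical(attr(a, "n_bits"), attr(b, "n_bits"))) {
    stop("fingerprint parameter mismatch (family/width)")
  }
  u <- sum(a | b)
  if (u == 0L) stop("both fingerprints are empty")
  sum(a & b) / u
}

# Metabolites commonly excluded as substrates: ubiquitous cofactors and
# small inorganics whose "inhibition" would hit every energy reaction.
DEFAULT_COFACTOR_STOPLIST <- c("atp", "adp", "amp", "nad", "nadh", "nadp",
                               "nadph", "h2o", "h", "o2", "co2", "pi",
                               "ppi", "coa", "nh4")

#' Competitive-inhibition antimetabolite screen
#'
#' For every model metabolite with a SMILES annotation (cofactors on the
#' stop-list excluded), finds the reactions consuming it (negative
#' stoichiometry with the baseline flux direction respected), lowers the
#' bound nearest each baseline flux to `factor` times that flux (toward
#' zero, in both the disease and the healthy model, reactions with zero
#' baseline flux left untouched), re-solves both models and scores the
#' growth reductions. A compound is a hit for a metabolite when the
#' fingerprint Tanimoto similarity exceeds `tanimoto_cutoff`, the disease
#' growth reduction exceeds `growth_cutoff` and the healthy reduction stays
#' within `safety_cutoff`.
#'
#' @param mb_model,healthy_model Paired `metabolic_model` objects.
#' @param compounds `data.frame` with `id`, `name`, `smiles` (see
#'   [read_compound_table()]).
#' @param config Optional [scenario_config()] for both models.
#' @param factor Inhibition factor on the baseline flux (default 0.1).
#' @param tanimoto_cutoff Similarity gate (default 0.90, strict `>`).
#' @param growth_cutoff Disease growth-reduction gate (default 0.40,
#'   strict `>`).
#' @param safety_cutoff Allowed healthy growth reduction (default 0.40).
#' @param stoplist Cofactor base names excluded as substrates.
#' @param fingerprint_args Arguments passed to [fingerprint()].
#' @return `data.frame` with one row per (metabolite, compound) pair scoring
#'   above the similarity gate plus one summary row per screened metabolite
#'   without a similar compound: `metabolite`, `analog`, `tanimoto`,
#'   `targeted_reactions`, `mb_growth_reduction`, `healthy_reduction`,
#'   `healthy_safe`, `hit`.
#' @export
competitive_inhibition_screen <- function(mb_model, healthy_model, compounds,
                                          config = NULL, factor = 0.1,
                                          tanimoto_cutoff = 0.90,
                                          growth_cutoff = 0.40,
                                          safety_cutoff = 0.40,
                                          stoplist =
                                            DEFAULT_COFACTOR_STOPLIST,
                                          fingerprint_args = list()) {
  stopifnot(factor >= 0, factor <= 1)
  mb_base <- fba(mb_model, config = config)
  h_base <- fba(healthy_model, config = config)
  if (mb_base$status != "optimal" || h_base$status != "optimal") {
    stop("baseline optimization failed")
  }
  mb_wt <- unname(mb_base$fluxes[mb_model$biomass_id])
  h_wt <- unname(h_base$fluxes[healthy_model$biomass_id])

  mets <- mb_model$metabolites
  screened <- mets[!is.na(mets$smiles) &
                     !(metabolite_base(mets$id) %in% stoplist), ,
                   drop = FALSE]
  if (!nrow(screened)) return(empty_hit_table())

  cmpd_fp <- lapply(compounds$smiles, function(s)
    do.call(fingerprint, c(list(s), fingerprint_args)))

  rows <- list()
  for (k in seq_len(nrow(screened))) {
    met <- screened$id[k]
    mfp <- do.call(fingerprint, c(list(screened$smiles[k]),
                                  fingerprint_args))
    sims <- vapply(cmpd_fp, tanimoto, numeric(1), a = mfp)

    targets_mb <- consuming_reactions(mb_model, met, mb_base$fluxes)
    targets_h <- consuming_reactions(healthy_model, met, h_base$fluxes)
    if (!length(targets_mb)) {
      message("antimetabolite: '", met, "' consumed nowhere - no targets")
      mb_red <- 0; h_red <- 0
    } else {
      mb_red <- inhibition_reduction(mb_model, targets_mb, mb_base, mb_wt,
                                     factor, config)
      h_red <- if (length(targets_h)) {
        inhibition_reduction(healthy_model, targets_h, h_base, h_wt,
                             factor, config)
      } else 0
    }
    safe <- h_red <= safety_cutoff
    sel <- which(sims > tanimoto_cutoff)
    if (!length(sel)) sel <- which.max(sims)   # best match, reported not-hit
    for (s in sel) {
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = met, analog = compounds$id[s], tanimoto = sims[s],
        targeted_reactions = paste(targets_mb, collapse = ";"),
        mb_growth_reduction = mb_red, healthy_reduction = h_red,
        healthy_safe = safe,
        hit = sims[s] > tanimoto_cutoff && mb_red > growth_cutoff && safe,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_hit_table <- function() {
  data.frame(metabolite = character(), analog = character(),
             tanimoto = numeric(), targeted_reactions = character(),
             mb_growth_reduction = numeric(), healthy_reduction = numeric(),
             healthy_safe = logical(), hit = logical())
}

# Reactions consuming a metabolite under the baseline flux direction:
# negative coefficient with forward flux, or positive coefficient with
# backward flux.
consuming_reactions <- function(model, met, fluxes) {
  hits <- character()
  for (rid in model$reactions$id) {
    coef <- model$stoich[[rid]][met]
    if (is.na(coef)) next
    f <- fluxes[rid]
    if ((coef < 0 && f > 1e-9) || (coef > 0 && f < -1e-9)) {
      hits <- c(hits, rid)
    }
  }
  hits
}

# Tighten the bound nearest each baseline flux to factor * flux (toward
# zero) and return the growth reduction after FBA + MOMA re-solve.
inhibition_reduction <- function(model, targets, base, wt_value, factor,
                                 config) {
  overrides <- list()
  bounds <- model_bounds(model, config)
  for (rid in targets) {
    f <- unname(base$fluxes[rid])
    if (abs(f) <= 1e-9) next   # untouched: 0.1 x 0 would be a knockout
    if (f > 0) {
      overrides[[rid]] <- c(min(bounds$lb[rid], factor * f), factor * f)
    } else {
      overrides[[rid]] <- c(factor * f, max(bounds$ub[rid], factor * f))
    }
  }
  if (!length(overrides)) return(0)
  sol <- fba(model, config = config, bound_overrides = overrides,
             min_norm = FALSE)
  if (sol$status != "optimal") return(1)
  adj <- moma(model, base, config = config, bound_overrides = overrides)
  val <- if (adj$status == "optimal") {
    unname(adj$fluxes[model$biomass_id])
  } else sol$objective_value
  min(max(1 - val / wt_value, 0), 1)
}
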