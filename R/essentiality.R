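# Gene/reaction deletion screens: single deletions under three objectives,
# synthetic-lethal double deletions, and the healthy-cell safety filter.

#' Single gene or reaction deletions
#'
#' Deletes each target in turn, re-solves and scores the growth (or ATP /
#' lactate production) reduction. A gene deletion disables exactly the
#' reactions whose GPR evaluates inactive under the knockout; the knockout
#' value is taken from MOMA against the wild-type solution (the FBA+MOMA
#' pairing; `method = "fba"` gives the raw re-optimized value instead). A
#' deletion whose constrained model is infeasible scores zero. Targets are
#' essential when the reduction fraction strictly exceeds `cutoff` (default
#' 0.40 - "more than 40%").
#'
#' @param model A `metabolic_model`.
#' @param targets Character vector of gene ids (`type = "gene"`) or reaction
#'   ids; defaults to all genes / all reactions.
#' @param type `"gene"` or `"reaction"`.
#' @param objective `NULL` (biomass), `"atp"` or `"lactate"`; see [fba()].
#' @param config Optional [scenario_config()].
#' @param method `"moma"` (default) or `"fba"`.
#' @param cutoff Essentiality cutoff on the reduction fraction (strict `>`).
#' @return `data.frame` with `target`, `objective`, `wt_value`, `ko_value`,
#'   `reduction_fraction`, `essential`.
#' @export
single_deletion <- function(model, targets = NULL,
                            type = c("gene", "reaction"), objective = NULL,
                            config = NULL, method = c("moma", "fba"),
                            cutoff = 0.40) {
  type <- match.arg(type)
  method <- match.arg(method)
  if (is.null(targets)) {
    targets <- if (type == "gene") model$genes else model$reactions$id
  }
  if (is.null(objective)) objective <- model$biomass_id
  wt <- fba(model, objective = objective, config = config)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("wild-type optimization failed (status ", wt$status, ")")
  }
  cc <- objective_coefficients(model, objective)
  cache <- new.env(parent = emptyenv())
  ko_value <- vapply(targets, function(tg) {
    off <- if (type == "gene") reactions_disabled_by(model, tg) else tg
    key <- paste0("k_", paste(sort(off), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- deletion_value(model, off, objective, cc, wt, config, method)
    cache[[key]] <- val
    val
  }, numeric(1))
  red <- pmin(pmax(1 - ko_value / wt$objective_value, 0), 1)
  data.frame(target = targets,
             objective = if (is.character(objective)) objective else
               "custom",
             wt_value = wt$objective_value, ko_value = unname(ko_value),
             reduction_fraction = unname(red),
             essential = unname(red > cutoff),
             row.names = NULL, stringsAsFactors = FALSE)
}

deletion_value <- function(model, off_reactions, objective, cc, wt, config,
                           method) {
  if (!length(off_reactions)) return(wt$objective_value)
  sol <- fba(model, objective = objective, config = config,
             knockout_reactions = off_reactions, min_norm = FALSE)
  if (sol$status != "optimal") return(0)
  if (method == "fba") return(sol$objective_value)
  adj <- moma(model, wt, config = config,
              knockout_reactions = off_reactions,
              fix_objective = list(objective = objective,
                                   value = sol$objective_value))
  if (adj$status != "optimal") return(0)
  sum(cc * adj$fluxes)
}

#' Synthetic-lethal gene pairs by double deletion
#'
#' Screens all unordered pairs of genes that are individually non-essential
#' (single-essential genes are excluded from pairing first, following the
#' screening rule of the analysis). A pair is synthetic lethal when its
#' joint deletion reduces the objective by more than `cutoff` while both
#' single deletions stay at or below it.
#'
#' @inheritParams single_deletion
#' @param genes Candidate genes; defaults to all model genes.
#' @param singles Optional precomputed [single_deletion()] table (saves the
#'   singles pass).
#' @return `data.frame` with `gene1`, `gene2`, `wt_value`, `ko_value`,
#'   `reduction_fraction`, `synthetic_lethal`.
#' @export
double_deletion_synthetic_lethals <- function(model, genes = NULL,
                                              objective = NULL,
                                              config = NULL,
                                              method = c("moma", "fba"),
                                              cutoff = 0.40,
                                              singles = NULL) {
  method <- match.arg(method)
  if (is.null(genes)) genes <- model$genes
  if (is.null(objective)) objective <- model$biomass_id
  if (is.null(singles)) {
    singles <- single_deletion(model, genes, "gene", objective, config,
                               method, cutoff)
  }
  keep <- singles$target[!singles$essential]
  keep <- intersect(genes, keep)
  if (length(keep) < 2L) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      wt_value = numeric(), ko_value = numeric(),
                      reduction_fraction = numeric(),
                      synthetic_lethal = logical()))
  }
  wt <- fba(model, objective = objective, config = config)
  cc <- objective_coefficients(model, objective)
  pairs <- utils::combn(sort(keep), 2L)
  cache <- new.env(parent = emptyenv())
  vals <- apply(pairs, 2L, function(pr) {
    off <- reactions_disabled_by(model, pr)
    key <- paste0("k_", paste(sort(off), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- deletion_value(model, off, objective, cc, wt, config, method)
    cache[[key]] <- val
    val
  })
  red <- pmin(pmax(1 - vals / wt$objective_value, 0), 1)
  data.frame(gene1 = pairs[1, ], gene2 = pairs[2, ],
             wt_value = wt$objective_value, ko_value = vals,
             reduction_fraction = red, synthetic_lethal = red > cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Common essential genes across objectives with a healthy-cell filter
#'
#' Runs single gene deletions on the disease model under the three
#' objectives (biomass, ATP production, lactate production), intersects the
#' essential sets, then re-tests each common essential gene on the healthy
#' model: a gene is healthy-safe when its knockout reduces neither healthy
#' biomass nor healthy ATP production by more than `safety_cutoff`. The
#' therapeutic candidates are the common essential, healthy-safe genes.
#'
#' @param mb_model,healthy_model `metabolic_model` objects sharing gene ids.
#' @param config Optional [scenario_config()] applied to both models.
#' @param cutoff Essentiality cutoff on the disease model (default 0.40).
#' @param safety_cutoff Allowed healthy reduction (default 0.40, symmetric
#'   with the disease criterion).
#' @param method `"moma"` or `"fba"`.
#' @return `data.frame` with one row per gene essential for at least one
#'   objective: `gene`, logical `essential_biomass` / `essential_atp` /
#'   `essential_lactate`, `common_essential`, `healthy_biomass_reduction`,
#'   `healthy_atp_reduction`, `healthy_safe`, `candidate`.
#' @export
common_essential_screen <- function(mb_model, healthy_model, config = NULL,
                                    cutoff = 0.40, safety_cutoff = 0.40,
                                    method = "moma") {
  objs <- list(biomass = NULL, atp = "atp", lactate = "lactate")
  ess <- lapply(objs, function(ob)
    single_deletion(mb_model, objective = ob, config = config,
                    method = method, cutoff = cutoff))
  genes <- ess$biomass$target
  tab <- data.frame(
    gene = genes,
    essential_biomass = ess$biomass$essential,
    essential_atp = ess$atp$essential[match(genes, ess$atp$target)],
    essential_lactate = ess$lactate$essential[match(genes,
                                                    ess$lactate$target)],
    stringsAsFactors = FALSE)
  tab$common_essential <- tab$essential_biomass & tab$essential_atp &
    tab$essential_lactate
  tab <- tab[tab$essential_biomass | tab$essential_atp |
               tab$essential_lactate, , drop = FALSE]

  tab$healthy_biomass_reduction <- NA_real_
  tab$healthy_atp_reduction <- NA_real_
  tab$healthy_safe <- NA
  check <- which(tab$common_essential)
  if (length(check)) {
    hb <- single_deletion(healthy_model, tab$gene[check], "gene", NULL,
                          config, method, safety_cutoff)
    ha <- single_deletion(healthy_model, tab$gene[check], "gene", "atp",
                          config, method, safety_cutoff)
    tab$healthy_biomass_reduction[check] <- hb$reduction_fraction
    tab$healthy_atp_reduction[check] <- ha$reduction_fraction
    tab$healthy_safe[check] <- hb$reduction_fraction <= safety_cutoff &
      ha$reduction_fraction <= safety_cutoff
  }
  tab$candidate <- tab$common_essential & !is.na(tab$healthy_safe) &
    tab$healthy_safe
  rownames(tab) <- NULL
  tab
}
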