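# Scenario configuration: context-specific uptake constraints and the
# deprivation / metastasis scenario runner.

# nutrient label -> base metabolite species name
NUTRIENT_SPECIES <- c(
  glucose = "glc", glutamine = "gln", oxygen = "o2", leucine = "leu",
  tryptophan = "trp", tyrosine = "tyr", methionine = "met",
  glycogen = "glyg", ketone_bodies = "ketone", ammonia = "nh4",
  lactate = "lac"
)

#' Scenario configuration for context-specific constraints
#'
#' Carries the uptake bounds (mmol/gDW/h, as magnitudes) imposed on the
#' cerebellum system, the neuron/astrocyte tissue split used to share each
#' bound between the two cell types, and per-reaction overrides. The default
#' uptakes are the medulloblastoma context: glucose 0.852, glutamine 0.080,
#' oxygen 0.142, leucine 0.034 (= glucose/25), tryptophan 0.0074, tyrosine
#' 0.0028, methionine 0.008, glycogen 0 and ketone bodies 0; the tissue
#' split is 97% neurons / 3% astrocytes.
#'
#' @param uptake_bounds Named numeric vector of uptake magnitudes.
#' @param neuron_fraction,astrocyte_fraction Tissue fractions, summing to 1.
#' @param overrides Named list of `c(lb, ub)` reaction-bound overrides.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(uptake_bounds = NULL, neuron_fraction = 0.97,
                            astrocyte_fraction = 1 - neuron_fraction,
                            overrides = list()) {
  defaults <- c(glucose = 0.852, glutamine = 0.080, oxygen = 0.142,
                leucine = 0.034, tryptophan = 0.0074, tyrosine = 0.0028,
                methionine = 0.008, glycogen = 0, ketone_bodies = 0)
  ub <- defaults
  if (!is.null(uptake_bounds)) ub[names(uptake_bounds)] <- uptake_bounds
  if (any(ub < 0)) stop("uptake bounds are magnitudes and must be >= 0")
  if (neuron_fraction < 0 || neuron_fraction > 1 ||
      abs(neuron_fraction + astrocyte_fraction - 1) > 1e-9) {
    stop("neuron/astrocyte fractions must lie in [0,1] and sum to 1")
  }
  structure(list(uptake_bounds = ub, neuron_fraction = neuron_fraction,
                 astrocyte_fraction = astrocyte_fraction,
                 overrides = overrides),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file with optional keys `uptake_bounds`,
#'   `neuron_fraction`, `overrides`.
#' @return A [scenario_config()].
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  scenario_config(
    uptake_bounds = if (!is.null(obj$uptake_bounds)) unlist(obj$uptake_bounds),
    neuron_fraction = if (!is.null(obj$neuron_fraction))
      obj$neuron_fraction else 0.97,
    overrides = if (!is.null(obj$overrides))
      lapply(obj$overrides, as.numeric) else list())
}

# Resolve a scenario_config into per-reaction bound assignments.
# An uptake magnitude b is split multiplicatively: 0.97*b to the neuron
# exchange and 0.03*b to the astrocyte exchange when both exist; a nutrient
# with a single-cell transporter receives the full bound (message). The new
# value sets the exchange upper bound; the lower bound is clamped to stay
# consistent (so forced uptakes relax when a scenario zeroes the nutrient).
apply_scenario_bounds <- function(model, config) {
  lb <- numeric(0); ub <- numeric(0)
  rxns <- model$reactions
  for (nutrient in names(config$uptake_bounds)) {
    species <- NUTRIENT_SPECIES[[nutrient]]
    if (is.null(species)) species <- nutrient
    b <- config$uptake_bounds[[nutrient]]
    ex <- rxns$id[rxns$is_exchange]
    hits <- ex[vapply(ex, function(rid) {
      sto <- model$stoich[[rid]]
      sto > 0 && metabolite_base(names(sto)) == species
    }, logical(1))]
    if (!length(hits)) {
      message("scenario: no uptake exchange for '", nutrient, "' - skipped")
      next
    }
    tags <- vapply(hits, function(rid)
      metabolite_tag(names(model$stoich[[rid]])), character(1))
    both <- all(c("N", "A") %in% tags)
    for (k in seq_along(hits)) {
      frac <- if (!both) {
        if (length(hits) > 1L) 1 / length(hits) else {
          message("scenario: single-cell transporter for '", nutrient,
                  "' - full bound assigned")
          1
        }
      } else if (tags[k] == "N") config$neuron_fraction
        else if (tags[k] == "A") config$astrocyte_fraction else 1
      new_ub <- b * frac
      ub[hits[k]] <- new_ub
      cur_lb <- rxns$lower_bound[match(hits[k], rxns$id)]
      lb[hits[k]] <- min(cur_lb, new_ub)
    }
  }
  for (rid in names(config$overrides)) {
    lb[rid] <- config$overrides[[rid]][1]
    ub[rid] <- config$overrides[[rid]][2]
  }
  list(lb = lb, ub = ub)
}

#' Run a nutrient-deprivation scenario
#'
#' Reproduces the deprivation experiments: the named uptake bounds are set
#' to zero, FBA (biomass maximization) is run on the constrained model, and
#' MOMA then adjusts the solution against the baseline flux state, mirroring
#' the FBA+MOMA pairing used throughout the analysis. Returns the post-MOMA
#' fluxes, their energy accounting and the realized biomass rate.
#'
#' @param model A `metabolic_model`.
#' @param config A [scenario_config()]; defaults to the medulloblastoma
#'   context bounds.
#' @param scenario One of `"baseline"`, `"no_glucose"`, `"no_glutamine"`,
#'   `"no_both"`.
#' @param reference Optional baseline [flux_vector()] to adjust against;
#'   computed by FBA under `config` when missing.
#' @return List with elements `fluxes` ([flux_vector()]), `accounting`
#'   ([energy_accounting()] result) and `biomass`.
#' @export
scenario_run <- function(model, config = scenario_config(),
                         scenario = c("baseline", "no_glucose",
                                      "no_glutamine", "no_both"),
                         reference = NULL) {
  scenario <- match.arg(scenario)
  zero <- switch(scenario,
    baseline = character(),
    no_glucose = "glucose",
    no_glutamine = "glutamine",
    no_both = c("glucose", "glutamine"))
  if (is.null(reference)) reference <- fba(model, config = config)
  if (reference$status != "optimal") {
    stop("baseline FBA is ", reference$status, "; scenario aborted")
  }
  if (!length(zero)) {
    acct <- energy_accounting(model, reference)
    return(list(fluxes = reference, accounting = acct,
                biomass = unname(reference$fluxes[model$biomass_id])))
  }
  cfg2 <- config
  cfg2$uptake_bounds[zero] <- 0
  sol <- fba(model, config = cfg2)
  if (sol$status != "optimal") {
    return(list(fluxes = sol, accounting = NULL, biomass = NA_real_))
  }
  adj <- moma(model, reference, config = cfg2,
              fix_objective = list(objective = model$biomass_id,
                                   value = sol$objective_value))
  if (adj$status != "optimal") {
    return(list(fluxes = adj, accounting = NULL, biomass = NA_real_))
  }
  list(fluxes = adj, accounting = energy_accounting(model, adj),
       biomass = unname(adj$fluxes[model$biomass_id]))
}
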