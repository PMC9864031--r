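# End-to-end workflow: integrate -> solve -> sample -> regulate -> couple ->
# essentiality -> antimetabolite, with per-stage artifacts, content-hash
# caching and a summary report.

#' Pipeline configuration
#'
#' Bundles every input and cutoff of the full workflow. Models, expression
#' data and the compound table may be given as in-memory objects or file
#' paths. Cutoffs are validated up front so a bad configuration fails
#' before any stage runs.
#'
#' @param healthy_model,mb_model `metabolic_model` objects or model file
#'   paths.
#' @param expression An `expression_matrix` or TSV path
#'   ([read_expression_tsv()]).
#' @param compounds Compound `data.frame` or TSV path.
#' @param condition_healthy,condition_mb Condition labels in the expression
#'   data.
#' @param threshold_fraction Binarization threshold fraction (see
#'   [gimme_threshold_presets]); may be a preset name.
#' @param scenario A [scenario_config()].
#' @param n_samples,thinning ACHR settings (defaults 10000 / 100).
#' @param seed Root seed; stage seeds are derived from it.
#' @param z_crit,essential_cutoff,tanimoto_cutoff,inhibition_factor,alpha,
#'   growth_fraction,safety_cutoff Analysis cutoffs (defaults 1.96, 0.40,
#'   0.90, 0.1, 0.05, 0.9, 0.40).
#' @param out_dir Output directory for stage artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(healthy_model, mb_model, expression, compounds,
                            condition_healthy = "healthy",
                            condition_mb = "MB",
                            threshold_fraction = "GSE37418",
                            scenario = scenario_config(),
                            n_samples = 10000L, thinning = 100L, seed = 1L,
                            z_crit = 1.96, essential_cutoff = 0.40,
                            tanimoto_cutoff = 0.90, inhibition_factor = 0.1,
                            alpha = 0.05, growth_fraction = 0.9,
                            safety_cutoff = 0.40, out_dir = tempfile("mbgem")) {
  if (is.character(threshold_fraction)) {
    threshold_fraction <- gimme_threshold_presets[[threshold_fraction]]
    if (is.null(threshold_fraction)) stop("unknown threshold preset")
  }
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || x < lo || x > hi) {
      stop("invalid ", nm, ": must lie in [", lo, ", ", hi, "]")
    }
  }
  chk(tanimoto_cutoff, 0, 1, "tanimoto_cutoff")
  chk(essential_cutoff, 0, 1, "essential_cutoff")
  chk(inhibition_factor, 0, 1, "inhibition_factor")
  chk(alpha, 0, 1, "alpha")
  chk(growth_fraction, 1e-12, 1, "growth_fraction")
  chk(safety_cutoff, 0, 1, "safety_cutoff")
  chk(threshold_fraction, 1e-12, 10, "threshold_fraction")
  if (z_crit <= 0) stop("invalid z_crit: must be positive")
  load_if_path <- function(x, loader) if (is.character(x)) {
    if (!file.exists(x)) stop("referenced file does not exist: ", x)
    loader(x)
  } else x
  structure(list(
    healthy_model = load_if_path(healthy_model, load_model),
    mb_model = load_if_path(mb_model, load_model),
    expression = load_if_path(expression, read_expression_tsv),
    compounds = load_if_path(compounds, read_compound_table),
    condition_healthy = condition_healthy, condition_mb = condition_mb,
    threshold_fraction = threshold_fraction, scenario = scenario,
    n_samples = as.integer(n_samples), thinning = as.integer(thinning),
    seed = as.integer(seed), z_crit = z_crit,
    essential_cutoff = essential_cutoff, tanimoto_cutoff = tanimoto_cutoff,
    inhibition_factor = inhibition_factor, alpha = alpha,
    growth_fraction = growth_fraction, safety_cutoff = safety_cutoff,
    out_dir = out_dir), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on the paired healthy/MB models: GIMME
#' integration of the expression data into the MB model, the deprivation
#' scenarios, ACHR sampling of both models with differential-flux testing,
#' ZF/ZG regulation classification, flux coupling against biomass, the
#' essentiality and synthetic-lethality screens with the healthy-safety
#' filter, and the antimetabolite screen. Stage outputs are written to
#' `config$out_dir` as TSV/JSON; slow stages are cached by a content hash of
#' their inputs, so re-runs with an unchanged configuration reuse results.
#' Identical configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List with per-stage results and `summary` (the headline counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  manifest <- list()
  manifest_path <- file.path(config$out_dir, "manifest.json")
  note <- function(stage, state) {
    manifest[[stage]] <<- state
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  }
  cached <- function(stage, inputs, fun) {
    key <- rlang::hash(list(stage = stage, inputs = inputs))
    path <- file.path(cache_dir, paste0(stage, "_", key, ".rds"))
    if (file.exists(path)) {
      note(stage, "cached")
      return(readRDS(path))
    }
    out <- fun()
    saveRDS(out, path)
    note(stage, "complete")
    out
  }
  tsv <- function(df, name) utils::write.table(
    df, file.path(config$out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # 1. transcriptome integration ---------------------------------------
  states <- binarize_expression(config$expression, config$condition_mb,
                                config$threshold_fraction)
  gim <- cached("integrate",
                list(states$states, config$growth_fraction,
                     config$mb_model$reactions),
                function() gimme_reduce(config$mb_model, states,
                                        config$growth_fraction,
                                        config$scenario))
  mb <- gim$model
  tsv(data.frame(gene = names(states$states), state = states$states),
      "gene_states.tsv")
  tsv(data.frame(removed_reaction = gim$removed), "gimme_removed.tsv")

  # 2. scenarios ---------------------------------------------------------
  scen_names <- c("baseline", "no_glucose", "no_glutamine", "no_both")
  scenarios <- lapply(scen_names, function(sc)
    scenario_run(mb, config$scenario, sc))
  names(scenarios) <- scen_names
  tsv(data.frame(
    scenario = scen_names,
    biomass = vapply(scenarios, function(s)
      if (is.null(s$biomass)) NA_real_ else s$biomass, numeric(1)),
    atp_total = vapply(scenarios, function(s)
      if (is.null(s$accounting)) NA_real_ else s$accounting$atp_total,
      numeric(1))), "scenarios.tsv")

  # 3. flux sampling -----------------------------------------------------
  seed_h <- config$seed + 1L
  seed_m <- config$seed + 2L
  samp_h <- cached("sample_healthy",
                   list(config$healthy_model$reactions, config$scenario,
                        config$n_samples, config$thinning, seed_h),
                   function() achr_sample(config$healthy_model,
                                          config$scenario,
                                          config$n_samples, seed_h,
                                          config$thinning))
  samp_m <- cached("sample_mb",
                   list(mb$reactions, config$scenario, config$n_samples,
                        config$thinning, seed_m),
                   function() achr_sample(mb, config$scenario,
                                          config$n_samples, seed_m,
                                          config$thinning))

  # 4. differential flux + regulation ------------------------------------
  diff <- differential_flux_test(samp_h, samp_m, config$alpha)
  tsv(diff, "differential_flux.tsv")
  zrec <- compute_z_scores(samp_h, samp_m, config$expression,
                           config$condition_healthy, config$condition_mb,
                           mb)
  reg <- classify_regulation(zrec, config$z_crit, mb)
  tsv(reg, "regulation.tsv")

  # 5. flux coupling -----------------------------------------------------
  coup <- cached("coupling", list(mb$reactions, mb$stoich),
                 function() biomass_coupled_set(mb))
  tsv(coup, "coupling.tsv")

  # 6. essentiality ------------------------------------------------------
  ess <- cached("essentiality",
                list(mb$reactions, mb$stoich, config$scenario,
                     config$essential_cutoff),
                function() single_deletion(mb, config = config$scenario,
                                           cutoff = config$essential_cutoff))
  sl <- cached("synthetic_lethals",
               list(mb$reactions, mb$stoich, config$scenario,
                    config$essential_cutoff),
               function() double_deletion_synthetic_lethals(
                 mb, config = config$scenario,
                 cutoff = config$essential_cutoff, singles = ess))
  screen <- cached("common_essential",
                   list(mb$reactions, config$healthy_model$reactions,
                        config$scenario, config$essential_cutoff,
                        config$safety_cutoff),
                   function() common_essential_screen(
                     mb, config$healthy_model, config$scenario,
                     config$essential_cutoff, config$safety_cutoff))
  tsv(ess, "single_deletion.tsv")
  tsv(sl, "synthetic_lethals.tsv")
  tsv(screen, "common_essential.tsv")

  # 7. antimetabolite ----------------------------------------------------
  anti <- cached("antimetabolite",
                 list(mb$reactions, config$compounds, config$scenario,
                      config$tanimoto_cutoff, config$inhibition_factor,
                      config$essential_cutoff, config$safety_cutoff),
                 function() competitive_inhibition_screen(
                   mb, config$healthy_model, config$compounds,
                   config$scenario, config$inhibition_factor,
                   config$tanimoto_cutoff, config$essential_cutoff,
                   config$safety_cutoff))
  tsv(anti, "antimetabolite_hits.tsv")

  counts <- attr(coup, "counts")
  summary <- list(
    gimme_removed = length(gim$removed),
    gimme_inconsistency = gim$inconsistency_score,
    biomass_baseline = scenarios$baseline$biomass,
    biomass_no_glucose = scenarios$no_glucose$biomass,
    biomass_no_glutamine = scenarios$no_glutamine$biomass,
    atp_total_baseline = scenarios$baseline$accounting$atp_total,
    atp_total_no_both = if (is.null(scenarios$no_both$accounting)) 0 else
      scenarios$no_both$accounting$atp_total,
    significant_reactions = sum(diff$significant),
    tested_reactions = nrow(diff),
    tr_reactions = sum(reg$class == "TR"),
    ntr_reactions = sum(reg$class == "NTR"),
    coupled_to_biomass = sum(coup$class %in%
      c("fully", "partially", "directionally_i_to_j",
        "directionally_j_to_i")),
    fully_coupled = unname(counts[["fully"]]),
    essential_genes = sum(ess$essential),
    synthetic_lethal_pairs = sum(sl$synthetic_lethal),
    common_essential = sum(screen$common_essential),
    candidate_genes = sum(screen$candidate),
    antimetabolite_hits = sum(anti$hit),
    antimetabolite_hit_metabolites =
      sort(unique(anti$metabolite[anti$hit])))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("summary", "complete")
  invisible(list(states = states, gimme = gim, scenarios = scenarios,
                 sampling = list(healthy = samp_h, mb = samp_m),
                 differential = diff, regulation = reg, coupling = coup,
                 essentiality = ess, synthetic_lethals = sl,
                 common_essential = screen, antimetabolite = anti,
                 summary = summary))
}
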