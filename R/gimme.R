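# Transcriptome integration: Present/Absent binarization at a
# percent-of-mean threshold and GIMME model reduction.

#' Expression matrix with condition labels
#'
#' @param values Numeric matrix, genes x samples, linear scale, rownames =
#'   gene ids, colnames = sample ids.
#' @param conditions Character vector of condition labels per sample (e.g.
#'   `healthy`, `MB`, `WNT`, `SHH`, `GR3`, `GR4`, `M0`, `M2`, `M4`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, conditions) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (length(conditions) != ncol(values)) {
    stop("one condition label per sample is required")
  }
  structure(list(
    values = values, genes = rownames(values),
    samples = data.frame(sample = colnames(values),
                         condition = unname(conditions),
                         stringsAsFactors = FALSE)),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", paste(unique(x$samples$condition), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Percent-of-mean thresholds used for the expression datasets
#'
#' Named presets for the binarization threshold fraction of each
#' context-specific model: the overall MB threshold of the GSE37418-like
#' series (0.723), its four subgroup thresholds (WNT 0.725, SHH 0.747,
#' GR3 0.9024, GR4 0.7634), the GSE62600-like MB threshold (0.30) and the
#' metastasis-stage thresholds of the GSE10327-like series (M0 0.45,
#' M2 0.50, M4 0.55).
#'
#' @export
gimme_threshold_presets <- c(
  GSE37418 = 0.723, WNT = 0.725, SHH = 0.747, GR3 = 0.9024, GR4 = 0.7634,
  GSE62600 = 0.30, M0 = 0.45, M2 = 0.50, M4 = 0.55
)

#' Binarize expression into Present/Absent gene states
#'
#' Each gene's state in a condition is decided against a single threshold:
#' `threshold_fraction` times the grand mean of all per-gene mean expression
#' levels in that condition. Genes whose mean expression is greater than or
#' equal to the threshold are Present, the rest Absent; ties are Present
#' (the conservative choice - it keeps reactions in the model).
#'
#' @param expr An [expression_matrix()].
#' @param condition Condition label selecting the samples.
#' @param threshold_fraction Positive fraction of the grand mean; see
#'   [gimme_threshold_presets] for the shipped values.
#' @return An object of class `gene_state_map`: list with `states` (named
#'   character, `"P"`/`"A"`), `threshold_value`, `threshold_fraction`.
#' @export
binarize_expression <- function(expr, condition, threshold_fraction) {
  stopifnot(threshold_fraction > 0)
  keep <- expr$samples$condition == condition
  if (!any(keep)) stop("no samples with condition '", condition, "'")
  vals <- expr$values[, keep, drop = FALSE]
  gene_means <- rowMeans(vals)
  threshold <- threshold_fraction * mean(gene_means)
  states <- ifelse(gene_means >= threshold, "P", "A")
  structure(list(states = states, threshold_value = threshold,
                 threshold_fraction = threshold_fraction,
                 condition = condition),
            class = "gene_state_map")
}

#' @export
print.gene_state_map <- function(x, ...) {
  cat("<gene_state_map> condition ", x$condition, ": ",
      sum(x$states == "P"), " Present / ", sum(x$states == "A"),
      " Absent (threshold ", format(x$threshold_value, digits = 4),
      " = ", x$threshold_fraction, " x grand mean)\n", sep = "")
  invisible(x)
}

#' GIMME reduction of a model against binarized expression
#'
#' Classic GIMME: reactions whose GPR evaluates inactive when the Absent
#' genes are removed form the penalized set; a linear program then minimizes
#' the total absolute flux through penalized reactions subject to steady
#' state, bounds and a required biomass functionality
#' (`biomass >= growth_fraction x` the unconstrained FBA optimum). The
#' objective value is the inconsistency score. Penalized reactions that carry
#' zero flux at the optimum *and* cannot carry flux at all under the growth
#' constraint (flux-variability check) are removed from the model.
#'
#' @param model A `metabolic_model`.
#' @param states A `gene_state_map` from [binarize_expression()]. Model
#'   genes missing from it are treated as Present (and noted).
#' @param growth_fraction Required fraction of the FBA optimum in (0, 1];
#'   default 0.9, the GIMME literature default.
#' @param config Optional [scenario_config()].
#' @return List with `model` (the reduced `metabolic_model`),
#'   `inconsistency_score`, `removed` (reaction ids), `penalized`.
#' @export
gimme_reduce <- function(model, states, growth_fraction = 0.9,
                         config = NULL) {
  stopifnot(growth_fraction > 0, growth_fraction <= 1)
  st <- states$states
  missing_genes <- setdiff(model$genes, names(st))
  if (length(missing_genes)) {
    message("GIMME: ", length(missing_genes),
            " model gene(s) absent from the expression data",
            " - treated as Present")
  }
  absent <- names(st)[st == "A"]
  absent <- intersect(absent, model$genes)
  penalized <- reactions_disabled_by(model, absent)

  wt <- fba(model, config = config, min_norm = FALSE)
  if (wt$status != "optimal") stop("FBA on the input model is ", wt$status)
  req <- growth_fraction * wt$objective_value

  if (!length(penalized)) {
    return(list(model = model, inconsistency_score = 0,
                removed = character(), penalized = character()))
  }

  S <- as.matrix(build_stoichiometric_matrix(model))
  bounds <- model_bounds(model, config)
  rid <- colnames(S)
  # |v_p| via mirror split for reversible penalized reactions
  rev_p <- penalized[bounds$lb[penalized] < 0]
  n <- ncol(S)
  Saug <- S
  lb <- bounds$lb; ub <- bounds$ub
  for (p in rev_p) {
    j <- match(p, rid)
    Saug <- cbind(Saug, -S[, j])          # v_p = f - r
    lb <- c(lb, 0); ub <- c(ub, -bounds$lb[p])
    lb[j] <- 0
  }
  cc <- c(ifelse(rid %in% penalized, -1, 0), rep(-1, length(rev_p)))
  # growth constraint as inequality: -v_bio <= -req
  G <- matrix(0, 1, ncol(Saug))
  G[1, match(model$biomass_id, rid)] <- -1
  res <- simplex_lp_ineq(Saug, rep(0, nrow(Saug)), cc, lb, ub,
                         G = G, h = -req)
  if (res$status != "optimal") {
    stop("GIMME LP is ", res$status,
         " - the expression threshold is too aggressive for the required",
         " growth fraction")
  }
  v <- res$x[seq_len(n)]
  names(v) <- rid
  for (k in seq_along(rev_p)) v[rev_p[k]] <- v[rev_p[k]] - res$x[n + k]
  score <- -res$obj

  # a penalized reaction is dropped when it carries no flux at the optimum
  # and cannot carry any in the whole penalty-optimal space: max |v_p|
  # subject to growth >= req and total penalty <= score
  removed <- character()
  Gc <- rbind(G, c(ifelse(rid %in% penalized, 1, 0), rep(1, length(rev_p))))
  hc <- c(-req, score + 1e-9 * (1 + score))
  for (p in penalized) {
    if (abs(v[p]) > 1e-9) next
    rng <- flux_range_constrained(Saug, lb, ub, match(p, rid), Gc, hc)
    if (all(is.na(rng))) next
    if (max(abs(rng)) <= 1e-9) removed <- c(removed, p)
  }
  reduced <- drop_reactions(model, removed)
  list(model = reduced, inconsistency_score = score, removed = removed,
       penalized = penalized)
}

# min/max of variable j over {S v = 0, G v <= h, bounds}
flux_range_constrained <- function(S, lb, ub, j, G, h) {
  cc <- rep(0, ncol(S)); cc[j] <- 1
  lo <- simplex_lp_ineq(S, rep(0, nrow(S)), -cc, lb, ub, G = G, h = h)
  hi <- simplex_lp_ineq(S, rep(0, nrow(S)), cc, lb, ub, G = G, h = h)
  if (lo$status != "optimal" || hi$status != "optimal") {
    return(c(NA_real_, NA_real_))
  }
  c(-lo$obj, hi$obj)
}

# Remove reactions (and any metabolites left orphaned) from a model.
drop_reactions <- function(model, rxn_ids) {
  if (!length(rxn_ids)) return(model)
  keep <- !model$reactions$id %in% rxn_ids
  rxns <- model$reactions[keep, , drop = FALSE]
  stoich <- model$stoich[rxns$id]
  used <- unique(unlist(lapply(stoich, names)))
  mets <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  genes <- sort(unique(unlist(lapply(rxns$gpr, gpr_genes))))
  metabolic_model(mets, rxns, stoich, genes, model$biomass_id)
}
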