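# Flux balance analysis and minimization of metabolic adjustment.

#' Flux vector constructor
#'
#' The result container shared by [fba()], [moma()] and the scenario runner:
#' a named flux map (mmol/gDW/h), the objective value and a solver status.
#'
#' @param fluxes Named numeric vector, one entry per reaction.
#' @param objective_value Objective at the solution (`NA` if not optimal).
#' @param status `"optimal"`, `"infeasible"` or `"unbounded"`.
#' @param objective Reaction id (or coefficient vector) that was optimized.
#' @return An object of class `flux_vector`.
#' @export
flux_vector <- function(fluxes, objective_value = NA_real_,
                        status = "optimal", objective = NULL) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, objective = objective),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("<flux_vector> status: ", x$status, sep = "")
  if (!is.na(x$objective_value)) {
    cat(", objective: ", format(x$objective_value, digits = 6), sep = "")
  }
  cat(", ", length(x$fluxes), " reactions\n", sep = "")
  invisible(x)
}

# Effective bounds after scenario config and knockouts.
# Returns list(lb, ub) named by reaction id.
model_bounds <- function(model, config = NULL, knockout_genes = NULL,
                         knockout_reactions = NULL, bound_overrides = NULL) {
  rxns <- model$reactions
  lb <- stats::setNames(rxns$lower_bound, rxns$id)
  ub <- stats::setNames(rxns$upper_bound, rxns$id)
  if (!is.null(config)) {
    sc <- apply_scenario_bounds(model, config)
    lb[names(sc$lb)] <- sc$lb
    ub[names(sc$ub)] <- sc$ub
  }
  if (!is.null(bound_overrides)) {
    for (rid in names(bound_overrides)) {
      if (!rid %in% rxns$id) stop("override for unknown reaction: ", rid)
      lb[rid] <- bound_overrides[[rid]][1]
      ub[rid] <- bound_overrides[[rid]][2]
    }
  }
  off <- union(knockout_reactions,
               reactions_disabled_by(model, knockout_genes))
  if (length(off)) {
    lb[off] <- 0
    ub[off] <- 0
  }
  list(lb = lb, ub = ub)
}

# Objective coefficient vector for the named objective.
objective_coefficients <- function(model, objective) {
  rxns <- model$reactions
  cc <- stats::setNames(rep(0, nrow(rxns)), rxns$id)
  if (is.numeric(objective)) {
    cc[names(objective)] <- objective
  } else if (identical(objective, "atp")) {
    # gross ATP production: positive-yield reactions weighted by their yield
    cc[] <- pmax(rxns$atp_yield, 0)
  } else if (identical(objective, "lactate")) {
    ids <- lactate_exchange_ids(model)
    if (!length(ids)) stop("model has no lactate exchange reaction")
    cc[ids] <- 1
  } else {
    if (!objective %in% rxns$id) stop("unknown objective reaction: ",
                                      objective)
    cc[objective] <- 1
  }
  cc
}

lactate_exchange_ids <- function(model) {
  rxns <- model$reactions
  ex <- rxns$id[rxns$is_exchange]
  keep <- vapply(ex, function(rid) {
    sto <- model$stoich[[rid]]
    metabolite_base(names(sto)) == "lac" && sto < 0
  }, logical(1))
  ex[keep]
}

oxygen_exchange_ids <- function(model) {
  rxns <- model$reactions
  ex <- rxns$id[rxns$is_exchange]
  keep <- vapply(ex, function(rid) {
    sto <- model$stoich[[rid]]
    metabolite_base(names(sto)) == "o2" && sto > 0
  }, logical(1))
  ex[keep]
}

#' Flux balance analysis
#'
#' Solves the linear program `max/min c'v` subject to steady state
#' (`S v = 0`) and flux bounds, optionally under a scenario configuration
#' and gene/reaction knockouts. Among alternate optima the reported flux
#' vector is canonicalized to the minimum-norm optimal solution (a quadratic
#' polish at the fixed optimal objective), so results are deterministic and
#' do not depend on pivot order.
#'
#' @param model A `metabolic_model`.
#' @param objective A reaction id (defaults to the biomass reaction), or
#'   `"atp"` (gross ATP production, [objective_coefficients()]), or
#'   `"lactate"` (lactate excretion), or a named coefficient vector.
#' @param sense `"max"` or `"min"`.
#' @param config Optional [scenario_config()] applied before solving.
#' @param knockout_genes,knockout_reactions Identifiers to delete.
#' @param bound_overrides Named list of `c(lb, ub)` per reaction id.
#' @param min_norm Canonicalize alternate optima (default `TRUE`).
#' @return A [flux_vector()].
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min"),
                config = NULL, knockout_genes = NULL,
                knockout_reactions = NULL, bound_overrides = NULL,
                min_norm = TRUE) {
  sense <- match.arg(sense)
  if (is.null(objective)) objective <- model$biomass_id
  cc <- objective_coefficients(model, objective)
  bounds <- model_bounds(model, config, knockout_genes, knockout_reactions,
                         bound_overrides)
  S <- as.matrix(build_stoichiometric_matrix(model))
  sig <- if (sense == "max") 1 else -1
  res <- simplex_lp(S, rep(0, nrow(S)), sig * cc, bounds$lb, bounds$ub)
  if (res$status != "optimal") {
    return(flux_vector(stats::setNames(rep(NA_real_, ncol(S)), colnames(S)),
                       NA_real_, status = res$status, objective = objective))
  }
  v <- stats::setNames(res$x, colnames(S))
  obj <- sum(cc * v)
  if (min_norm) {
    v2 <- min_norm_polish(S, cc, obj, bounds$lb, bounds$ub, v)
    if (!is.null(v2)) v <- stats::setNames(v2, colnames(S))
  }
  flux_vector(v, sum(cc * v), status = "optimal", objective = objective)
}

# Minimum-norm point of the optimal face {S v = 0, c'v = obj, bounds}.
# Falls back to the simplex vertex if the QP solver declines.
min_norm_polish <- function(S, cc, obj, lb, ub, vertex) {
  n <- ncol(S)
  Aeq <- rbind(S, cc)
  qd <- qr(t(Aeq))
  Aeq <- Aeq[qd$pivot[seq_len(qd$rank)], , drop = FALSE]
  beq <- c(rep(0, nrow(S)), obj)[qd$pivot[seq_len(qd$rank)]]
  sol <- tryCatch(
    quadprog::solve.QP(diag(1, n), rep(0, n),
                       cbind(t(Aeq), diag(n), -diag(n)),
                       c(beq, lb - 1e-9, -ub - 1e-9), meq = nrow(Aeq)),
    error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  v <- pmin(pmax(sol$solution, lb), ub)
  if (max(abs(S %*% v)) > 1e-6 * max(1, max(abs(v)))) return(NULL)
  if (abs(sum(cc * v) - obj) > 1e-6 * (1 + abs(obj))) return(NULL)
  v
}

#' Flux variability range of one reaction
#'
#' Minimum and maximum feasible flux of `reaction` subject to steady state,
#' bounds and optional extra linear constraints; used by the sampler warmup,
#' GIMME pruning and the coupling analysis.
#'
#' @param model A `metabolic_model`.
#' @param reaction Reaction id.
#' @inheritParams fba
#' @param extra_eq Optional list(A, b) of extra equality rows (named columns).
#' @return Numeric `c(min, max)`.
#' @export
flux_range <- function(model, reaction, config = NULL, knockout_genes = NULL,
                       knockout_reactions = NULL, bound_overrides = NULL,
                       extra_eq = NULL) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  bounds <- model_bounds(model, config, knockout_genes, knockout_reactions,
                         bound_overrides)
  A <- S; b <- rep(0, nrow(S))
  if (!is.null(extra_eq)) {
    A <- rbind(A, extra_eq$A)
    b <- c(b, extra_eq$b)
  }
  cc <- stats::setNames(rep(0, ncol(S)), colnames(S))
  cc[reaction] <- 1
  lo <- simplex_lp(A, b, -cc, bounds$lb, bounds$ub)
  hi <- simplex_lp(A, b, cc, bounds$lb, bounds$ub)
  if (lo$status != "optimal" || hi$status != "optimal") {
    return(c(NA_real_, NA_real_))
  }
  c(-lo$obj, hi$obj)
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Finds the flux vector of a perturbed model closest in Euclidean distance
#' to a reference state: `argmin D(h, m) = sqrt(sum_i (h_i - m_i)^2)` over
#' the perturbed feasible set. The reference is typically a healthy or
#' wild-type FBA solution; the perturbation a knockout or bound change. The
#' quadratic program is solved with a dual active-set method at feasibility
#' tolerance 1e-9.
#'
#' @param model A `metabolic_model` (defines the perturbed feasible set
#'   together with the knockout/override arguments).
#' @param reference A [flux_vector()] or named numeric vector `h`. Reactions
#'   absent from the reference (e.g. when comparing across models) are
#'   treated as unreferenced and do not enter the distance.
#' @param fix_objective Optional list `list(objective=, value=)`: restrict
#'   the adjustment to flux states attaining at least `value` of the named
#'   objective. This is the FBA-then-MOMA pairing used by [scenario_run()]
#'   and the deletion screens: FBA determines the attainable objective,
#'   MOMA selects the closest flux distribution achieving it. The default
#'   (`NULL`) is the classic unconstrained adjustment.
#' @inheritParams fba
#' @return A [flux_vector()] whose `objective_value` is the distance `D`.
#' @export
moma <- function(model, reference, config = NULL, knockout_genes = NULL,
                 knockout_reactions = NULL, bound_overrides = NULL,
                 fix_objective = NULL) {
  h <- if (inherits(reference, "flux_vector")) reference$fluxes else reference
  S <- as.matrix(build_stoichiometric_matrix(model))
  bounds <- model_bounds(model, config, knockout_genes, knockout_reactions,
                         bound_overrides)
  n <- ncol(S)
  target <- stats::setNames(rep(0, n), colnames(S))
  w <- stats::setNames(rep(0, n), colnames(S))   # 1 where referenced
  shared <- intersect(names(h), colnames(S))
  target[shared] <- h[shared]
  w[shared] <- 1
  # min sum_i w_i (v_i - h_i)^2  + tiny ridge on unreferenced fluxes
  D <- diag(w + 1e-9, n)
  dvec <- w * target
  qd <- qr(t(S))
  Sr <- S[qd$pivot[seq_len(qd$rank)], , drop = FALSE]
  Amat <- cbind(t(Sr), diag(n), -diag(n))
  bvec <- c(rep(0, nrow(Sr)), bounds$lb - 1e-9, -bounds$ub - 1e-9)
  if (!is.null(fix_objective)) {
    oc <- objective_coefficients(model, fix_objective$objective)
    Amat <- cbind(Amat, oc[colnames(S)])
    bvec <- c(bvec, fix_objective$value - 1e-9 * (1 + abs(fix_objective$value)))
  }
  sol <- tryCatch(
    quadprog::solve.QP(D, dvec, Amat, bvec, meq = nrow(Sr)),
    error = function(e) NULL)
  if (is.null(sol)) {
    # infeasible perturbed set (or numerically intractable): report status
    feas <- simplex_lp(S, rep(0, nrow(S)), rep(0, n), bounds$lb, bounds$ub)
    status <- if (feas$status == "optimal") "error" else "infeasible"
    return(flux_vector(stats::setNames(rep(NA_real_, n), colnames(S)),
                       NA_real_, status = status))
  }
  v <- stats::setNames(pmin(pmax(sol$solution, bounds$lb), bounds$ub),
                       colnames(S))
  dist <- sqrt(sum((v[shared] - h[shared])^2))
  flux_vector(v, dist, status = "optimal", objective = "moma_distance")
}
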