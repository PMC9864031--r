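# Flux coupling analysis on the steady-state cone.
#
# Coupling is a property of the cone {v : S v = 0, v >= 0 in irreversible
# form}, not of the finite bounds: reversible reactions are split into
# forward/backward parts first, results are mapped back to the original
# reaction ids with the strongest class among split variants. For a pair
# (i, j) the attainable extremes of v_i with v_j normalized to 1 (two LPs,
# plus the symmetric pair) decide the class:
#   fully coupled        - ratio fixed and nonzero
#   partially coupled    - ratio bounded away from 0 and infinity, not fixed
#   directionally i->j   - activity of i forces activity of j, not conversely
#   uncoupled            - each can run without the other
#   blocked              - a reaction that can carry no flux at all

COUPLING_CLASSES <- c("fully", "partially", "directionally_i_to_j",
                      "directionally_j_to_i", "uncoupled", "blocked")

# Split reversible reactions: returns list(S, map) where map$orig gives the
# original reaction index per column and map$dir the direction (+1/-1).
irreversible_form <- function(model) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  rxns <- model$reactions
  rev <- which(rxns$lower_bound < 0)
  orig <- seq_len(ncol(S))
  dir <- rep(1, ncol(S))
  if (length(rev)) {
    S <- cbind(S, -S[, rev, drop = FALSE])
    orig <- c(orig, rev)
    dir <- c(dir, rep(-1, length(rev)))
  }
  colnames(S) <- paste0(rxns$id[orig], ifelse(dir > 0, "", "_rev"))
  list(S = S, orig = rxns$id[orig], dir = dir)
}

# Extremes of v_i over {S v = 0, 0 <= v <= cap, v_j = 1}; cap acts as the
# proxy for infinity on the cone.
ratio_extremes <- function(S, i, j, cap = 1e3) {
  n <- ncol(S)
  lb <- rep(0, n); ub <- rep(cap, n)
  lb[j] <- 1; ub[j] <- 1
  cc <- rep(0, n); cc[i] <- 1
  lo <- simplex_lp(S, rep(0, nrow(S)), -cc, lb, ub)
  hi <- simplex_lp(S, rep(0, nrow(S)), cc, lb, ub)
  if (lo$status != "optimal" || hi$status != "optimal") return(NULL)
  c(min = -lo$obj, max = hi$obj)
}

#' Coupling class of a reaction pair
#'
#' Classifies the flux coupling between two reactions on the steady-state
#' cone via the standard four-LP characterization (ratio extremes in both
#' orientations). Numerical equality of the ratio extremes for the "fully
#' coupled" call uses tolerance 1e-6; the ratio cap standing in for an
#' unbounded direction is 1e3.
#'
#' @param model A `metabolic_model` (split to irreversible form internally).
#' @param i,j Reaction ids.
#' @param cap Cone box cap (proxy for infinity).
#' @param tol Equality tolerance for ratio extremes.
#' @return List with `i`, `j`, `ratio_min`, `ratio_max` (extremes of
#'   `v_i / v_j`), and `class` (one of fully, partially,
#'   directionally_i_to_j, directionally_j_to_i, uncoupled, blocked).
#' @export
classify_pair_coupling <- function(model, i, j, cap = 1e3, tol = 1e-6) {
  irr <- irreversible_form(model)
  blocked <- blocked_reactions_irr(irr, cap)
  classify_pair_irr(irr, i, j, blocked, cap, tol)
}

# blocked original ids: zero max flux in every split direction
blocked_reactions_irr <- function(irr, cap = 1e3) {
  S <- irr$S
  n <- ncol(S)
  maxflux <- stats::setNames(rep(0, length(unique(irr$orig))),
                             unique(irr$orig))
  lb <- rep(0, n); ub <- rep(cap, n)
  for (k in seq_len(n)) {
    cc <- rep(0, n); cc[k] <- 1
    hi <- simplex_lp(S, rep(0, nrow(S)), cc, lb, ub)
    if (hi$status == "optimal") {
      maxflux[irr$orig[k]] <- max(maxflux[irr$orig[k]], hi$obj)
    }
  }
  names(maxflux)[maxflux <= 1e-9]
}

classify_pair_irr <- function(irr, i, j, blocked, cap = 1e3, tol = 1e-6) {
  rec <- list(i = i, j = j, ratio_min = NA_real_, ratio_max = NA_real_)
  if (i %in% blocked || j %in% blocked) {
    rec$class <- "blocked"
    return(rec)
  }
  # strongest class over split-variant combinations that are both unblocked
  cols_i <- which(irr$orig == i)
  cols_j <- which(irr$orig == j)
  best <- NULL
  for (ci in cols_i) for (cj in cols_j) {
    ij <- ratio_extremes(irr$S, ci, cj, cap)
    if (is.null(ij)) next
    ji <- ratio_extremes(irr$S, cj, ci, cap)
    if (is.null(ji)) next
    i_can_rest <- ij["min"] <= tol          # v_i can be 0 while v_j runs
    j_can_rest <- ji["min"] <= tol
    cls <- if (!i_can_rest && !j_can_rest) {
      if (abs(ij["max"] - ij["min"]) <= tol * max(1, abs(ij["max"])))
        "fully" else "partially"
    } else if (!j_can_rest) "directionally_i_to_j"
      else if (!i_can_rest) "directionally_j_to_i"
      else "uncoupled"
    rank <- match(cls, COUPLING_CLASSES)
    if (is.null(best) || rank < match(best$class, COUPLING_CLASSES)) {
      best <- list(ratio_min = unname(ij["min"]),
                   ratio_max = unname(ij["max"]), class = cls)
    }
  }
  if (is.null(best)) {
    rec$class <- "blocked"
    return(rec)
  }
  rec$ratio_min <- best$ratio_min
  rec$ratio_max <- best$ratio_max
  rec$class <- best$class
  rec
}

#' Reactions coupled to the biomass reaction
#'
#' Classifies every non-blocked reaction against the growth reaction and
#' partitions the result by coupling class; the "coupled set" reported by
#' the analysis is everything classed fully, partially or directionally.
#'
#' @param model A `metabolic_model`.
#' @param anchor Reaction id to couple against (default the biomass
#'   reaction).
#' @inheritParams classify_pair_coupling
#' @return `data.frame` with `reaction`, `class`, `ratio_min`, `ratio_max`
#'   (ratio of reaction flux to anchor flux), plus a `counts` attribute with
#'   the per-class tally.
#' @export
biomass_coupled_set <- function(model, anchor = model$biomass_id,
                                cap = 1e3, tol = 1e-6) {
  irr <- irreversible_form(model)
  blocked <- blocked_reactions_irr(irr, cap)
  if (anchor %in% blocked) stop("anchor reaction '", anchor, "' is blocked")
  others <- setdiff(model$reactions$id, anchor)
  rows <- lapply(others, function(rid) {
    rec <- classify_pair_irr(irr, rid, anchor, blocked, cap, tol)
    data.frame(reaction = rid, class = rec$class,
               ratio_min = rec$ratio_min, ratio_max = rec$ratio_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- table(factor(out$class, COUPLING_CLASSES))
  out
}
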