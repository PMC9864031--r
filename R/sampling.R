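# ACHR flux sampling and sampling-based differential-flux testing.

#' Sample the feasible flux space with ACHR
#'
#' Artificially-centered hit-and-run sampling of the steady-state flux
#' polytope `{v : S v = 0, lb <= v <= ub}`. Warmup points are the
#' `2 x n_reactions` boundary solutions of per-reaction min/max LPs (the
#' flux-variability vertices); chain directions are drawn through the running
#' center of all stored points, which adapts the proposal to the elongated
#' geometry typical of flux cones. The chain is deterministic for a fixed
#' seed.
#'
#' @param model A `metabolic_model`.
#' @param config Optional [scenario_config()].
#' @param n_samples Number of flux profiles to return (the analysis uses
#'   10,000).
#' @param seed Integer seed; fans out to the warmup and chain streams.
#' @param thinning Chain steps per recorded sample (default 100).
#' @param bound_cap Box cap applied to unbounded directions (with a
#'   warning), keeping the sampled region bounded.
#' @param knockout_genes,knockout_reactions Optional deletions.
#' @return An object of class `sampling_result`: list with `samples`
#'   (reactions x n_samples matrix), `seed`, `n_warmup`, `thinning`.
#' @export
achr_sample <- function(model, config = NULL, n_samples = 1000L,
                        seed = 1L, thinning = 100L, bound_cap = 1e3,
                        knockout_genes = NULL, knockout_reactions = NULL) {
  bounds <- model_bounds(model, config, knockout_genes, knockout_reactions)
  capped <- bounds$ub > bound_cap | bounds$lb < -bound_cap
  if (any(capped)) {
    warning(sum(capped), " unbounded direction(s) capped at +/-", bound_cap)
    bounds$ub <- pmin(bounds$ub, bound_cap)
    bounds$lb <- pmax(bounds$lb, -bound_cap)
  }
  S <- as.matrix(build_stoichiometric_matrix(model))
  n <- ncol(S)
  rid <- colnames(S)

  feas <- simplex_lp(S, rep(0, nrow(S)), rep(0, n), bounds$lb, bounds$ub)
  if (feas$status != "optimal") stop("model is infeasible; cannot sample")

  set.seed(seed)
  warmup <- matrix(0, n, 2L * n, dimnames = list(rid, NULL))
  cc0 <- rep(0, n)
  for (j in seq_len(n)) {
    cc <- cc0; cc[j] <- 1
    hi <- simplex_lp(S, rep(0, nrow(S)), cc, bounds$lb, bounds$ub)
    lo <- simplex_lp(S, rep(0, nrow(S)), -cc, bounds$lb, bounds$ub)
    if (hi$status != "optimal" || lo$status != "optimal") {
      stop("warmup LP failed for reaction ", rid[j])
    }
    warmup[, 2L * j - 1L] <- hi$x
    warmup[, 2L * j] <- lo$x
  }
  # Coordinates whose realized flux-variability span is zero (blocked
  # reactions, forced uptakes) are frozen at their value and removed from
  # the walk; the remaining coordinates are whitened by their span so the
  # polytope has comparable extents in every direction - without this,
  # directions mixing wide and narrow fluxes are limited to tiny chords
  # and the chain mixes poorly. Both are affine reparametrizations, so
  # uniformity of hit-and-run is preserved.
  span <- apply(warmup, 1L, max) - apply(warmup, 1L, min)
  free <- span > 1e-9
  if (!any(free)) {
    samples <- matrix(warmup[, 1L], n, n_samples,
                      dimnames = list(rid, NULL))
  } else {
    scale <- span[free]
    Sf <- S[, free, drop = FALSE] * rep(scale, each = nrow(S))
    qd <- qr(t(Sf))
    r <- qd$rank
    nf <- sum(free)
    if (r >= nf) {
      samples <- matrix(warmup[, 1L], n, n_samples,
                        dimnames = list(rid, NULL))
    } else {
      # orthonormal basis of the free-coordinate null space: the chain is
      # re-projected onto the affine slice, so mass balance cannot drift
      N <- qr.Q(qd, complete = TRUE)[, (r + 1L):nf, drop = FALSE]
      wf <- warmup[free, , drop = FALSE] / scale
      chain <- .achr_chain(N, wf, wf[, 1L], bounds$lb[free] / scale,
                           bounds$ub[free] / scale, as.integer(n_samples),
                           as.integer(thinning))
      samples <- matrix(warmup[, 1L], n, n_samples,
                        dimnames = list(rid, NULL))
      samples[free, ] <- chain * scale
    }
  }

  # Geweke-style drift check: warn when early and late chain means diverge
  nq <- max(10L, n_samples %/% 5L)
  if (n_samples >= 50L) {
    early <- rowMeans(samples[, seq_len(nq), drop = FALSE])
    late <- rowMeans(samples[, (n_samples - nq + 1L):n_samples, drop = FALSE])
    sdv <- apply(samples, 1L, stats::sd)
    drift <- abs(late - early) / (sdv + 1e-12)
    if (any(sdv > 1e-9) &&
        stats::median(drift[sdv > 1e-9]) > 1.5) {
      warning("sampler mean drift detected; consider more thinning")
    }
  }
  structure(list(samples = samples, seed = seed, n_warmup = 2L * n,
                 thinning = thinning),
            class = "sampling_result")
}

#' @export
print.sampling_result <- function(x, ...) {
  cat("<sampling_result> ", nrow(x$samples), " reactions x ",
      ncol(x$samples), " samples (seed ", x$seed, ", thinning ",
      x$thinning, ")\n", sep = "")
  invisible(x)
}

#' Differential-flux test between two sampled models
#'
#' Welch's two-sample t-test (unequal variances) on the per-reaction sampled
#' flux distributions of two conditions, with Benjamini-Hochberg step-up
#' correction across the shared reaction set. Reactions present in only one
#' model are skipped (the analysis is defined on the common reactions).
#'
#' @param a,b `sampling_result` objects.
#' @param alpha Significance level for the adjusted p-values (default 0.05).
#' @return `data.frame` with columns `reaction`, `mean_a`, `mean_b`,
#'   `var_a`, `var_b`, `t_stat`, `df`, `p`, `p_adj`, `significant`.
#' @export
differential_flux_test <- function(a, b, alpha = 0.05) {
  shared <- intersect(rownames(a$samples), rownames(b$samples))
  if (!length(shared)) stop("no shared reactions between the two samplings")
  xa <- a$samples[shared, , drop = FALSE]
  xb <- b$samples[shared, , drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t_stat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df),
              ifelse(abs(ma - mb) > 0, 0, 1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(reaction = shared, mean_a = ma, mean_b = mb, var_a = va,
             var_b = vb, t_stat = t_stat, df = df, p = p, p_adj = p_adj,
             significant = p_adj < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}
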