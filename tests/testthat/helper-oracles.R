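# Shared fixtures and independent brute-force oracles.

# ---- tiny fixtures ---------------------------------------------------------

# Linear chain: uptake (ub 10) -> A -> biomass drain.
chain_model <- function(ub_in = 10) {
  metabolic_model(
    data.frame(id = c("aC", "bC"), name = c("a", "b")),
    data.frame(id = c("EX_a", "R1", "BIO"),
               name = c("a uptake", "a to b", "growth"),
               lower_bound = 0, upper_bound = c(ub_in, 100, 100),
               is_exchange = c(TRUE, FALSE, FALSE)),
    list(EX_a = c(aC = 1), R1 = c(aC = -1, bC = 1), BIO = c(bC = -1)),
    biomass_id = "BIO")
}

# Branch point: A -> B and A -> C with separate drains.
branch_model <- function() {
  metabolic_model(
    data.frame(id = c("aC", "bC", "cC"), name = c("a", "b", "c")),
    data.frame(id = c("EX_a", "RB", "RC", "EX_b", "EX_c"),
               name = c("a in", "a to b", "a to c", "b out", "c out"),
               lower_bound = 0, upper_bound = c(10, 10, 10, 10, 10),
               is_exchange = c(TRUE, FALSE, FALSE, TRUE, TRUE)),
    list(EX_a = c(aC = 1), RB = c(aC = -1, bC = 1), RC = c(aC = -1, cC = 1),
         EX_b = c(bC = -1), EX_c = c(cC = -1)),
    biomass_id = "EX_b")
}

# Random small stoichiometric network with bounded fluxes; always feasible
# (v = 0 is admissible unless forced otherwise).
random_network <- function(seed, rev_frac = 0.3) {
  set.seed(seed)
  n <- sample(4:6, 1)
  m <- sample(2:4, 1)
  S <- matrix(sample(c(-2, -1, -1, 0, 0, 0, 0, 1, 1, 2), n * m,
                     replace = TRUE), m, n)
  lb <- ifelse(stats::runif(n) < rev_frac, -stats::runif(n, 0, 5), 0)
  ub <- stats::runif(n, 0.5, 10)
  cc <- stats::rnorm(n)
  list(S = S, lb = lb, ub = ub, cc = cc)
}

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(generate_toy_models())
    }
    cache
  }
})

toy_expression <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) {
      tm <- toy_fixture()
      cache <<- generate_expression_series(expression_spec(
        genes = tm$mb$genes,
        planted_up = tm$ground_truth$planted_up_genes,
        planted_down = tm$ground_truth$gimme_absent_genes), seed = seed)
    }
    cache
  }
})

compound_fixture <- function() {
  read_compound_table(system.file("extdata", "compounds_synthetic.tsv",
                                  package = "mbgem"))
}

# ---- independent oracles ---------------------------------------------------

# LP oracle: enumerate all basic solutions (vertices) of
# {S v = 0, lb <= v <= ub} and maximize c'v over them.
vertex_enum_lp <- function(S, lb, ub, cc, tol = 1e-9) {
  n <- ncol(S)
  qd <- qr(t(S))
  r <- qd$rank
  Sr <- matrix(S[qd$pivot[seq_len(r)], , drop = FALSE], nrow = r)
  best <- -Inf
  feasible <- FALSE
  basis_sets <- if (r == 0) list(integer(0)) else
    utils::combn(n, r, simplify = FALSE)
  for (B in basis_sets) {
    SB <- Sr[, B, drop = FALSE]
    if (r > 0 && abs(det(SB)) < 1e-10) next
    Nn <- setdiff(seq_len(n), B)
    grid <- if (length(Nn)) {
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(Nn))))
    } else matrix(FALSE, 1, 0)
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (length(Nn)) v[Nn] <- ifelse(grid[g, ], ub[Nn], lb[Nn])
      if (r > 0) {
        rhs <- -Sr[, Nn, drop = FALSE] %*% v[Nn]
        v[B] <- solve(SB, rhs)
      }
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        feasible <- TRUE
        best <- max(best, sum(cc * v))
      }
    }
  }
  if (!feasible) return(list(status = "infeasible"))
  list(status = "optimal", obj = best)
}

# Extreme rays of the cone {S v = 0, v >= 0}: supports whose submatrix has
# a one-dimensional, sign-definite null space.
extreme_rays <- function(S, tol = 1e-9) {
  n <- ncol(S)
  rays <- list()
  for (size in seq_len(n)) {
    for (T in utils::combn(n, size, simplify = FALSE)) {
      ST <- S[, T, drop = FALSE]
      ns <- MASS_null(ST)
      if (ncol(ns) != 1L) next
      w <- ns[, 1]
      if (all(w >= -tol)) w <- pmax(w, 0)
      else if (all(w <= tol)) w <- pmax(-w, 0)
      else next
      if (max(w) < tol) next
      v <- numeric(n)
      v[T] <- w / max(w)
      if (any(v[T] < tol)) next   # support must be exact (minimality)
      dup <- any(vapply(rays, function(r)
        max(abs(r - v / max(v))) < 1e-6, logical(1)))
      if (!dup) rays[[length(rays) + 1L]] <- v / max(v)
    }
  }
  rays
}

# base-only null space helper (orthonormal basis of null(A))
MASS_null <- function(A) {
  qd <- qr(t(A))
  n <- ncol(A)
  r <- qd$rank
  if (r >= n) return(matrix(0, n, 0))
  qr.Q(qd, complete = TRUE)[, (r + 1L):n, drop = FALSE]
}

# Coupling-class oracle for a pair (i, j) from the extreme rays of the cone.
ray_coupling_class <- function(rays, i, j, tol = 1e-9) {
  ri <- vapply(rays, function(r) r[i], numeric(1))
  rj <- vapply(rays, function(r) r[j], numeric(1))
  if (all(ri < tol) || all(rj < tol)) return("blocked")
  act_j <- rj > tol
  ratios <- ri[act_j] / rj[act_j]
  i_can_rest <- min(ratios) < tol
  act_i <- ri > tol
  ratios_ji <- rj[act_i] / ri[act_i]
  j_can_rest <- min(ratios_ji) < tol
  if (!i_can_rest && !j_can_rest) {
    hi <- if (any(act_i & rj < tol)) Inf else max(ratios)
    if (is.finite(hi) && (hi - min(ratios)) < 1e-6 * max(1, hi))
      "fully" else "partially"
  } else if (!j_can_rest) "directionally_i_to_j"
  else if (!i_can_rest) "directionally_j_to_i"
  else "uncoupled"
}
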