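# Internal linear-programming kernel.
#
# Bounded-variable two-phase revised simplex for
#     max  c'x   s.t.  A x = b,  lb <= x <= ub   (finite bounds).
#
# Written for this package because no functioning LP solver is available
# among the hard dependencies; validated against vertex enumeration in the
# test suite. Dense arithmetic: problems here are a few hundred variables.
# Dantzig pricing with a Bland's-rule fallback after a run of degenerate
# pivots; explicit basis inverse with product-form updates and periodic
# refactorization.

simplex_lp <- function(A, b, cc, lb, ub, tol = 1e-9, maxit = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("simplex_lp requires finite bounds")
  }
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible"))
  ub <- pmax(ub, lb)
  if (is.null(maxit)) maxit <- max(2000L, 200L * (m + n))

  # start each structural variable at its bound nearest zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  AA <- cbind(A, diag(sgn, m))
  lbA <- c(lb, rep(0, m)); ubA <- c(ub, rep(Inf, m))
  xA <- c(x, abs(r))
  basis <- (n + 1L):(n + m)
  at_lb <- c(abs(lb) <= abs(ub), rep(TRUE, m))
  Binv <- diag(1 / sgn, m)
  ntot <- n + m
  allow <- rep(TRUE, ntot)

  run_phase <- function(obj, xA, basis, at_lb, Binv, lbA, ubA, allow) {
    it <- 0L; degen <- 0L; bland <- FALSE
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(status = "maxit"))
      if (it %% 60L == 0L) {
        Binv <- tryCatch(solve(AA[, basis, drop = FALSE]),
                         error = function(e) NULL)
        if (is.null(Binv)) return(list(status = "singular"))
      }
      y <- crossprod(Binv, obj[basis])
      nb <- setdiff(seq_len(ntot), basis)
      nb <- nb[allow[nb]]
      zj <- obj[nb] - as.vector(crossprod(AA[, nb, drop = FALSE], y))
      viol <- ifelse(at_lb[nb], zj, -zj)
      cand <- which(viol > tol)
      if (!length(cand)) {
        return(list(status = "optimal", xA = xA, basis = basis,
                    at_lb = at_lb, Binv = Binv))
      }
      e <- if (bland) min(nb[cand]) else nb[cand[which.max(viol[cand])]]
      dirsign <- if (at_lb[e]) 1 else -1
      d <- as.vector(Binv %*% AA[, e]) * dirsign
      xB <- xA[basis]
      tmax <- ubA[e] - lbA[e]; leave <- 0L
      for (i in seq_len(m)) {
        if (d[i] > tol) {
          ti <- (xB[i] - lbA[basis[i]]) / d[i]
        } else if (d[i] < -tol) {
          ti <- (xB[i] - ubA[basis[i]]) / d[i]
        } else next
        if (ti < tmax - 1e-12 ||
            (ti < tmax + 1e-12 && leave != 0L && abs(d[i]) > abs(d[leave]))) {
          tmax <- ti; leave <- i
        }
      }
      if (!is.finite(tmax)) return(list(status = "unbounded"))
      if (tmax <= 1e-12) {
        degen <- degen + 1L
        if (degen > 2L * m + 20L) bland <- TRUE
      } else degen <- 0L
      tmax <- max(tmax, 0)
      xA[basis] <- xB - d * tmax
      xA[e] <- xA[e] + dirsign * tmax
      if (leave == 0L) { at_lb[e] <- !at_lb[e]; next }
      lv <- basis[leave]
      at_lb[lv] <- d[leave] > 0
      xA[lv] <- if (d[leave] > 0) lbA[lv] else ubA[lv]
      basis[leave] <- e
      col <- as.vector(Binv %*% AA[, e])
      piv <- col[leave]
      if (abs(piv) < 1e-11) {
        Binv <- tryCatch(solve(AA[, basis, drop = FALSE]),
                         error = function(e) NULL)
        if (is.null(Binv)) return(list(status = "singular"))
      } else {
        Brow <- Binv[leave, ] / piv
        Binv <- Binv - outer(col, Brow)
        Binv[leave, ] <- Brow
      }
    }
  }

  ph1 <- c(rep(0, n), rep(-1, m))
  res <- run_phase(ph1, xA, basis, at_lb, Binv, lbA, ubA, allow)
  if (res$status %in% c("singular", "maxit", "unbounded")) {
    return(list(status = "error", message = res$status))
  }
  if (sum(res$xA[(n + 1L):ntot]) > 1e-7 * (1 + max(abs(b), 0))) {
    return(list(status = "infeasible"))
  }
  ubA[(n + 1L):ntot] <- 0
  lbA[(n + 1L):ntot] <- 0
  res$xA[(n + 1L):ntot][res$xA[(n + 1L):ntot] < 1e-9] <- 0
  allow[(n + 1L):ntot] <- FALSE
  ph2 <- c(cc, rep(0, m))
  res <- run_phase(ph2, res$xA, res$basis, res$at_lb, res$Binv, lbA, ubA,
                   allow)
  if (res$status == "unbounded") return(list(status = "unbounded"))
  if (res$status %in% c("singular", "maxit")) {
    return(list(status = "error", message = res$status))
  }
  x <- res$xA[seq_len(n)]
  list(status = "optimal", x = x, obj = sum(cc * x))
}

# Solve max c'x over {A x = b, extra inequality rows G x <= h, bounds}.
# Inequalities are folded in with slack columns so the simplex core only
# sees equalities. Slack upper bounds are capped generously.
simplex_lp_ineq <- function(A, b, cc, lb, ub, G = NULL, h = NULL, ...) {
  if (is.null(G) || nrow(G) == 0L) return(simplex_lp(A, b, cc, lb, ub, ...))
  k <- nrow(G)
  slack_cap <- pmax(1e6, 10 * (abs(h) + sum(abs(ub)) + sum(abs(lb))))
  A2 <- rbind(cbind(A, matrix(0, nrow(A), k)), cbind(G, diag(k)))
  res <- simplex_lp(A2, c(b, h), c(cc, rep(0, k)),
                    c(lb, rep(0, k)), c(ub, slack_cap), ...)
  if (res$status == "optimal") res$x <- res$x[seq_along(cc)]
  res
}
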