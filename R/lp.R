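`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve a bounded linear program with equality constraints
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A %*% x == b` and
#' `lb <= x <= ub`, using a two-phase bounded-variable primal simplex with
#' Bland's anti-cycling rule. This is the kernel behind [solve_fba()]; it is
#' exposed so that flux problems outside the model container (and the test
#' suite) can reach it directly.
#'
#' Degeneracy is ubiquitous in flux balance problems, so pivot selection uses
#' Bland's rule throughout: slower than steepest-edge on large problems but
#' provably finite and deterministic, which makes repeated solves
#' bit-reproducible.
#'
#' @param A constraint matrix (m x n), dense numeric.
#' @param b right-hand side, length m.
#' @param obj objective coefficients, length n.
#' @param lb,ub variable bounds, length n; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize when `TRUE` (default).
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `objective` (numeric, `NA` unless optimal) and `x` (primal solution).
#' @export
solve_lp <- function(A, b, obj, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  if (m == 0L) {
    # box-constrained: pick the best bound per variable
    sgn <- if (maximize) 1 else -1
    x <- ifelse(sgn * obj > 0, ub, ifelse(sgn * obj < 0, lb, pmin(pmax(0, lb), ub)))
    if (any(!is.finite(x) & obj != 0)) return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }

  cc <- if (maximize) obj else -obj

  # start structural variables at the feasible point nearest zero
  x0 <- pmin(pmax(0, lb), ub)
  x0[lb == -Inf & ub == Inf] <- 0
  r <- b - as.vector(A %*% x0)
  art_sign <- ifelse(r >= 0, 1, -1)

  # augmented problem: n structural + m artificial columns
  Aa <- cbind(A, diag(art_sign, m, m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(Inf, m))
  x <- c(x0, abs(r))
  basis <- n + seq_len(m)

  run_phase <- function(cvec, x, basis, lbv, ubv, maxit = 20000L) {
    nt <- length(cvec)
    for (it in seq_len(maxit)) {
      B <- Aa[, basis, drop = FALSE]
      Blu <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Blu)) return(list(status = "singular"))
      y <- as.vector(t(Blu) %*% cvec[basis])
      nonbasic <- setdiff(seq_len(nt), basis)
      d <- cvec[nonbasic] - as.vector(y %*% Aa[, nonbasic, drop = FALSE])
      # Bland: smallest-index improving nonbasic variable
      can_up <- d > tol & x[nonbasic] < ubv[nonbasic] - tol
      can_dn <- d < -tol & x[nonbasic] > lbv[nonbasic] + tol
      cand <- nonbasic[can_up | can_dn]
      if (length(cand) == 0L)
        return(list(status = "optimal", x = x, basis = basis))
      j <- min(cand)
      up <- d[match(j, nonbasic)] > tol
      t_dir <- if (up) 1 else -1
      w <- as.vector(Blu %*% Aa[, j])
      # basic variables move as x_B - delta * t_dir * w
      xb <- x[basis]
      step_lim <- rep(Inf, m)
      dec <- t_dir * w > tol   # basic decreases toward its lower bound
      inc <- t_dir * w < -tol  # basic increases toward its upper bound
      step_lim[dec] <- (xb[dec] - lbv[basis][dec]) / (t_dir * w[dec])
      step_lim[inc] <- (ubv[basis][inc] - xb[inc]) / (-t_dir * w[inc])
      # entering variable's own travel limit (it may start between its bounds)
      own <- if (up) ubv[j] - x[j] else x[j] - lbv[j]
      delta <- min(step_lim, own)
      if (!is.finite(delta)) return(list(status = "unbounded"))
      if (own <= min(step_lim)) {
        x[j] <- x[j] + t_dir * delta
        x[basis] <- xb - delta * t_dir * w
      } else {
        hit <- which(step_lim <= delta + 1e-12)
        l <- hit[which.min(basis[hit])]  # Bland tie-break on variable index
        leave <- basis[l]
        x[basis] <- xb - delta * t_dir * w
        x[j] <- x[j] + t_dir * delta
        x[leave] <- if (dec[l]) lbv[leave] else ubv[leave]
        basis[l] <- j
      }
    }
    list(status = "maxiter")
  }

  # phase 1: drive artificial variables to zero
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, x, basis, lba, uba)
  if (!identical(p1$status, "optimal"))
    stop("LP phase-1 failure: ", p1$status)
  if (sum(p1$x[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))

  # phase 2: freeze artificials at zero, optimize the true objective
  uba2 <- c(ub, rep(0, m))
  x2 <- p1$x
  x2[n + seq_len(m)] <- 0
  p2 <- run_phase(c(cc, rep(0, m)), x2, p1$basis, lba, uba2)
  if (identical(p2$status, "unbounded"))
    return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
  if (!identical(p2$status, "optimal"))
    stop("LP phase-2 failure: ", p2$status)
  xs <- p2$x[seq_len(n)]
  xs <- pmin(pmax(xs, lb), ub)
  list(status = "optimal", objective = sum(obj * xs), x = xs)
}

#' Brute-force LP optimum by basic-solution enumeration
#'
#' Independent reference for [solve_lp()] on small problems: enumerates every
#' basic solution of `{A x = b, lb <= x <= ub}` (all choices of n - m
#' variables fixed at a bound, the rest solved from the square system) and
#' returns the best feasible objective. Exponential in n - m; intended for
#' networks of at most ~10 reactions. Requires finite bounds.
#'
#' @inheritParams solve_lp
#' @return list with `status` ("optimal" or "infeasible") and `objective`.
#' @export
enumerate_lp_optimum <- function(A, b, obj, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  Afull <- A; bfull <- b
  # reduce to an independent row set; candidates are re-checked on the full system
  qrt <- qr(t(A))
  keep <- sort(qrt$pivot[seq_len(qrt$rank)])
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), n >= m)
  sgn <- if (maximize) 1 else -1
  best <- -Inf
  fixed_sets <- utils::combn(n, n - m, simplify = FALSE)
  if (n == m) fixed_sets <- list(integer(0))
  for (fixed in fixed_sets) {
    free <- setdiff(seq_len(n), fixed)
    Af <- A[, free, drop = FALSE]
    if (length(free) > 0 && abs(det(Af)) < 1e-12) next
    n_fix <- length(fixed)
    picks <- if (n_fix > 0) expand.grid(rep(list(c(FALSE, TRUE)), n_fix)) else data.frame(row.names = 1)
    for (g in seq_len(nrow(picks))) {
      vfix <- ifelse(unlist(picks[g, ]), ub[fixed], lb[fixed])
      rhs <- b - if (n_fix > 0) as.vector(A[, fixed, drop = FALSE] %*% vfix) else b * 0
      vfree <- if (length(free) > 0) as.vector(solve(Af, rhs)) else numeric(0)
      if (length(free) > 0 &&
          (any(vfree < lb[free] - 1e-8) || any(vfree > ub[free] + 1e-8))) next
      if (length(free) == 0 && any(abs(rhs) > 1e-8)) next
      xc <- numeric(n); xc[fixed] <- vfix; xc[free] <- vfree
      if (max(abs(Afull %*% xc - bfull)) > 1e-8) next
      val <- sum(obj[fixed] * vfix) + sum(obj[free] * vfree)
      if (sgn * val > sgn * best || !is.finite(best)) best <- val
    }
  }
  if (!is.finite(best)) return(list(status = "infeasible", objective = NA_real_))
  list(status = "optimal", objective = best)
}
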