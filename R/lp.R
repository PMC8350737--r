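# Linear programming layer.
#
# No simplex LP package ships with this package's dependency set, so LPs
# are solved by a proximal-point scheme built on quadprog's dual-method QP
# solver: iterate
#     x_{k+1} = argmin_{x in C} (eps/2) ||x - x_k||^2 - c'x
# over the LP's constraint set C. Each subproblem is a strictly convex,
# well-conditioned QP; for polyhedral C the iteration reaches a point
# satisfying -c in the normal cone of C in finitely many steps, i.e. an
# exact LP optimum (Rockafellar's proximal point method on polyhedral
# functions). All variables are box-bounded, so the LP is never unbounded
# and the iteration always terminates. Redundant equality rows (e.g.
# paired conserved-moiety rows of a stoichiometric matrix) are removed by
# QR factorization, as quadprog requires independent equality constraints.

#' Solve a box-bounded linear program
#'
#' Solves `max/min c'x` subject to `A x <= b`, `Aeq x = beq` and
#' `lb <= x <= ub` (all bounds finite).
#'
#' @param obj numeric objective coefficients.
#' @param A,b inequality constraints `A x <= b` (may be `NULL`).
#' @param Aeq,beq equality constraints (may be `NULL`).
#' @param lb,ub finite variable bounds.
#' @param maximize logical; maximize instead of minimize.
#' @param eps proximal regularization weight.
#' @param max_prox iteration cap for the proximal loop.
#' @return list with `x` (solution), `objval`, `feasible` (logical) and
#'   `message`.
#' @keywords internal
lp_solve <- function(obj, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                     lb, ub, maximize = FALSE, eps = 1e-4,
                     max_prox = 200L) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (!all(is.finite(lb)) || !all(is.finite(ub))) {
    stop_zf("lp_solve requires finite variable bounds", "zf_lp_bounds")
  }
  fail <- function(msg) list(x = rep(NA_real_, n), objval = NA_real_,
                             feasible = FALSE, message = msg)
  if (any(lb > ub + 1e-9)) return(fail("inconsistent bounds (lb > ub)"))

  d <- if (maximize) obj else -obj
  dscale <- max(1, abs(d))
  d <- d / dscale

  if (!is.null(Aeq)) {
    Aeq <- as.matrix(Aeq)
    qrt <- qr(t(Aeq))
    keep <- sort(qrt$pivot[seq_len(qrt$rank)])
    Aeq_k <- Aeq[keep, , drop = FALSE]
    beq_k <- beq[keep]
  } else {
    Aeq_k <- NULL
    beq_k <- numeric(0)
  }

  # quadprog form: min 1/2 x'Dx - dvec'x, Amat' x >= bvec (first meq equal)
  Amat <- NULL
  bvec <- NULL
  if (!is.null(Aeq_k) && nrow(Aeq_k)) {
    Amat <- t(Aeq_k)
    bvec <- beq_k
  }
  meq <- length(beq_k)
  if (!is.null(A)) {
    Amat <- cbind(Amat, -t(as.matrix(A)))
    bvec <- c(bvec, -b)
  }
  Amat <- cbind(Amat, diag(n), -diag(n))
  bvec <- c(bvec, lb, -ub)

  xc <- pmin(pmax(numeric(n), lb), ub)  # proximal center
  x <- NULL
  for (k in seq_len(max_prox)) {
    sol <- NULL
    eps_k <- eps
    for (try_k in 1:4) {
      sol <- tryCatch(
        quadprog::solve.QP(Dmat = diag(eps_k, n), dvec = d + eps_k * xc,
                           Amat = Amat, bvec = bvec, meq = meq),
        error = function(e) NULL
      )
      if (!is.null(sol)) break
      eps_k <- eps_k * 100
    }
    if (is.null(sol)) {
      return(fail(if (is.null(x)) "QP subproblem failed (likely infeasible LP)"
                  else "QP subproblem failed mid-iteration"))
    }
    x <- sol$solution
    move <- sqrt(sum((x - xc)^2))
    xc <- x
    if (move < 1e-8 * max(1, sqrt(sum(x^2)))) break
  }
  x <- pmin(pmax(x, lb), ub)
  if (!is.null(Aeq) && length(beq) && max(abs(Aeq %*% x - beq)) > 1e-6) {
    return(fail("equality constraints violated (inconsistent system)"))
  }
  if (!is.null(A) && length(b) && max(A %*% x - b) > 1e-6) {
    return(fail("inequality constraints violated"))
  }
  list(x = x, objval = sum(obj * x), feasible = TRUE, message = "ok")
}
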