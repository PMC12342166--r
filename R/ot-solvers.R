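#' Solver configuration for the entropic OT family
#'
#' @param eta entropic regularization strength (> 0). The entropy used is
#'   \eqn{H(T) = -\sum_{ij} T_{ij} (\log T_{ij} - 1)}, so the 1x1 robust plan
#'   has the closed form \eqn{\exp(-c / (\eta + 2\varepsilon))}.
#' @param epsilon marginal (KL) relaxation strength for robust OT (> 0).
#' @param s transport budget for partial OT; `NULL` unless partial OT is used.
#' @param tol convergence tolerance, measured in L1 on marginal violations
#'   (balanced) or on the change of the plan/marginals between sweeps
#'   (unbalanced, partial); for partial OT it is relative to the transported
#'   mass when the budget exceeds 1.
#' @param max_iter iteration cap; non-convergence returns a plan flagged
#'   `converged = FALSE` with a warning.
#' @return a `solver_config` list.
#' @export
solver_config <- function(eta = 1e-2, epsilon = 1, s = NULL, tol = 1e-9,
                          max_iter = 10000L) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0)
    abort_invalid("`eta` must be a positive number")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0)
    abort_invalid("`epsilon` must be a positive number")
  if (!is.null(s) && (!is.numeric(s) || length(s) != 1L || s < 0))
    abort_invalid("`s` must be NULL or a nonnegative number")
  if (!is.numeric(tol) || tol <= 0) abort_invalid("`tol` must be positive")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    abort_invalid("`max_iter` must be a positive integer")
  structure(list(eta = eta, epsilon = epsilon, s = s, tol = tol,
                 max_iter = max_iter),
            class = "solver_config")
}

# strip zero-mass rows/columns, run `fun` on the positive submatrix, and
# reinsert structural zero rows/columns in the returned plan
solve_on_support <- function(C, a, b, fun) {
  ia <- which(a > 0)
  ib <- which(b > 0)
  res <- fun(C[ia, ib, drop = FALSE], a[ia], b[ib])
  plan <- matrix(0, nrow(C), ncol(C))
  plan[ia, ib] <- res$plan
  res$plan <- plan
  res
}

finish_plan <- function(res, C, method) {
  if (!res$converged)
    warn_dotgrn(sprintf("%s did not converge within %d iterations", method,
                        res$iterations))
  new_transport_plan(res$plan, res$converged, res$iterations,
                     objective = sum(C * res$plan), method = method)
}

#' Entropic (balanced) optimal transport via Sinkhorn scaling
#'
#' Minimizes \eqn{\langle C, T\rangle - \eta H(T)} subject to both marginal
#' constraints. Runs diagonal Sinkhorn scaling, switching automatically to a
#' log-domain implementation when the Gibbs kernel \eqn{e^{-C/\eta}} would
#' underflow.
#'
#' @inheritParams solve_exact_ot
#' @param cfg a [solver_config()]; `cfg$eta` and `cfg$tol` are used, with
#'   `cfg$tol` bounding \eqn{\|T1 - a\|_1} at convergence.
#' @return a [transport_plan].
#' @export
solve_entropic_ot <- function(C, a, b, cfg = solver_config()) {
  check_ot_inputs(C, a, b)
  if (abs(sum(a) - sum(b)) > 1e-9 * max(1, sum(a)))
    abort_invalid(sprintf(
      "total masses differ (%.10g vs %.10g); balanced OT requires equality",
      sum(a), sum(b)))
  res <- solve_on_support(C, a, b, function(Cs, as, bs) {
    ot_sinkhorn_cpp(Cs, as, bs, cfg$eta, cfg$tol, cfg$max_iter)
  })
  finish_plan(res, C, "sinkhorn")
}

#' Robust (unbalanced) optimal transport via unbalanced Sinkhorn-Knopp
#'
#' Minimizes \eqn{\langle C, T\rangle - \eta H(T) + \varepsilon KL(T1\|a) +
#' \varepsilon KL(T^\top 1\|b)} by the damped fixed-point iteration with
#' scaling exponent \eqn{\varepsilon/(\varepsilon+\eta)}. Mass vectors need
#' not balance; the transported mass may fall below
#' \eqn{\min(\|a\|_1, \|b\|_1)}. As \eqn{\varepsilon \to \infty} the solution
#' approaches the balanced entropic plan.
#'
#' @inheritParams solve_entropic_ot
#' @return a [transport_plan].
#' @export
solve_robust_ot <- function(C, a, b, cfg = solver_config()) {
  check_numeric_matrix(C)
  if (any(C < 0)) abort_invalid("cost matrix must be nonnegative")
  if (!is.numeric(a) || !is.numeric(b) || any(a < 0) || any(b < 0) ||
      any(!is.finite(a)) || any(!is.finite(b)))
    abort_invalid("mass vectors must be finite and nonnegative")
  if (nrow(C) != length(a) || ncol(C) != length(b))
    abort_invalid("cost matrix dimensions do not match mass vectors")
  # KL(.||0) forces the corresponding marginal to zero; all-zero mass on
  # either side therefore yields the zero plan
  if (sum(a) == 0 || sum(b) == 0) {
    return(new_transport_plan(matrix(0, nrow(C), ncol(C)), TRUE, 0L, 0,
                              method = "unbalanced_sinkhorn"))
  }
  res <- solve_on_support(C, a, b, function(Cs, as, bs) {
    ot_usinkhorn_cpp(Cs, as, bs, cfg$eta, cfg$epsilon, cfg$tol, cfg$max_iter)
  })
  finish_plan(res, C, "unbalanced_sinkhorn")
}

#' Entropic partial optimal transport via Dykstra projections
#'
#' Computes the entropy-regularized partial plan with row/column capacity
#' constraints \eqn{T1 \le a}, \eqn{T^\top 1 \le b} and equality transport
#' budget \eqn{1^\top T 1 = s}, by iterated KL-Bregman (Dykstra) projections
#' onto the three constraint sets in the log domain. With small `eta` and
#' unit masses the plan concentrates on a pseudo-permutation matching.
#'
#' @inheritParams solve_entropic_ot
#' @param cfg a [solver_config()] whose `s` holds the budget,
#'   `0 <= s <= min(sum(a), sum(b))`.
#' @return a [transport_plan].
#' @export
solve_partial_ot <- function(C, a, b, cfg = solver_config()) {
  check_ot_inputs(C, a, b)
  s <- cfg$s
  if (is.null(s)) abort_invalid("partial OT requires a budget `s` in the config")
  smax <- min(sum(a), sum(b))
  if (s < 0 || s > smax + 1e-9 * max(1, smax))
    abort_invalid(sprintf("budget s = %.6g outside [0, %.6g]", s, smax))
  if (s == 0) {
    return(new_transport_plan(matrix(0, nrow(C), ncol(C)), TRUE, 0L, 0,
                              method = "partial_dykstra"))
  }
  res <- solve_on_support(C, a, b, function(Cs, as, bs) {
    ot_partial_dykstra_cpp(Cs, as, bs, cfg$eta, min(s, min(sum(as), sum(bs))),
                           cfg$tol, cfg$max_iter)
  })
  finish_plan(res, C, "partial_dykstra")
}
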