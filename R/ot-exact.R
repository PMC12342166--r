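#' Transport plan objects
#'
#' Solvers in dotgrn return a `transport_plan`: the nonnegative plan matrix
#' together with solver metadata (convergence flag, iteration count, and the
#' linear transport cost of the returned plan).
#'
#' @param x a `transport_plan`.
#' @param ... ignored.
#' @name transport_plan
NULL

new_transport_plan <- function(plan, converged, iterations, objective, method) {
  structure(
    list(plan = plan, converged = converged, iterations = as.integer(iterations),
         objective = objective, method = method),
    class = "transport_plan"
  )
}

#' @rdname transport_plan
#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("<transport_plan: %s, %d x %d>\n", x$method,
              nrow(x$plan), ncol(x$plan)))
  cat(sprintf("  transported mass %.6g, cost %.6g, %d iterations, %s\n",
              sum(x$plan), x$objective, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

plan_matrix <- function(T) {
  if (inherits(T, "transport_plan")) T$plan else T
}

check_ot_inputs <- function(C, a, b) {
  check_numeric_matrix(C)
  if (any(C < 0)) abort_invalid("cost matrix must be nonnegative")
  check_mass_vector(a, "a")
  check_mass_vector(b, "b")
  if (nrow(C) != length(a) || ncol(C) != length(b))
    abort_invalid(sprintf(
      "cost matrix is %d x %d but mass vectors have lengths %d and %d",
      nrow(C), ncol(C), length(a), length(b)))
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Exact balanced OT by the transportation simplex (north-west corner start,
# MODI/u-v pivoting on the basis tree). Intended as a small-instance oracle;
# no LP package is assumed.
# ---------------------------------------------------------------------------

transport_simplex <- function(C, a, b) {
  n <- nrow(C); m <- ncol(C)
  if (n == 1L) {
    return(list(plan = matrix(b, 1L, m), pivots = 0L))
  }
  if (m == 1L) {
    return(list(plan = matrix(a, n, 1L), pivots = 0L))
  }

  # north-west corner initial basis: exactly n + m - 1 basic cells
  flow <- matrix(0, n, m)
  basis <- matrix(FALSE, n, m)
  ra <- a; rb <- b
  i <- 1L; j <- 1L
  repeat {
    t0 <- min(ra[i], rb[j])
    flow[i, j] <- t0
    basis[i, j] <- TRUE
    ra[i] <- ra[i] - t0
    rb[j] <- rb[j] - t0
    if (i == n && j == m) break
    if (i < n && (ra[i] <= rb[j] || j == m)) i <- i + 1L else j <- j + 1L
  }

  tol_opt <- 1e-10 * (1 + max(abs(C)))
  max_pivots <- 2000L * (n + m)
  pivots <- 0L

  repeat {
    bc <- which(basis)
    bi <- (bc - 1L) %% n + 1L
    bj <- (bc - 1L) %/% n + 1L

    # dual variables from the basis spanning tree
    u <- rep(NA_real_, n); v <- rep(NA_real_, m)
    u[1L] <- 0
    repeat {
      progressed <- FALSE
      for (k in seq_along(bc)) {
        ui <- u[bi[k]]; vj <- v[bj[k]]
        if (!is.na(ui) && is.na(vj)) {
          v[bj[k]] <- C[bc[k]] - ui; progressed <- TRUE
        } else if (is.na(ui) && !is.na(vj)) {
          u[bi[k]] <- C[bc[k]] - vj; progressed <- TRUE
        }
      }
      if (!progressed) break
    }
    if (anyNA(u) || anyNA(v))
      abort_solver("transportation simplex: basis is not a spanning tree")

    rc <- C - outer(u, rep(1, m)) - matrix(v, n, m, byrow = TRUE)
    rc[basis] <- 0
    if (min(rc) >= -tol_opt) break

    ent <- which(rc == min(rc))[1L]
    ei <- (ent - 1L) %% n + 1L
    ej <- (ent - 1L) %/% n + 1L

    # unique path row-node ei -> col-node ej through the basis tree
    # nodes: 1..n rows, n+1..n+m columns
    parent <- integer(n + m); parent_cell <- integer(n + m)
    seen <- logical(n + m)
    queue <- ei; seen[ei] <- TRUE
    while (length(queue) > 0L && !seen[n + ej]) {
      node <- queue[1L]; queue <- queue[-1L]
      if (node <= n) {
        hits <- which(bi == node)
        nbr <- n + bj[hits]
      } else {
        hits <- which(bj == node - n)
        nbr <- bi[hits]
      }
      new <- !seen[nbr]
      seen[nbr[new]] <- TRUE
      parent[nbr[new]] <- node
      parent_cell[nbr[new]] <- bc[hits[new]]
      queue <- c(queue, nbr[new])
    }
    if (!seen[n + ej])
      abort_solver("transportation simplex: basis tree disconnected")

    # cycle cells: entering cell first, then basis cells walking back ej -> ei
    cyc <- ent
    node <- n + ej
    while (node != ei) {
      cyc <- c(cyc, parent_cell[node])
      node <- parent[node]
    }
    minus <- cyc[seq(2L, length(cyc), by = 2L)]
    plus <- cyc[seq(1L, length(cyc), by = 2L)]
    theta <- min(flow[minus])
    leave <- minus[which.min(flow[minus])]

    flow[plus] <- flow[plus] + theta
    flow[minus] <- flow[minus] - theta
    flow[leave] <- 0
    basis[leave] <- FALSE
    basis[ent] <- TRUE

    pivots <- pivots + 1L
    if (pivots > max_pivots)
      abort_solver("transportation simplex failed to terminate (cycling?)")
  }

  list(plan = flow, pivots = pivots)
}

#' Exact optimal transport (linear-programming oracle)
#'
#' Solves the Kantorovich OT problem
#' \deqn{\min_{T \ge 0} \langle C, T\rangle \quad s.t.\; T 1 = a,\; T^\top 1 = b}
#' exactly by the transportation simplex. Intended for small instances
#' (roughly `n1 * n2 <= 1e4`), primarily as a ground-truth oracle for the
#' scalable entropic solvers.
#'
#' @param C nonnegative cost matrix (`n1 x n2`).
#' @param a,b nonnegative mass vectors with equal total mass.
#' @return a [transport_plan] with exact marginals and minimal cost.
#' @seealso [solve_entropic_ot()], [solve_exact_partial_ot()]
#' @export
solve_exact_ot <- function(C, a, b) {
  check_ot_inputs(C, a, b)
  if (abs(sum(a) - sum(b)) > 1e-9 * max(1, sum(a)))
    abort_invalid(sprintf(
      "total masses differ (%.10g vs %.10g); balanced OT requires equality",
      sum(a), sum(b)))
  res <- transport_simplex(C, a, b)
  new_transport_plan(res$plan, converged = TRUE, iterations = res$pivots,
                     objective = sum(C * res$plan), method = "exact_lp")
}

#' Exact partial optimal transport (linear-programming oracle)
#'
#' Solves partial OT with an equality transport budget:
#' \deqn{\min_{T \ge 0} \langle C, T\rangle \quad s.t.\; T1 \le a,\;
#'   T^\top 1 \le b,\; 1^\top T 1 = s,}
#' by the classical reduction to balanced OT with one dummy source and one
#' dummy sink (zero cost to the dummies, a large dummy-dummy cost). With
#' `a = 1_n`, `b = 1_m` and integer `s` the optimal vertex is a 0-1
#' pseudo-permutation matrix with exactly `s` ones.
#'
#' @inheritParams solve_exact_ot
#' @param s transport budget, `0 <= s <= min(sum(a), sum(b))`.
#' @return a [transport_plan].
#' @export
solve_exact_partial_ot <- function(C, a, b, s) {
  check_ot_inputs(C, a, b)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s))
    abort_invalid("`s` must be a single finite number")
  smax <- min(sum(a), sum(b))
  if (s < -1e-12 || s > smax + 1e-9 * max(1, smax))
    abort_invalid(sprintf("budget s = %.6g outside [0, %.6g]", s, smax))
  s <- min(max(s, 0), smax)
  if (s == 0) {
    return(new_transport_plan(matrix(0, nrow(C), ncol(C)), TRUE, 0L, 0,
                              method = "exact_partial_lp"))
  }
  big <- 2 * max(C) + 1
  C2 <- rbind(cbind(C, 0), c(rep(0, ncol(C)), big))
  a2 <- c(a, sum(b) - s)
  b2 <- c(b, sum(a) - s)
  res <- transport_simplex(C2, a2, b2)
  plan <- res$plan[seq_len(nrow(C)), seq_len(ncol(C)), drop = FALSE]
  new_transport_plan(plan, converged = TRUE, iterations = res$pivots,
                     objective = sum(C * plan), method = "exact_partial_lp")
}

#' Generalized Kullback-Leibler divergence between mass vectors
#'
#' \eqn{KL(u \| v) = \sum_i u_i \log(u_i/v_i) - u_i + v_i} with the convention
#' \eqn{0 \log 0 = 0}. Nonnegative, zero iff `u == v`; returns `Inf` when some
#' `u_i > 0` has `v_i = 0`.
#'
#' @param u,v nonnegative numeric vectors of equal length.
#' @return a nonnegative scalar (possibly `Inf`).
#' @export
kl_divergence <- function(u, v) {
  if (!is.numeric(u) || !is.numeric(v) || length(u) != length(v))
    abort_invalid("`u` and `v` must be numeric vectors of equal length")
  if (any(u < 0) || any(v < 0))
    abort_invalid("`u` and `v` must be nonnegative")
  if (any(u > 0 & v == 0)) return(Inf)
  pos <- u > 0
  sum(u[pos] * log(u[pos] / v[pos]) - u[pos] + v[pos]) + sum(v[!pos])
}

#' Unregularized robust OT objective
#'
#' Evaluates \eqn{\langle C, T\rangle + \varepsilon KL(T1 \| a) +
#' \varepsilon KL(T^\top 1 \| b)} for a given plan; used for diagnostics and
#' for monotonicity checks of the unbalanced solver.
#'
#' @inheritParams solve_exact_ot
#' @param T a plan matrix or [transport_plan].
#' @param epsilon marginal relaxation strength (>= 0).
#' @return a scalar.
#' @export
robust_objective <- function(C, T, a, b, epsilon) {
  T <- plan_matrix(T)
  check_numeric_matrix(T, "T")
  if (nrow(T) != nrow(C) || ncol(T) != ncol(C))
    abort_invalid("plan and cost matrix dimensions differ")
  sum(C * T) +
    epsilon * kl_divergence(rowSums(T), a) +
    epsilon * kl_divergence(colSums(T), b)
}
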