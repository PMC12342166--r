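# Independent test oracles: brute-force LP by basic-solution enumeration and
# exhaustive ranking metrics. These never call the solver paths they check.

# minimal-cost balanced transport by enumerating all basic solutions
# (choose n1 + n2 - 1 cells, solve the marginal equations, keep feasible ones);
# only for tiny instances
bf_exact_ot_objective <- function(C, a, b) {
  n <- nrow(C); m <- ncol(C)
  cells_i <- rep(seq_len(n), times = m)
  cells_j <- rep(seq_len(m), each = n)
  nb <- n + m - 1L
  combs <- utils::combn(n * m, nb)
  best <- Inf
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    A <- matrix(0, n + m, nb)
    for (t in seq_along(idx)) {
      A[cells_i[idx[t]], t] <- 1
      A[n + cells_j[idx[t]], t] <- 1
    }
    sol <- tryCatch(solve(A[-(n + m), , drop = FALSE], c(a, b)[-(n + m)]),
                    error = function(e) NULL)
    if (is.null(sol) || any(sol < -1e-9)) next
    if (abs(sum(sol[cells_j[idx] == m]) - b[m]) > 1e-8) next
    obj <- sum(C[cbind(cells_i[idx], cells_j[idx])] * sol)
    best <- min(best, obj)
  }
  best
}

# brute-force partial OT through the textbook dummy-node reduction, solved by
# the enumeration oracle above (re-derived here, independent of the package)
bf_exact_partial_objective <- function(C, a, b, s) {
  if (s <= 0) return(0)
  big <- 2 * max(C) + 1
  C2 <- rbind(cbind(C, 0), c(rep(0, ncol(C)), big))
  bf_exact_ot_objective(C2, c(a, sum(b) - s), c(b, sum(a) - s))
}

# pairwise-comparison AUROC: P(score_pos > score_neg) + 0.5 P(tie)
bf_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (sp in pos) tot <- tot + sum(sp > neg) + 0.5 * sum(sp == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive threshold enumeration, step-wise precision-recall summation
bf_aupr <- function(scores, labels) {
  K <- sum(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0; r_prev <- 0
  for (t in thr) {
    sel <- scores >= t
    p <- sum(labels[sel]) / sum(sel)
    r <- sum(labels[sel]) / K
    area <- area + (r - r_prev) * p
    r_prev <- r
  }
  area
}

bf_early_precision <- function(scores, labels, reg_idx, tgt_idx) {
  K <- sum(labels)
  ord <- order(-scores, reg_idx, tgt_idx)
  sum(labels[ord][seq_len(K)]) / K
}

# random balanced OT instance with probability-mass marginals
random_ot_instance <- function(n1, n2) {
  C <- matrix(stats::runif(n1 * n2), n1, n2)
  a <- stats::runif(n1); a <- a / sum(a)
  b <- stats::runif(n2); b <- b / sum(b)
  list(C = C, a = a, b = b)
}

expr_matrix <- function(values, p, k, genes = sprintf("g%d", seq_len(p)),
                        samples = sprintf("s%d", seq_len(k))) {
  matrix(values, p, k, dimnames = list(genes, samples))
}

with_seed_matrix <- function(seed, p, genes) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(stats::runif(p * p), p, p, dimnames = list(genes, genes))
}
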