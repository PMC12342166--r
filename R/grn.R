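#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive mid-ranks).
#' Constant vectors yield 0 with a warning rather than `NA`, so that a flat
#' gene contributes the maximal transport cost instead of failing.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return a scalar in `[-1, 1]`.
#' @export
spearman_corr <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    abort_invalid("`x` and `y` must be numeric vectors of equal length")
  if (length(x) < 3L)
    abort_invalid("Spearman correlation requires at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warn_dotgrn("constant vector in Spearman correlation; returning 0")
    return(0)
  }
  stats::cor(rx, ry)
}

#' Gene-gene transport cost from paired expression
#'
#' For aligned matrices sharing genes and sample count, the cost of moving
#' expression mass from normal gene i to tumor gene j is
#' \eqn{C_{ij} = 1 - |r(x_{(i)}, y_{(j)})|}, with r the Spearman correlation
#' between row i of `X` and row j of `Y`. Constant rows get zero correlation
#' (cost 1) with a warning naming the genes.
#'
#' @param X,Y expression matrices (genes x samples) with identical gene order
#'   and equal sample counts.
#' @return a `p x p` cost matrix with entries in `[0, 1]`.
#' @export
gene_cost_matrix <- function(X, Y) {
  X <- as_expression_matrix(X, "X"); Y <- as_expression_matrix(Y, "Y")
  check_shared_genes(X, Y)
  if (ncol(X) != ncol(Y))
    abort_invalid("X and Y must have equal sample counts (paired/aligned)")
  if (ncol(X) < 3L)
    abort_invalid("Spearman costs require at least 3 paired samples")
  RX <- t(apply(X, 1L, rank))
  RY <- t(apply(Y, 1L, rank))
  flat_x <- apply(RX, 1L, stats::sd) == 0
  flat_y <- apply(RY, 1L, stats::sd) == 0
  if (any(flat_x) || any(flat_y))
    warn_dotgrn(sprintf(
      "constant expression rows treated as zero-correlation: %s",
      paste(unique(rownames(X)[flat_x | flat_y]), collapse = ", ")))
  R <- suppressWarnings(stats::cor(t(RX), t(RY)))
  R[!is.finite(R)] <- 0
  C <- 1 - abs(R)
  C[C < 0] <- 0
  C[C > 1] <- 1
  dimnames(C) <- list(rownames(X), rownames(Y))
  C
}

#' Gene-level OT marginals
#'
#' Per-gene mean expression over the aligned samples, `a = X 1_s / s` and
#' `b = Y 1_s / s`. By default both are normalized to expression proportions
#' summing to 1, which keeps the scale of the marginal relaxation `epsilon`
#' independent of the data's units; set `normalize = FALSE` for raw row means.
#'
#' @inheritParams gene_cost_matrix
#' @param normalize normalize each marginal to total mass 1 (default).
#' @return a list with mass vectors `a` and `b`.
#' @export
gene_marginals <- function(X, Y, normalize = TRUE) {
  X <- as_expression_matrix(X, "X"); Y <- as_expression_matrix(Y, "Y")
  a <- rowMeans(X); b <- rowMeans(Y)
  if (sum(a) <= 0 || sum(b) <= 0)
    abort_invalid("all-zero expression matrix has no mass to transport")
  if (normalize) {
    a <- a / sum(a); b <- b / sum(b)
  }
  list(a = a, b = b)
}

#' Joint PCA projection of samples
#'
#' Stacks the `n + m` samples of both conditions as points in gene space,
#' centers them jointly, and projects onto the top-`r` right-singular
#' directions of the centered joint matrix. The sign of each component is
#' fixed by making its largest-magnitude gene loading positive, so the
#' projection is deterministic.
#'
#' @inheritParams gene_cost_matrix
#' @param r number of principal components, at most `min(p, n + m - 1)`.
#' @return a list with `X_proj` (`n x r`) and `Y_proj` (`m x r`).
#' @export
project_samples <- function(X, Y, r) {
  X <- as_expression_matrix(X, "X"); Y <- as_expression_matrix(Y, "Y")
  check_shared_genes(X, Y)
  n <- ncol(X); m <- ncol(Y); p <- nrow(X)
  r <- as.integer(r)
  if (is.na(r) || r < 1L || r > min(p, n + m - 1L))
    abort_invalid(sprintf("`r` must be in [1, %d]", min(p, n + m - 1L)))
  Z <- t(cbind(X, Y))                       # samples x genes
  Z <- scale(Z, center = TRUE, scale = FALSE)
  sv <- svd(Z, nu = 0, nv = r)
  V <- sv$v[, seq_len(r), drop = FALSE]
  flip <- apply(V, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  V <- sweep(V, 2L, flip, `*`)
  S <- Z %*% V
  list(X_proj = S[seq_len(n), , drop = FALSE],
       Y_proj = S[n + seq_len(m), , drop = FALSE])
}

#' Sample-sample transport cost (cosine distance in PC space)
#'
#' \eqn{C_{ij} = 1 - \cos(\tilde x_i, \tilde y_j)} where the tilded vectors
#' are the joint-PCA projections from [project_samples()]. Entries lie in
#' `[0, 2]`; a projected vector of length zero gets cost 1 (orthogonality
#' convention) with a warning.
#'
#' @inheritParams project_samples
#' @return an `n x m` cost matrix.
#' @export
sample_cost_matrix <- function(X, Y, r) {
  pr <- project_samples(X, Y, r)
  nx <- sqrt(rowSums(pr$X_proj^2))
  ny <- sqrt(rowSums(pr$Y_proj^2))
  zx <- nx == 0; zy <- ny == 0
  if (any(zx) || any(zy))
    warn_dotgrn("zero projected sample vector(s); using orthogonality cost 1")
  nx[zx] <- 1; ny[zy] <- 1
  cosim <- (pr$X_proj %*% t(pr$Y_proj)) / outer(nx, ny)
  cosim[zx, ] <- 0
  cosim[, zy] <- 0
  C <- 1 - cosim
  C[C < 0] <- 0
  C[C > 2] <- 2
  dimnames(C) <- list(colnames(X), colnames(Y))
  C
}

#' Alignment configuration for unpaired samples
#'
#' @param r number of principal components used for the sample cost;
#'   `NULL` resolves to `min(50, n + m - 1, p)`. When per-sample variation is
#'   spread isotropically across genes, the matching signal occupies many
#'   components, so a generous default is safer than a sharp truncation.
#' @param s matching budget: a count of pairs when `s >= 1`, or a fraction
#'   of `min(n, m)` when `s < 1`. Defaults to 0.8, matching only the most
#'   confident subset of samples; pass `s = min(n, m)` to match everything.
#' @return an `alignment_config` list.
#' @export
alignment_config <- function(r = NULL, s = 0.8) {
  if (!is.null(r) && (!is.numeric(r) || length(r) != 1L || r < 1))
    abort_invalid("`r` must be NULL or a positive integer")
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    abort_invalid("`s` must be a positive count or a fraction below 1")
  structure(list(r = if (is.null(r)) NULL else as.integer(r), s = s),
            class = "alignment_config")
}

resolve_alignment <- function(cfg, p, n, m) {
  r <- cfg$r %||% min(50L, n + m - 1L, p)
  if (r > min(p, n + m - 1L))
    abort_invalid(sprintf("`r` = %d exceeds min(p, n + m - 1) = %d", r,
                          min(p, n + m - 1L)))
  s <- if (cfg$s < 1) max(1L, floor(cfg$s * min(n, m))) else as.integer(cfg$s)
  if (s > min(n, m))
    abort_invalid(sprintf("budget s = %d exceeds min(n, m) = %d", s, min(n, m)))
  list(r = as.integer(r), s = as.integer(s))
}

#' Align unpaired samples by entropic partial OT
#'
#' Solves partial OT between the two sample sets with uniform unit masses
#' (`a = 1_n`, `b = 1_m`) and budget `s` on the cosine-in-PC-space cost, then
#' hardens the (soft, entropic) plan into a partial matching: argmax along
#' the shorter side, greedy resolution of duplicate targets by descending
#' plan mass, then the `s` candidate pairs with the highest plan mass (ties
#' broken by lowest index). Candidates with plan mass below 1e-9 are dropped
#' first; if fewer than `s` survive, `s` shrinks with a warning. Pairs are
#' returned sorted by normal-sample index.
#'
#' @inheritParams gene_cost_matrix
#' @param acfg an [alignment_config()].
#' @param solver a [solver_config()] for the partial OT solve; the default
#'   uses a sharper `eta` than the gene level so the plan is near-binary, and
#'   a tolerance suited to the hard-matching extraction (which only consumes
#'   the argmax pattern of the plan).
#' @return a `sample_alignment` tibble with columns `normal`, `tumor`
#'   (column indices), `normal_id`, `tumor_id`, and `mass` (plan weight).
#' @export
align_samples <- function(X, Y, acfg = alignment_config(),
                          solver = solver_config(eta = 5e-3, tol = 1e-7,
                                                 max_iter = 20000L)) {
  X <- as_expression_matrix(X, "X"); Y <- as_expression_matrix(Y, "Y")
  check_shared_genes(X, Y)
  n <- ncol(X); m <- ncol(Y)
  res <- resolve_alignment(acfg, nrow(X), n, m)
  C <- sample_cost_matrix(X, Y, res$r)
  cfg <- solver
  cfg$s <- res$s
  P <- solve_partial_ot(C, rep(1, n), rep(1, m), cfg)$plan

  if (n <= m) {
    tgt <- apply(P, 1L, which.max)
    cand <- data.frame(normal = seq_len(n), tumor = tgt,
                       mass = P[cbind(seq_len(n), tgt)])
    other <- "tumor"
  } else {
    src <- apply(P, 2L, which.max)
    cand <- data.frame(normal = src, tumor = seq_len(m),
                       mass = P[cbind(src, seq_len(m))])
    other <- "normal"
  }
  cand <- cand[cand$mass > 1e-9, , drop = FALSE]
  # at most one use of each sample on the argmax side too: keep the heaviest
  cand <- cand[order(-cand$mass, cand$normal, cand$tumor), , drop = FALSE]
  cand <- cand[!duplicated(cand[[other]]), , drop = FALSE]
  if (nrow(cand) == 0L) abort_solver("sample alignment produced no matches")
  if (nrow(cand) < res$s) {
    warn_dotgrn(sprintf("only %d confident pairs available; reducing s from %d",
                        nrow(cand), res$s))
  }
  cand <- utils::head(cand, res$s)
  cand <- cand[order(cand$normal), , drop = FALSE]
  out <- tibble::tibble(
    normal = cand$normal, tumor = cand$tumor,
    normal_id = colnames(X)[cand$normal], tumor_id = colnames(Y)[cand$tumor],
    mass = cand$mass)
  class(out) <- c("sample_alignment", class(out))
  attr(out, "s") <- nrow(out)
  attr(out, "r") <- res$r
  out
}

# ---------------------------------------------------------------------------
# fitted differential GRN
# ---------------------------------------------------------------------------

new_dot_grn <- function(scores, alignment, paired, plan, solver, marginals) {
  structure(
    list(scores = scores, gene_ids = rownames(scores), alignment = alignment,
         paired = paired, converged = plan$converged,
         iterations = plan$iterations, solver = solver,
         marginals = marginals),
    class = "dot_grn")
}

#' Infer a differential GRN from paired samples
#'
#' Gene-level step of the double-OT method: the robust (unbalanced) OT plan
#' between the per-gene mean expression of the two conditions, on the
#' Spearman cost [gene_cost_matrix()], scores every directed link; entry
#' `(i, j)` of the score matrix is the mass transported from normal gene i to
#' tumor gene j. Self-links (the diagonal) are retained: regulatory networks
#' may contain loops and cycles.
#'
#' @inheritParams gene_cost_matrix
#' @param solver a [solver_config()].
#' @param normalize_marginals see [gene_marginals()].
#' @return a `dot_grn` object; see [tidy.dot_grn()], [rank_edges()].
#' @export
infer_grn_paired <- function(X, Y, solver = solver_config(),
                             normalize_marginals = TRUE) {
  X <- as_expression_matrix(X, "X"); Y <- as_expression_matrix(Y, "Y")
  check_shared_genes(X, Y)
  if (ncol(X) != ncol(Y))
    abort_invalid("paired inference requires equal sample counts")
  C <- gene_cost_matrix(X, Y)
  mg <- gene_marginals(X, Y, normalize = normalize_marginals)
  plan <- solve_robust_ot(C, mg$a, mg$b, solver)
  scores <- plan$plan
  dimnames(scores) <- dimnames(C)
  new_dot_grn(scores, alignment = NULL, paired = TRUE, plan = plan,
              solver = solver, marginals = mg)
}

#' Infer a differential GRN (paired or unpaired samples)
#'
#' End-to-end double-OT inference. With `paired = TRUE` the gene-level robust
#' OT step runs directly on the matched columns. With `paired = FALSE` the
#' samples are first aligned by [align_samples()]; the matched columns of `X`
#' and `Y` are reorganized into paired matrices of `s` samples and the gene
#' step runs on those.
#'
#' @inheritParams infer_grn_paired
#' @param paired are columns of `X` and `Y` already matched one-to-one?
#' @param acfg an [alignment_config()] (unpaired mode only).
#' @param align_solver [solver_config()] for the sample-level partial OT.
#' @return a `dot_grn`; in unpaired mode its `alignment` field holds the
#'   `sample_alignment` used.
#' @export
infer_grn <- function(X, Y, paired = TRUE, acfg = alignment_config(),
                      solver = solver_config(),
                      align_solver = solver_config(eta = 5e-3, tol = 1e-7,
                                                   max_iter = 20000L),
                      normalize_marginals = TRUE) {
  X <- as_expression_matrix(X, "X"); Y <- as_expression_matrix(Y, "Y")
  check_shared_genes(X, Y)
  if (paired) {
    if (ncol(X) != ncol(Y))
      abort_invalid(sprintf(
        "paired = TRUE but sample counts differ (n = %d, m = %d)",
        ncol(X), ncol(Y)))
    return(infer_grn_paired(X, Y, solver, normalize_marginals))
  }
  al <- align_samples(X, Y, acfg, align_solver)
  fit <- infer_grn_paired(X[, al$normal, drop = FALSE],
                          Y[, al$tumor, drop = FALSE],
                          solver, normalize_marginals)
  fit$paired <- FALSE
  fit$alignment <- al
  fit
}

score_matrix <- function(E) {
  if (inherits(E, "dot_grn")) return(E$scores)
  check_numeric_matrix(E, "scores")
  if (is.null(rownames(E)))
    dimnames(E) <- list(sprintf("g%0*d", nchar(nrow(E)), seq_len(nrow(E))),
                        sprintf("g%0*d", nchar(ncol(E)), seq_len(ncol(E))))
  E
}

#' Rank regulatory links by transported mass
#'
#' All `p^2` directed gene pairs sorted by score descending; ties are broken
#' by (regulator index, target index) ascending so the ranking is
#' deterministic.
#'
#' @param E a `dot_grn` fit or a `p x p` score matrix.
#' @param top_k optional truncation of the returned list.
#' @return a tibble with columns `regulator`, `target`, `score`, `rank`.
#' @export
rank_edges <- function(E, top_k = NULL) {
  S <- score_matrix(E)
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (is.na(top_k) || top_k <= 0L)
      abort_invalid("`top_k` must be a positive integer")
  }
  p <- nrow(S); q <- ncol(S)
  reg_idx <- rep(seq_len(p), times = q)
  tgt_idx <- rep(seq_len(q), each = p)
  ord <- order(-as.vector(S), reg_idx, tgt_idx)
  if (!is.null(top_k)) ord <- utils::head(ord, top_k)
  tibble::tibble(
    regulator = rownames(S)[reg_idx[ord]],
    target = colnames(S)[tgt_idx[ord]],
    score = as.vector(S)[ord],
    rank = seq_along(ord))
}

#' @export
print.dot_grn <- function(x, ...) {
  cat(sprintf("<dot_grn: %d genes, %s mode>\n", length(x$gene_ids),
              if (x$paired) "paired" else "unpaired"))
  if (!is.null(x$alignment))
    cat(sprintf("  %d aligned sample pairs\n", nrow(x$alignment)))
  cat(sprintf("  total edge score mass %.4g; solver %s in %d iterations\n",
              sum(x$scores), if (x$converged) "converged" else "did not converge",
              x$iterations))
  invisible(x)
}

#' Tidy a fitted differential GRN into a ranked edge list
#'
#' @param x a `dot_grn`.
#' @param top_k optional truncation (see [rank_edges()]).
#' @param ... ignored.
#' @return a tibble of ranked directed links.
#' @export
tidy.dot_grn <- function(x, top_k = NULL, ...) rank_edges(x, top_k)

#' One-row summary of a fitted differential GRN
#'
#' @param x a `dot_grn`.
#' @param ... ignored.
#' @return a one-row tibble: gene count, aligned sample count, transported
#'   mass, solver settings and convergence.
#' @export
glance.dot_grn <- function(x, ...) {
  tibble::tibble(
    p = length(x$gene_ids),
    s = if (is.null(x$alignment)) NA_integer_ else nrow(x$alignment),
    paired = x$paired,
    total_mass = sum(x$scores),
    eta = x$solver$eta,
    epsilon = x$solver$epsilon,
    converged = x$converged,
    iterations = x$iterations)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
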