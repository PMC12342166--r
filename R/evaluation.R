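truth_matrix <- function(truth, gene_ids) {
  p <- length(gene_ids)
  if (inherits(truth, "grn_truth")) truth <- truth$edges
  if (is.matrix(truth)) {
    if (!all(dim(truth) == c(p, p)))
      abort_invalid("truth matrix dimensions do not match the gene set")
    return(truth != 0)
  }
  if (!is.data.frame(truth) || ncol(truth) < 2L)
    abort_invalid("truth must be a grn_truth, a p x p matrix, or a data frame with regulator/target columns")
  reg <- as.character(truth[[if ("regulator" %in% names(truth)) "regulator" else 1L]])
  tgt <- as.character(truth[[if ("target" %in% names(truth)) "target" else 2L]])
  unknown <- setdiff(c(reg, tgt), gene_ids)
  if (length(unknown) > 0L)
    abort_invalid(sprintf("truth names unknown gene(s): %s",
                          paste(utils::head(unknown, 5L), collapse = ", ")))
  M <- matrix(FALSE, p, p, dimnames = list(gene_ids, gene_ids))
  M[cbind(match(reg, gene_ids), match(tgt, gene_ids))] <- TRUE
  M
}

# flatten scores + labels over the candidate universe (all ordered pairs,
# optionally excluding the diagonal), in deterministic column-major layout
edge_candidates <- function(E, truth, include_self = TRUE) {
  S <- score_matrix(E)
  if (nrow(S) != ncol(S))
    abort_invalid("edge score matrix must be square (p x p)")
  M <- truth_matrix(truth, rownames(S))
  p <- nrow(S)
  reg_idx <- rep(seq_len(p), times = p)
  tgt_idx <- rep(seq_len(p), each = p)
  keep <- if (include_self) rep(TRUE, p * p) else reg_idx != tgt_idx
  list(scores = as.vector(S)[keep], labels = as.vector(M)[keep],
       reg_idx = reg_idx[keep], tgt_idx = tgt_idx[keep])
}

#' Area under the ROC curve of a ranked edge prediction
#'
#' Rank-based (Mann-Whitney) AUROC over all candidate directed gene pairs,
#' with mid-ranks for tied scores. The candidate universe is all `p^2`
#' ordered pairs, or all off-diagonal pairs with `include_self = FALSE`.
#'
#' @param E a `dot_grn` fit or square score matrix.
#' @param truth a `grn_truth`, a two-column regulator/target data frame, or a
#'   `p x p` indicator matrix.
#' @param include_self count self-links (the diagonal) as candidates?
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(E, truth, include_self = TRUE) {
  cc <- edge_candidates(E, truth, include_self)
  K <- sum(cc$labels); N <- length(cc$labels)
  if (K == 0L || K == N)
    abort_metric("AUROC undefined: truth labels all-positive or all-negative")
  r <- rank(cc$scores)
  (sum(r[cc$labels]) - K * (K + 1) / 2) / (K * (N - K))
}

#' Area under the precision-recall curve
#'
#' Step-wise (interpolation-free) summation
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} over descending unique score thresholds
#' -- the conservative convention, documented so cross-implementation
#' comparisons are exact.
#'
#' @inheritParams auroc
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(E, truth, include_self = TRUE) {
  cc <- edge_candidates(E, truth, include_self)
  K <- sum(cc$labels)
  if (K == 0L)
    abort_metric("AUPR undefined: no true edges among the candidates")
  ord <- order(-cc$scores)
  lab <- cc$labels[ord]
  sc <- cc$scores[ord]
  tp <- cumsum(lab)
  np <- seq_along(lab)
  n <- length(sc)                           # last index of each unique score
  cut <- c(which(sc[-n] != sc[-1L]), n)
  prec <- tp[cut] / np[cut]
  rec <- tp[cut] / K
  sum(diff(c(0, rec)) * prec)
}

#' Early precision of the top-K predictions
#'
#' Fraction of true edges among the top-K ranked candidates, where K is the
#' number of edges in the ground-truth network (restricted to the candidate
#' universe). Ranking uses the deterministic [rank_edges()] order: score
#' descending, ties by (regulator, target) index.
#'
#' @inheritParams auroc
#' @return early precision in `[0, 1]`.
#' @export
early_precision <- function(E, truth, include_self = TRUE) {
  cc <- edge_candidates(E, truth, include_self)
  K <- sum(cc$labels)
  if (K == 0L)
    abort_metric("early precision undefined: no true edges among candidates")
  if (K > length(cc$labels))
    abort_invalid("K exceeds the number of candidate edges")
  ord <- order(-cc$scores, cc$reg_idx, cc$tgt_idx)
  sum(cc$labels[ord][seq_len(K)]) / K
}

#' Accuracy of a sample alignment against the true pairing
#'
#' @param al a `sample_alignment` from [align_samples()].
#' @param true_perm integer vector: `true_perm[i]` is the tumor column truly
#'   generated from normal column i (see [true_pairing()]).
#' @return the fraction of aligned pairs that are correct, in `[0, 1]`.
#' @export
alignment_accuracy <- function(al, true_perm) {
  if (!inherits(al, "sample_alignment"))
    abort_invalid("`al` must be a sample_alignment")
  if (any(al$normal > length(true_perm)))
    abort_invalid("`true_perm` does not cover all matched normal samples")
  mean(al$tumor == true_perm[al$normal])
}

#' Trivial baseline edge scores
#'
#' `random`: i.i.d. Uniform(0, 1) scores from `seed`. `spearman`: the
#' absolute Spearman correlation `|r(x_(i), y_(j))|` itself as the score
#' (algebraically `1 - gene_cost_matrix(X, Y)`).
#'
#' @inheritParams gene_cost_matrix
#' @param kind `"random"` or `"spearman"`.
#' @param seed RNG seed for the random baseline.
#' @return a `p x p` score matrix.
#' @export
baseline_scores <- function(X, Y, kind = c("random", "spearman"), seed = 1L) {
  kind <- match.arg(kind)
  X <- as_expression_matrix(X, "X"); Y <- as_expression_matrix(Y, "Y")
  check_shared_genes(X, Y)
  p <- nrow(X)
  if (kind == "random") {
    S <- with_local_seed(seed, matrix(stats::runif(p * p), p, p))
    dimnames(S) <- list(rownames(X), rownames(Y))
    S
  } else {
    1 - gene_cost_matrix(X, Y)
  }
}

#' Evaluate a ranked edge prediction against ground truth
#'
#' @inheritParams auroc
#' @return a one-row tibble: `auroc`, `aupr`, `ep`, `K` (true edge count in
#'   the candidate universe), `n_candidates`.
#' @export
evaluate_grn <- function(E, truth, include_self = TRUE) {
  cc <- edge_candidates(E, truth, include_self)
  tibble::tibble(
    auroc = auroc(E, truth, include_self),
    aupr = aupr(E, truth, include_self),
    ep = early_precision(E, truth, include_self),
    K = sum(cc$labels),
    n_candidates = length(cc$labels))
}
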