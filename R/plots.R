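#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of regulatory-link scores
#'
#' Tile plot of the transported-mass score matrix (regulators on rows,
#' targets on columns), optionally restricted to the genes touched by the
#' `top_k` strongest links to keep large networks readable.
#'
#' @param object a `dot_grn` fit.
#' @param top_k show only genes involved in the `top_k` highest-scoring
#'   links (default: all genes, capped at 50 for legibility).
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.dot_grn <- function(object, top_k = NULL, ...) {
  S <- object$scores
  if (is.null(top_k) && nrow(S) > 50L) top_k <- 100L
  if (!is.null(top_k)) {
    top <- rank_edges(object, top_k)
    keep <- union(unique(top$regulator), unique(top$target))
    S <- S[rownames(S) %in% keep, colnames(S) %in% keep, drop = FALSE]
  }
  df <- data.frame(
    regulator = factor(rep(rownames(S), times = ncol(S)),
                       levels = rev(rownames(S))),
    target = factor(rep(colnames(S), each = nrow(S)), levels = colnames(S)),
    score = as.vector(S))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$regulator,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "target (tumor state)", y = "regulator (normal state)",
                  fill = "mass") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a sample alignment
#'
#' Matched normal/tumor sample pairs with their partial-OT plan mass; a flat
#' profile near 1 indicates a confident, near-binary pseudo-permutation.
#'
#' @param object a `sample_alignment` from [align_samples()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.sample_alignment <- function(object, ...) {
  df <- data.frame(pair = seq_len(nrow(object)), mass = object$mass)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$mass)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "matched pair (by normal sample index)",
                  y = "transport plan mass") +
    ggplot2::theme_minimal()
}
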