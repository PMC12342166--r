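#' Expression matrices
#'
#' dotgrn represents expression data as plain numeric matrices with gene
#' identifiers as row names and sample identifiers as column names
#' (genes x samples, nonnegative finite values). `as_expression_matrix()`
#' validates and normalizes such an object; most user-facing functions call
#' it on their inputs.
#'
#' @param x a numeric matrix (genes x samples) or a data frame whose first
#'   column holds gene identifiers.
#' @param name label used in error messages.
#' @return a validated numeric matrix with dimnames.
#' @export
as_expression_matrix <- function(x, name = "x") {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1L]])
    x <- as.matrix(x[, -1L, drop = FALSE])
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x))
    abort_invalid(sprintf("`%s` must be a numeric matrix", name))
  if (nrow(x) < 2L || ncol(x) < 2L)
    abort_invalid(sprintf("`%s` needs at least 2 genes and 2 samples", name))
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("g%0*d", nchar(nrow(x)), seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("s%0*d", nchar(ncol(x)), seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    abort_invalid(sprintf("`%s` has duplicated gene identifiers (e.g. '%s')",
                          name, rownames(x)[duplicated(rownames(x))][1L]))
  if (any(!is.finite(x)))
    abort_invalid(sprintf("`%s` contains non-finite values", name))
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    abort_invalid(sprintf("`%s` has a negative value at gene '%s', sample '%s'",
                          name, rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  x
}

check_shared_genes <- function(X, Y) {
  if (nrow(X) != nrow(Y))
    abort_invalid("X and Y must contain the same genes")
  mism <- which(rownames(X) != rownames(Y))
  if (length(mism) > 0L)
    abort_invalid(sprintf(
      "gene order differs between X and Y (first offending id: '%s' vs '%s')",
      rownames(X)[mism[1L]], rownames(Y)[mism[1L]]))
  invisible(NULL)
}
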