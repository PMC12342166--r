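# TSV is the canonical on-disk format (CSV accepted on read); '#'-prefixed
# header lines carry the config/seed that produced a file.

io_delim <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers, and a numeric nonnegative body. `#`-prefixed lines are
#' treated as comments. Duplicate gene ids, non-numeric cells and negative
#' values are rejected with the offending coordinates.
#'
#' @param path file path; delimiter chosen by extension (`.csv` vs TSV).
#' @return a genes x samples numeric matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("file not found: %s", path))
  df <- tryCatch(
    readr::read_delim(path, delim = io_delim(path), comment = "#",
                      show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort_invalid(sprintf("cannot parse %s: %s", path,
                                              conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) < 2L)
    abort_invalid(sprintf("%s holds no expression data", path))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    abort_invalid(sprintf("duplicate gene id '%s' in %s",
                          ids[duplicated(ids)][1L], path))
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    abort_invalid(sprintf(
      "non-numeric cell '%s' at gene '%s', sample '%s' in %s",
      body[bad[1L], bad[2L]], ids[bad[1L]], colnames(df)[-1L][bad[2L]], path))
  }
  dimnames(vals) <- list(ids, colnames(df)[-1L])
  as_expression_matrix(vals, basename(path))
}

#' Write an expression matrix to TSV/CSV
#'
#' Values are rendered with full double precision (`%.17g`) so a write/read
#' round trip is bit-identical.
#'
#' @param X genes x samples matrix.
#' @param path output path (`.csv` switches to comma-delimited).
#' @param header optional character vector written as `#` comment lines
#'   (e.g. the config/seed that produced the data).
#' @export
write_expression_matrix <- function(X, path, header = NULL) {
  X <- as_expression_matrix(X, "X")
  delim <- io_delim(path)
  body <- apply(X, c(1L, 2L), function(v) sprintf("%.17g", v))
  lines <- c(
    if (length(header)) paste0("# ", header),
    paste(c("gene_id", colnames(X)), collapse = delim),
    vapply(seq_len(nrow(X)),
           function(i) paste(c(rownames(X)[i], body[i, ]), collapse = delim),
           character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked edge list to TSV
#'
#' Columns `regulator`, `target`, `score` (10 significant digits), `rank`;
#' deterministic output for a fixed input.
#'
#' @param rl a tibble from [rank_edges()] (or any data frame with those
#'   columns).
#' @param path output path.
#' @param header optional `#` comment lines.
#' @export
write_edge_list <- function(rl, path, header = NULL) {
  if (!is.data.frame(rl) ||
      !all(c("regulator", "target", "score", "rank") %in% names(rl)))
    abort_invalid("`rl` must have regulator, target, score and rank columns")
  lines <- c(
    if (length(header)) paste0("# ", header),
    "regulator\ttarget\tscore\trank",
    sprintf("%s\t%s\t%s\t%d", rl$regulator, rl$target,
            formatC(rl$score, digits = 10, format = "g"), rl$rank))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed edge list from TSV
#'
#' Needs at least two columns (regulator, target); extra columns are kept but
#' ignored for the edge set. Duplicate edges are dropped with a warning;
#' edges naming genes outside `gene_ids` (when given) are an error.
#'
#' @param path file path.
#' @param gene_ids optional gene universe to validate against.
#' @return a tibble with columns `regulator` and `target` (plus any extras).
#' @export
read_edge_list <- function(path, gene_ids = NULL) {
  if (!file.exists(path)) abort_invalid(sprintf("file not found: %s", path))
  df <- readr::read_delim(path, delim = io_delim(path), comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L)
    abort_invalid(sprintf("%s needs at least regulator and target columns", path))
  names(df)[1:2] <- c("regulator", "target")
  df$regulator <- as.character(df$regulator)
  df$target <- as.character(df$target)
  dup <- duplicated(df[, c("regulator", "target")])
  if (any(dup)) {
    warn_dotgrn(sprintf("%d duplicate edge row(s) dropped from %s",
                        sum(dup), path))
    df <- df[!dup, , drop = FALSE]
  }
  if (!is.null(gene_ids)) {
    unknown <- setdiff(c(df$regulator, df$target), gene_ids)
    if (length(unknown) > 0L)
      abort_invalid(sprintf("%s names unknown gene(s): %s", path,
                            paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  tibble::as_tibble(df)
}

# rebuild a square score matrix from a full ranked edge list
edge_list_to_scores <- function(rl) {
  genes <- sort(unique(c(rl$regulator, rl$target)))
  S <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  if (!"score" %in% names(rl))
    abort_invalid("edge list has no score column")
  S[cbind(match(rl$regulator, genes), match(rl$target, genes))] <- rl$score
  S
}
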