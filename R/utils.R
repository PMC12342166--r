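#' @importFrom rlang %||%
NULL

abort_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("dotgrn_invalid_input", "dotgrn_error",
                                     "error", "condition")))
}

abort_solver <- function(msg) {
  stop(errorCondition(msg, class = c("dotgrn_solver_error", "dotgrn_error",
                                     "error", "condition")))
}

abort_metric <- function(msg) {
  stop(errorCondition(msg, class = c("dotgrn_undefined_metric", "dotgrn_error",
                                     "error", "condition")))
}

warn_dotgrn <- function(msg) {
  warning(warningCondition(msg, class = c("dotgrn_warning", "warning",
                                          "condition")))
}

# run `expr` under a temporary RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive independent sub-seeds (network / baseline / noise / shuffle) from one
# master seed, all below 2^31
derive_seeds <- function(seed, k = 4L) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

check_numeric_matrix <- function(C, name = "C") {
  if (!is.matrix(C) || !is.numeric(C))
    abort_invalid(sprintf("`%s` must be a numeric matrix", name))
  if (any(!is.finite(C)))
    abort_invalid(sprintf("`%s` contains non-finite entries", name))
  invisible(C)
}

check_mass_vector <- function(a, name = "a") {
  if (!is.numeric(a) || length(a) < 1L)
    abort_invalid(sprintf("`%s` must be a numeric vector", name))
  if (any(!is.finite(a)) || any(a < 0))
    abort_invalid(sprintf("`%s` must be finite and nonnegative", name))
  if (sum(a) <= 0)
    abort_invalid(sprintf("`%s` must carry positive total mass", name))
  invisible(a)
}
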