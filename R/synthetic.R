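#' Configuration for the synthetic two-condition generator
#'
#' @param p number of genes.
#' @param n number of samples per condition.
#' @param alpha fraction of differentially expressed (DE) genes, in `(0, 1]`;
#'   `ceiling(alpha * p)` genes are made DE.
#' @param lam expected number of regulators per DE gene, including the gene
#'   itself (>= 1); realized in-degrees follow `1 + Poisson(lam - 1)`.
#' @param noise_sd conditional noise scale of the tumor state (> 0); stable
#'   (non-DE) pathways get a tenth of it.
#' @param seed master seed; independent substreams are derived for the
#'   network, the baseline expression, the conditional noise, and shuffling.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(p, n, alpha = 0.1, lam = 2, noise_sd = 0.5,
                             seed = 1L) {
  p <- as.integer(p); n <- as.integer(n)
  if (is.na(p) || p < 2L) abort_invalid("`p` must be an integer >= 2")
  if (is.na(n) || n < 2L) abort_invalid("`n` must be an integer >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    abort_invalid("`alpha` must lie in (0, 1]")
  if (ceiling(alpha * p) < 1) abort_invalid("alpha * p must round up to >= 1")
  if (!is.numeric(lam) || lam < 1) abort_invalid("`lam` must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    abort_invalid("`noise_sd` must be positive")
  structure(list(p = p, n = n, alpha = alpha, lam = lam, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

link_types <- c("linear", "quadratic", "sine")

#' Plant a ground-truth differential regulatory network
#'
#' Draws `ceiling(alpha * p)` DE genes uniformly without replacement. Each DE
#' gene j receives `1 + Poisson(lam - 1)` parents (so the expected in-degree
#' is exactly `lam` and every DE gene keeps at least one regulator): itself
#' first, the rest drawn uniformly from the other genes. Each parent gets a
#' weight with random sign and magnitude `Uniform(0.5, 1.5)`, and each target
#' a regulatory link type drawn from linear / quadratic / sine.
#'
#' @param cfg a [synthetic_config()].
#' @return a `grn_truth` object: gene ids, DE gene indices, a tibble of
#'   directed edges, and per-target regulatory function specs.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seeds <- derive_seeds(cfg$seed)
  p <- cfg$p
  gene_ids <- sprintf("g%0*d", nchar(p), seq_len(p))
  net <- with_local_seed(seeds[1L], {
    n_de <- ceiling(cfg$alpha * p)
    de <- sort(sample.int(p, n_de))
    funs <- lapply(de, function(j) {
      d <- min(1L + stats::rpois(1L, cfg$lam - 1), p)
      parents <- j
      if (d > 1L) parents <- c(j, sample(seq_len(p)[-j], d - 1L))
      list(target = j,
           parents = parents,
           weights = sample(c(-1, 1), d, replace = TRUE) *
             stats::runif(d, 0.5, 1.5),
           type = sample(link_types, 1L))
    })
    names(funs) <- gene_ids[de]
    list(de = de, funs = funs)
  })
  edges <- do.call(rbind, lapply(net$funs, function(f)
    data.frame(regulator = f$parents, target = f$target)))
  edges <- tibble::tibble(
    regulator = gene_ids[edges$regulator],
    target = gene_ids[edges$target],
    regulator_idx = edges$regulator,
    target_idx = edges$target)
  structure(
    list(gene_ids = gene_ids, de_genes = net$de, edges = edges,
         functions = net$funs, alpha = cfg$alpha, lam = cfg$lam),
    class = "grn_truth")
}

#' @export
print.grn_truth <- function(x, ...) {
  cat(sprintf("<grn_truth: %d genes, %d DE, %d directed edges>\n",
              length(x$gene_ids), length(x$de_genes), nrow(x$edges)))
  invisible(x)
}

regulatory_fn <- function(t, type, sigma = 1) {
  switch(type,
         linear = t,
         quadratic = sign(t) * t^2 / sigma,
         sine = 2 * sigma * sin(t / sigma),
         abort_invalid(sprintf("unknown regulatory link type '%s'", type)))
}

#' Simulate paired two-condition expression with a planted network
#'
#' Baseline (normal) expression is Gaussian around gene-specific means:
#' `X[i, k] = mu_i + N(0, 1)` with `mu_i ~ Uniform(2, 8)`, truncated at zero.
#' Non-DE genes keep their expression up to mild noise
#' (`Y = X + N(0, 0.1 * noise_sd)` -- stable pathways), while each DE gene j
#' is redrawn conditionally on its parents' baseline deviations:
#' `Y[j, k] = mu_j + sum_u w_u f(X[u, k] - mu_u) + N(0, noise_sd)`, truncated
#' at zero, where f is the planted linear / variance-matched quadratic / sine
#' link. Column k of `Y` derives from column k of `X`, so the dataset is
#' paired by construction.
#'
#' @param net a [generate_network()] result consistent with `cfg`.
#' @param cfg the [synthetic_config()].
#' @return a `grn_dataset`: matrices `X`, `Y`, the `truth` network, a `NULL`
#'   `permutation` slot (see [shuffle_columns()]), and the config.
#' @export
simulate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "grn_truth"), inherits(cfg, "synthetic_config"))
  if (length(net$gene_ids) != cfg$p)
    abort_invalid("network and config disagree on the number of genes")
  seeds <- derive_seeds(cfg$seed)
  p <- cfg$p; n <- cfg$n
  base <- with_local_seed(seeds[2L], {
    mu <- stats::runif(p, 2, 8)
    X <- mu + matrix(stats::rnorm(p * n), p, n)
    list(mu = mu, X = pmax(X, 0))
  })
  X <- base$X; mu <- base$mu
  Y <- with_local_seed(seeds[3L], {
    Y <- X + matrix(stats::rnorm(p * n, sd = 0.1 * cfg$noise_sd), p, n)
    for (f in net$functions) {
      dev <- X[f$parents, , drop = FALSE] - mu[f$parents]
      fx <- regulatory_fn(dev, f$type)
      Y[f$target, ] <- mu[f$target] + colSums(f$weights * fx) +
        stats::rnorm(n, sd = cfg$noise_sd)
    }
    pmax(Y, 0)
  })
  dimnames(X) <- list(net$gene_ids, sprintf("N%0*d", nchar(n), seq_len(n)))
  dimnames(Y) <- list(net$gene_ids, sprintf("T%0*d", nchar(n), seq_len(n)))
  structure(list(X = X, Y = Y, truth = net, permutation = NULL, config = cfg),
            class = "grn_dataset")
}

#' Shuffle tumor samples to emulate unpaired data
#'
#' Permutes the columns of `Y` by a uniformly random permutation, recorded in
#' the `permutation` slot: column k of the shuffled `Y` is column
#' `permutation[k]` of the paired `Y`. `X` is untouched.
#'
#' @param ds a paired `grn_dataset`.
#' @param seed permutation seed; defaults to the shuffle substream of the
#'   dataset's master seed.
#' @return the dataset with shuffled `Y` and recorded `permutation`.
#' @export
shuffle_columns <- function(ds, seed = NULL) {
  stopifnot(inherits(ds, "grn_dataset"))
  if (!is.null(ds$permutation))
    abort_invalid("dataset is already shuffled")
  seed <- seed %||% derive_seeds(ds$config$seed)[4L]
  perm <- with_local_seed(seed, sample.int(ncol(ds$Y)))
  ds$Y <- ds$Y[, perm, drop = FALSE]
  ds$permutation <- perm
  ds
}

#' True normal-to-tumor pairing of a shuffled dataset
#'
#' @param ds a shuffled `grn_dataset` (or a paired one, giving the identity).
#' @return integer vector `tp` with `tp[i]` the column of the (current) `Y`
#'   that was generated from column i of `X`.
#' @export
true_pairing <- function(ds) {
  stopifnot(inherits(ds, "grn_dataset"))
  n <- ncol(ds$X)
  if (is.null(ds$permutation)) return(seq_len(n))
  match(seq_len(n), ds$permutation)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: [generate_network()] + [simulate_expression()] and,
#' optionally, [shuffle_columns()].
#'
#' @inheritParams synthetic_config
#' @param shuffle also shuffle the tumor columns (unpaired mode)?
#' @return a `grn_dataset`.
#' @export
simulate_grn_data <- function(p, n, alpha = 0.1, lam = 2, noise_sd = 0.5,
                              seed = 1L, shuffle = FALSE) {
  cfg <- synthetic_config(p, n, alpha, lam, noise_sd, seed)
  ds <- simulate_expression(generate_network(cfg), cfg)
  if (shuffle) ds <- shuffle_columns(ds)
  ds
}

#' @export
print.grn_dataset <- function(x, ...) {
  cat(sprintf("<grn_dataset: %d genes x %d samples per condition, %s>\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$permutation)) "paired" else "shuffled"))
  print(x$truth)
  invisible(x)
}
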