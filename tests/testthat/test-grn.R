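test_that("spearman_corr reproduces rank-correlation values", {
  expect_equal(spearman_corr(c(1, 2, 3), c(2, 4, 9)), 1)
  expect_equal(spearman_corr(c(1, 2, 3), c(9, 4, 2)), -1)
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_warning(r <- spearman_corr(c(1, 1, 1), c(1, 2, 3)),
                 class = "dotgrn_warning")
  expect_equal(r, 0)
  expect_error(spearman_corr(1:3, 1:4), class = "dotgrn_invalid_input")
  expect_error(spearman_corr(1:2, 2:1), class = "dotgrn_invalid_input")
})

test_that("gene cost matrix is 1 - |spearman| with matched genes", {
  set.seed(13)
  X <- expr_matrix(runif(12, 1, 5), 4, 3)
  # identical rows: zero diagonal
  expect_equal(diag(gene_cost_matrix(X, X)), rep(0, 4), ignore_attr = TRUE)
  # antitone rows also give zero cost (|r| = 1)
  Y <- X
  Y[2, ] <- max(X[1, ]) + 1 - X[1, ]
  C <- gene_cost_matrix(X, Y)
  expect_equal(C[1, 2], 0)
  # the -0.5 example maps to cost 0.5
  X2 <- expr_matrix(rbind(c(1, 2, 3), c(5, 6, 7)), 2, 3, genes = c("a", "b"))
  Y2 <- expr_matrix(rbind(c(2, 5, 8), c(3, 1, 2)), 2, 3, genes = c("a", "b"))
  expect_equal(gene_cost_matrix(X2, Y2)["a", "b"], 0.5)
  expect_error(gene_cost_matrix(X, X[4:1, ]), class = "dotgrn_invalid_input")
})

test_that("gene cost matrix is invariant under monotone transforms of a row", {
  set.seed(23)
  X <- expr_matrix(runif(40, 1, 9), 5, 8)
  Y <- expr_matrix(runif(40, 1, 9), 5, 8)
  C0 <- gene_cost_matrix(X, Y)
  Xi <- X; Xi[3, ] <- exp(X[3, ])              # increasing transform
  expect_equal(gene_cost_matrix(Xi, Y), C0)
  Xd <- X; Xd[3, ] <- 100 - 3 * X[3, ]          # decreasing transform
  expect_equal(gene_cost_matrix(Xd, Y), C0)
})

test_that("gene marginals are normalized row means", {
  X <- expr_matrix(c(2, 6, 4, 8), 2, 2)
  m <- gene_marginals(X, 10 * X)
  expect_equal(m$a, c(0.3, 0.7), ignore_attr = TRUE)
  expect_equal(m$b, m$a)                        # scale invariance
  Xu <- expr_matrix(rep(1:2, each = 3) * 0 + 5, 3, 2)
  expect_equal(gene_marginals(Xu, Xu)$a, rep(1 / 3, 3), ignore_attr = TRUE)
  raw <- gene_marginals(X, X, normalize = FALSE)
  expect_equal(raw$a, rowMeans(X), ignore_attr = TRUE)
})

test_that("joint PCA projection is deterministic and agrees with an eigen oracle", {
  set.seed(33)
  X <- expr_matrix(runif(60, 0, 10), 20, 3)
  Y <- X  # copies project to identical coordinates
  pr <- project_samples(X, Y, 2)
  expect_equal(pr$X_proj, pr$Y_proj, ignore_attr = TRUE)

  Y2 <- expr_matrix(runif(60, 0, 10), 20, 3)
  r <- 4
  pr2 <- project_samples(X, Y2, r)
  # oracle: eigendecomposition of the covariance of the stacked samples
  Z <- scale(t(cbind(X, Y2)), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Z), symmetric = TRUE)
  S_or <- Z %*% ev$vectors[, seq_len(r)]
  got <- rbind(pr2$X_proj, pr2$Y_proj)
  for (j in seq_len(r)) {
    expect_equal(abs(got[, j]), abs(S_or[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_error(project_samples(X, Y2, 7), class = "dotgrn_invalid_input")
})

test_that("sample cost matrix is the cosine distance in PC space", {
  # rank-1 data: projections are collinear, parallel columns cost ~0
  base <- runif(6, 1, 2)
  X <- expr_matrix(c(base * 1, base * 2), 6, 2)
  Y <- expr_matrix(c(base * 3, base * 0.5), 6, 2)
  C <- sample_cost_matrix(X, Y, 1)
  expect_true(all(C %in% c(0, 2) | abs(C) < 1e-9 | abs(C - 2) < 1e-9))
  # direct cosine evaluation via an orthogonal 2-sample configuration
  set.seed(43)
  X2 <- expr_matrix(runif(40, 1, 9), 10, 4)
  Y2 <- expr_matrix(runif(40, 1, 9), 10, 4)
  pr <- project_samples(X2, Y2, 3)
  C2 <- sample_cost_matrix(X2, Y2, 3)
  i <- 2; j <- 3
  cosv <- sum(pr$X_proj[i, ] * pr$Y_proj[j, ]) /
    (sqrt(sum(pr$X_proj[i, ]^2)) * sqrt(sum(pr$Y_proj[j, ]^2)))
  expect_equal(C2[i, j], 1 - cosv, ignore_attr = TRUE)
  expect_true(all(C2 >= 0 & C2 <= 2))
})

test_that("alignment recovers a planted permutation and breaks ties low", {
  set.seed(53)
  X <- expr_matrix(runif(200, 0, 10), 20, 10)
  perm <- sample(10)
  Y <- X[, perm]
  colnames(Y) <- sprintf("t%d", 1:10)
  al <- align_samples(X, Y, alignment_config(s = 10),
                      solver_config(eta = 5e-3))
  expect_equal(nrow(al), 10)
  expect_equal(al$tumor[order(al$normal)], match(seq_len(10), perm))

  # duplicated normal sample: exactly one is matched, the lower index on ties
  X2 <- expr_matrix(runif(30, 0, 10), 10, 3)
  X2[, 2] <- X2[, 1]
  Y2 <- X2[, c(1, 3), drop = FALSE] + 0
  colnames(Y2) <- c("u1", "u2")
  al2 <- align_samples(X2, Y2, alignment_config(s = 1),
                       solver_config(eta = 5e-3))
  expect_equal(nrow(al2), 1)
  expect_lte(al2$normal, 2)
})

test_that("paired inference routes mass toward correlated gene pairs", {
  set.seed(63)
  n <- 30
  x1 <- sort(runif(n, 1, 9))
  X <- expr_matrix(rbind(x1, runif(n, 1, 9)), 2, n, genes = c("gA", "gB"))
  Y <- expr_matrix(rbind(runif(n, 1, 9), 2 * x1 + rnorm(n, sd = 1e-3)), 2, n,
                   genes = c("gA", "gB"))
  fit <- infer_grn_paired(X, Y)
  expect_gt(fit$scores["gA", "gB"], fit$scores["gA", "gA"])
})

test_that("uniform cost with uniform marginals yields flat scores", {
  set.seed(73)
  base <- runif(5, 1, 9)
  # every gene row is a permutation of the same values: uniform marginals
  X <- expr_matrix(rbind(base, base[c(2, 3, 4, 5, 1)], base[5:1],
                         base[c(3, 1, 5, 2, 4)]), 4, 5)
  Y <- expr_matrix(rep(3, 20), 4, 5)  # constant tumor rows: cost uniform 1
  expect_warning(fit <- infer_grn_paired(X, Y), class = "dotgrn_warning")
  expect_equal(max(fit$scores) - min(fit$scores), 0, tolerance = 1e-6)
})

test_that("gene-level scores are equivariant under gene permutation", {
  set.seed(83)
  X <- expr_matrix(runif(50, 1, 9), 5, 10)
  Y <- expr_matrix(runif(50, 1, 9), 5, 10)
  fit <- infer_grn_paired(X, Y)
  perm <- sample(5)
  fitp <- infer_grn_paired(X[perm, ], Y[perm, ])
  expect_equal(fitp$scores, fit$scores[perm, perm], tolerance = 1e-9)
})

test_that("unpaired mode equals paired mode when the alignment is exact", {
  ds <- simulate_grn_data(p = 60, n = 20, alpha = 0.2, lam = 2,
                          noise_sd = 0.5, seed = 5)
  dsu <- shuffle_columns(ds, seed = 99)
  fit_p <- infer_grn(ds$X, ds$Y, paired = TRUE)
  fit_u <- infer_grn(dsu$X, dsu$Y, paired = FALSE,
                     acfg = alignment_config(s = 20))
  expect_equal(alignment_accuracy(fit_u$alignment, true_pairing(dsu)), 1)
  expect_identical(fit_u$scores, fit_p$scores)
  # budget bound: never more than min(n, m) pairs
  expect_lte(nrow(fit_u$alignment), 20)
})

test_that("paired mode rejects unequal sample counts", {
  X <- expr_matrix(runif(20), 4, 5)
  Y <- expr_matrix(runif(16), 4, 4)
  expect_error(infer_grn(X, Y, paired = TRUE),
               class = "dotgrn_invalid_input")
})

test_that("rank_edges orders deterministically with index tie-breaks", {
  S <- matrix(c(0.5, 0.3, 0.1, 0.2), 2, 2,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  rl <- rank_edges(S)
  expect_equal(rl$regulator, c("g1", "g2", "g2", "g1"))
  expect_equal(rl$target, c("g1", "g1", "g2", "g2"))
  expect_equal(rl$rank, 1:4)
  # all-equal scores: lexicographic by (regulator, target) index
  Se <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
  rle <- rank_edges(Se)
  expect_equal(paste(rle$regulator, rle$target),
               c("g1 g1", "g1 g2", "g2 g1", "g2 g2"))
  expect_equal(nrow(rank_edges(Se, top_k = 4)), 4)
  expect_error(rank_edges(Se, top_k = 0), class = "dotgrn_invalid_input")
})

test_that("tidy and glance summarize a fit", {
  ds <- simulate_grn_data(p = 20, n = 15, alpha = 0.2, lam = 2,
                          noise_sd = 0.5, seed = 2)
  fit <- infer_grn(ds$X, ds$Y, paired = TRUE)
  td <- tidy(fit, top_k = 10)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10)
  expect_true(all(diff(td$score) <= 0))
  gl <- glance(fit)
  expect_equal(gl$p, 20)
  expect_true(gl$converged)
})

test_that("score mass is conserved in the classical limit", {
  ds <- simulate_grn_data(p = 20, n = 15, alpha = 0.2, lam = 2,
                          noise_sd = 0.5, seed = 3)
  fit <- infer_grn_paired(ds$X, ds$Y,
                          solver_config(eta = 1e-2, epsilon = 1e6,
                                        tol = 1e-10, max_iter = 1e5))
  # proportion marginals each sum to 1, so the balanced limit transports
  # total mass 1
  expect_lt(abs(sum(fit$scores) - 1), 1e-3)
})
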