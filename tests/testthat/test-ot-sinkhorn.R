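sharp <- solver_config(eta = 1e-3, tol = 1e-8, max_iter = 5e5)

test_that("entropic OT approaches the exact plan at small eta", {
  C <- matrix(c(0, 1, 1, 0), 2, 2)
  r <- solve_entropic_ot(C, c(0.5, 0.5), c(0.5, 0.5), sharp)
  expect_lt(sum(abs(r$plan - diag(2) * 0.5)), 1e-3)
  expect_true(r$converged)
})

test_that("entropic OT satisfies marginals and is near-optimal on random instances", {
  set.seed(12)
  for (k in 1:20) {
    inst <- random_ot_instance(5, 5)
    ex <- solve_exact_ot(inst$C, inst$a, inst$b)
    en <- solve_entropic_ot(inst$C, inst$a, inst$b, sharp)
    expect_lt(sum(abs(rowSums(en$plan) - inst$a)) +
                sum(abs(colSums(en$plan) - inst$b)), 1e-6)
    expect_lt(abs(en$objective - ex$objective), 0.02 * ex$objective + 1e-12)
  }
})

test_that("entropic OT limits behave as the regularization dictates", {
  set.seed(22)
  inst <- random_ot_instance(4, 4)
  # max-entropy limit: plan approaches the outer product a b^T
  big <- solve_entropic_ot(inst$C, inst$a, inst$b, solver_config(eta = 1e3))
  expect_lt(max(abs(big$plan - outer(inst$a, inst$b))), 1e-4)
  # 1x1: constraints force the plan for any eta
  one <- solve_entropic_ot(matrix(3, 1, 1), 1, 1, solver_config(eta = 0.05))
  expect_equal(one$plan[1, 1], 1, tolerance = 1e-9)
})

test_that("entropic OT flags non-convergence instead of failing", {
  set.seed(32)
  inst <- random_ot_instance(5, 5)
  expect_warning(
    r <- solve_entropic_ot(inst$C, inst$a, inst$b,
                           solver_config(eta = 1e-3, tol = 1e-12,
                                         max_iter = 20L)),
    class = "dotgrn_warning")
  expect_false(r$converged)
})

test_that("robust OT matches the scalar closed form exp(-c/(eta+2*eps))", {
  cfg_grid <- expand.grid(c = c(0.1, 0.5, 1, 2),
                          eta = c(0.01, 0.05, 0.1, 0.5),
                          eps = c(0.05, 0.2, 1))
  for (i in seq_len(nrow(cfg_grid))) {
    g <- cfg_grid[i, ]
    r <- solve_robust_ot(matrix(g$c, 1, 1), 1, 1,
                         solver_config(eta = g$eta, epsilon = g$eps,
                                       tol = 1e-13, max_iter = 2e5))
    expect_equal(r$plan[1, 1], exp(-g$c / (g$eta + 2 * g$eps)),
                 tolerance = 1e-6)
  }
})

test_that("robust OT approaches classical OT as epsilon grows", {
  set.seed(42)
  for (k in 1:10) {
    inst <- random_ot_instance(5, 5)
    cfg <- solver_config(eta = 1e-2, epsilon = 1e6, tol = 1e-10,
                         max_iter = 1e5)
    rob <- solve_robust_ot(inst$C, inst$a, inst$b, cfg)
    ent <- solve_entropic_ot(inst$C, inst$a, inst$b,
                             solver_config(eta = 1e-2, tol = 1e-10,
                                           max_iter = 1e5))
    expect_lt(max(abs(rob$plan - ent$plan)), 1e-3)
  }
})

test_that("robust OT transported mass is nondecreasing in epsilon", {
  set.seed(52)
  for (k in 1:5) {
    inst <- random_ot_instance(4, 4)
    masses <- vapply(c(0.01, 0.1, 1, 10, 100), function(eps) {
      sum(solve_robust_ot(inst$C, inst$a, inst$b,
                          solver_config(eta = 1e-2, epsilon = eps,
                                        tol = 1e-10, max_iter = 1e5))$plan)
    }, numeric(1))
    expect_true(all(diff(masses) >= -1e-7))
  }
})

test_that("robust OT handles zero mass and rejects bad regularization", {
  C <- matrix(runif(4), 2, 2)
  z <- solve_robust_ot(C, c(0, 0), c(0.5, 0.5), solver_config())
  expect_equal(z$plan, matrix(0, 2, 2))
  expect_error(solver_config(eta = 0), class = "dotgrn_invalid_input")
  expect_error(solver_config(epsilon = -1), class = "dotgrn_invalid_input")
})

test_that("partial OT respects the budget on toy instances", {
  C <- matrix(c(0, 1, 1, 0.5), 2, 2, byrow = TRUE)
  cfg <- function(s) solver_config(eta = 1e-3, s = s, tol = 1e-10,
                                   max_iter = 1e5)
  # zero budget: zero plan
  z <- solve_partial_ot(C, c(1, 1), c(1, 1), cfg(0))
  expect_equal(z$plan, matrix(0, 2, 2))
  # budget 1 concentrates on the zero-cost cell
  p1 <- solve_partial_ot(C, c(1, 1), c(1, 1), cfg(1))
  expect_equal(p1$plan[1, 1], 1, tolerance = 1e-3)
  expect_lt(p1$objective, 1e-3)
  # budget 2 is forced onto the diagonal, objective 0.5
  p2 <- solve_partial_ot(C, c(1, 1), c(1, 1), cfg(2))
  expect_equal(p2$plan, diag(2), tolerance = 1e-3)
  expect_equal(p2$objective, 0.5, tolerance = 1e-3)
  expect_error(solve_partial_ot(C, c(1, 1), c(1, 1), cfg(3)),
               class = "dotgrn_invalid_input")
})

test_that("partial OT tracks the exact-partial oracle on random instances", {
  set.seed(62)
  for (k in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    inst <- random_ot_instance(n1, n2)
    s <- runif(1, 0.2, 0.9)
    pe <- solve_exact_partial_ot(inst$C, inst$a, inst$b, s)
    pd <- solve_partial_ot(inst$C, inst$a, inst$b,
                           solver_config(eta = 1e-3, s = s, tol = 1e-10,
                                         max_iter = 1e5))
    expect_lt(abs(pd$objective - pe$objective), 0.02 * pe$objective + 1e-9)
    expect_true(all(rowSums(pd$plan) <= inst$a + 1e-6))
    expect_true(all(colSums(pd$plan) <= inst$b + 1e-6))
    expect_equal(sum(pd$plan), s, tolerance = 1e-6)
  }
})

test_that("entropic solvers are symmetric under transposition", {
  set.seed(72)
  inst <- random_ot_instance(3, 5)
  en <- solve_entropic_ot(inst$C, inst$a, inst$b,
                          solver_config(eta = 0.05, tol = 1e-11))
  ent <- solve_entropic_ot(t(inst$C), inst$b, inst$a,
                           solver_config(eta = 0.05, tol = 1e-11))
  expect_equal(ent$plan, t(en$plan), tolerance = 1e-6)
  rob <- solve_robust_ot(inst$C, inst$a, inst$b,
                         solver_config(eta = 0.05, epsilon = 0.5, tol = 1e-11))
  robt <- solve_robust_ot(t(inst$C), inst$b, inst$a,
                          solver_config(eta = 0.05, epsilon = 0.5, tol = 1e-11))
  expect_equal(robt$plan, t(rob$plan), tolerance = 1e-6)
})
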