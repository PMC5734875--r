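# draw admissible random rates for property checks
random_neutral_params <- function() {
  repeat {
    u <- runif(1, 1e-4, 0.2)
    v <- runif(1, 1e-4, 0.2)
    a <- runif(1, 1, 4)
    b <- runif(1, 1, 4)
    if (u <= 1 && a * u + v <= 1 && b * v <= 1) return(list(u = u, v = v, a = a, b = b))
  }
}

stationary_eigen <- function(M) {
  e <- eigen(t(M))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sum(v)
}

test_that("the neutral transition matrix is built exactly from the rates", {
  m <- build_neutral(u = 0.1, v = 0.01, a = 2, b = 1.5)
  expect_equal(m$M[2, ], c(0.2, 0.79, 0.01))
  expect_equal(m$M[1, ], c(0.9, 0.1, 0))
  expect_equal(m$M[3, ], c(0, 0.015, 0.985))
  expect_equal(rowSums(m$M), rep(1, 3))
  # zero rates freeze the chain
  expect_equal(build_neutral(0, 0, 2, 2)$M, diag(3))
  # inadmissible rates are refused with the offending row named
  expect_error(build_neutral(u = 0.5, v = 0.2, a = 2, b = 1), "x2")
})

test_that("the neutral equilibrium is [ab, b, 1]/z and matches the eigen oracle", {
  expect_equal(unname(neutral_equilibrium(1, 1)), rep(1 / 3, 3))
  expect_equal(unname(neutral_equilibrium(2, 1.5)), c(3, 1.5, 1) / 5.5)
  expect_equal(unname(neutral_equilibrium(2, 1.5)),
               c(0.54545, 0.27273, 0.18182), tolerance = 1e-4)
  set.seed(61)
  for (i in 1:100) {
    p <- random_neutral_params()
    m <- build_neutral(p$u, p$v, p$a, p$b)
    expect_equal(unname(m$stationary), stationary_eigen(m$M), tolerance = 1e-10)
  }
  # with a, b > 1 the third component is always below 1/3
  for (i in 1:50) {
    a <- runif(1, 1, 10); b <- runif(1, 1, 10)
    expect_lt(neutral_equilibrium(a, b)[3], 1 / 3 + 1e-12)
  }
})

test_that("trajectories match step-by-step multiplication and converge", {
  m <- build_neutral(0.1, 0.01, 2, 1.5)
  X0 <- c(1, 0, 0)
  expect_identical(trajectory(m, X0, 0), X0)
  expect_equal(trajectory(m, X0, 1), c(0.9, 0.1, 0))
  X <- X0
  for (T in 1:50) {
    X <- drop(X %*% m$M)
    expect_equal(trajectory(m, X0, T), X, tolerance = 1e-12)
  }
  expect_equal(sum(trajectory(m, X0, 1000)), 1, tolerance = 1e-12)
  # long-run convergence to the closed-form equilibrium (u = 10 v)
  expect_equal(unname(trajectory(m, X0, 5000)),
               unname(neutral_equilibrium(2, 1.5)), tolerance = 1e-8)
  expect_error(trajectory(m, X0, -1), "non-negative")
  expect_error(trajectory(m, c(0.5, 0.5), 1), "length 3")
})

test_that("the selection chain reduces to neutrality at s = t = 0", {
  m <- build_selection(0.1, 0.01, 2, 1.5, s = 0, t = 0)
  expect_equal(m$M_sel, m$M4)
  eq <- selection_equilibrium(m, method = "eigen")
  # detailed balance on the 4-state neutral chain: [ab, b, 1, 1/c]/z
  closed <- c(3, 1.5, 1, 1 / 1.5)
  expect_equal(unname(eq), closed / sum(closed), tolerance = 1e-10)
})

test_that("selection updates behave on hand-checkable cases", {
  # zero rates: the fourth state is absorbing under both updates
  m0 <- build_selection(0, 0, 2, 1.5, s = 0.3, t = 0.2)
  expect_equal(selection_step(m0, c(0, 0, 0, 1)), c(0, 0, 0, 1))
  expect_equal(selection_step(m0, c(0, 0, 0, 1), update = "population"),
               c(0, 0, 0, 1))
  # population update: pure fitness weighting renormalizes 0.5 : 0.5*2 to 1/3 : 2/3
  m1 <- build_selection(0, 0, 2, 1.5, s = 1, t = 0)
  expect_equal(selection_step(m1, c(0.5, 0.5, 0, 0), update = "population"),
               c(1 / 3, 2 / 3, 0, 0))
  # transition update with zero rates is the identity chain
  expect_equal(selection_step(m1, c(0.5, 0.5, 0, 0)), c(0.5, 0.5, 0, 0))
})

test_that("the selection equilibrium is unique and solver-independent", {
  m <- build_selection(0.1, 0.01, 2, 1.5, s = -0.5, t = 0.5)
  e1 <- selection_equilibrium(m, X0 = c(1, 0, 0, 0))
  e2 <- selection_equilibrium(m, X0 = c(0, 0, 0, 1))
  e3 <- selection_equilibrium(m, method = "eigen")
  expect_equal(e1, e2, tolerance = 1e-8)
  expect_equal(e1, e3, tolerance = 1e-8)
  expect_equal(sum(e1), 1, tolerance = 1e-12)
  # the fitter C(2:3) cluster overtakes C(2:2) and C(2:4)
  expect_true(e1[1] > e1[3] && e1[3] > e1[4] && e1[4] > e1[2])
})

test_that("neutrality is rejected for the observed clusters but not for neutral ones", {
  rep1 <- neutrality_test(c(0.41, 0.092, 0.482))
  expect_true(rep1$rejected)
  expect_lt(rep1$max_neutral_x3, 1 / 3)
  expect_false(rep1$ordering_consistent)

  eq <- neutral_equilibrium(2, 1.5)
  rep2 <- neutrality_test(eq)
  expect_false(rep2$rejected)
  expect_true(rep2$ordering_consistent)

  rep3 <- neutrality_test(c(0.6, 0.3, 0.1))
  expect_false(rep3$rejected)
  expect_true(rep3$ordering_consistent)
})

test_that("fit_selection recovers parameters from self-generated equilibria", {
  truth <- selection_equilibrium(build_selection(0.1, 0.01, 2, 1.5,
                                                 s = -0.5, t = 0.5),
                                 method = "eigen")
  fit <- fit_selection(truth, grid_step = 0.1)
  expect_equal(fit$s_hat, -0.5, tolerance = 0.02)
  expect_equal(fit$t_hat, 0.5, tolerance = 0.02)
  expect_lt(fit$loss, 1e-8)

  # neutral observations recover (0, 0)
  closed <- c(3, 1.5, 1, 1 / 1.5)
  fit0 <- fit_selection(closed / sum(closed), grid_step = 0.1)
  expect_equal(fit0$s_hat, 0, tolerance = 0.02)
  expect_equal(fit0$t_hat, 0, tolerance = 0.02)
})

test_that("the observed cluster vector demands s < 0 and t > 0", {
  obs <- c(0.374, 0.087, 0.292, 0.128)
  fit <- fit_selection(obs, grid_step = 0.05)
  expect_lt(fit$s_hat, 0)
  expect_gt(fit$t_hat, 0)
  # constraining either sign against the estimate costs a large loss factor
  expect_gt(fit$loss_s_nonneg / fit$loss, 3)
  expect_gt(fit$loss_t_nonpos / fit$loss, 3)
})
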