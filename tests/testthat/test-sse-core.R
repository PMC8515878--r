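test_that("state space and three-rate transition matrix are structured correctly", {
  sp <- sse_state_space(2)
  expect_equal(sp$n_states, 4)
  expect_equal(sp$obs_index, c(0, 1, 0, 1))
  Q <- pollendiv:::build_three_rate_q(0.1, 0.2, 0.05, sp)
  expect_equal(rowSums(Q), rep(0, 4))
  expect_equal(Q[1, 2], 0.1) # A->R within hidden 1
  expect_equal(Q[2, 1], 0.2)
  expect_equal(Q[1, 3], 0.05) # hidden flip within A
  expect_equal(Q[1, 4], 0) # dual transition
  expect_equal(Q[2, 3], 0)
  expect_error(sse_parameters(rep(0.1, 4), rep(0, 4),
                              matrix(0.1, 4, 4) - diag(0.4, 4), sp),
               "dual")
})

test_that("tip initial conditions encode state, ambiguity and sampling", {
  tr <- read_tree("(A:1,B:1);")
  sp2 <- sse_state_space(2)
  rho <- 89 / 397
  tip <- initialize_tips(c(A = "0", B = "1"), tr, sp2, rho)
  expect_equal(tip$D[1, ], c(rho, 0, rho, 0))
  expect_equal(tip$D[2, ], c(0, rho, 0, rho))
  expect_equal(tip$E[1, ], rep(1 - rho, 4))

  sp1 <- sse_state_space(1)
  tip2 <- initialize_tips(c(A = "1", B = "ambiguous"), tr, sp1, 1)
  expect_equal(tip2$D[1, ], c(0, 1))
  expect_equal(tip2$D[2, ], c(1, 1))
  expect_equal(tip2$E[1, ], c(0, 0))

  expect_error(initialize_tips(c(A = "0", B = "1"), tr, sp1, 0), "rho")
})

test_that("branch integration reproduces closed forms of the uncoupled ODEs", {
  sp <- sse_state_space(1)
  # mu = 0, q = 0, E = 0: pure exponential decay of D
  p <- sse_parameters(c(0.1, 0.1), c(0, 0), list(q01 = 0, q10 = 0), sp)
  out <- integrate_branch(list(E = c(0, 0), D = c(1, 1)), p, 10)
  expect_equal(out$D[1] * exp(out$logcomp), exp(-1), tolerance = 1e-7)

  # lambda = 0, q = 0: E(t) = 1 - exp(-mu t), D decays at rate mu
  p2 <- sse_parameters(c(0, 0), c(0.05, 0.05), list(q01 = 0, q10 = 0), sp)
  out2 <- integrate_branch(list(E = c(0, 0), D = c(1, 1)), p2, 10)
  expect_equal(out2$E[1], 1 - exp(-0.5), tolerance = 1e-7)
  expect_equal(out2$D[1] * exp(out2$logcomp), exp(-0.5), tolerance = 1e-7)

  # t = 0 is the identity
  out3 <- integrate_branch(list(E = c(0.2, 0.3), D = c(0.5, 0.6)), p, 0)
  expect_equal(out3$E, c(0.2, 0.3))
  expect_equal(out3$D, c(0.5, 0.6))
})

test_that("branch integration agrees with deSolve on coupled dynamics", {
  sp <- sse_state_space(1)
  p <- sse_parameters(c(0.3, 0.1), c(0.05, 0.12),
                      list(q01 = 0.07, q10 = 0.21), sp)
  rhs <- function(t, y, parms) {
    E <- y[1:2]
    D <- y[3:4]
    dE <- p$mu - (p$lambda + p$mu) * E + as.numeric(p$Q %*% E) +
      p$lambda * E^2
    dD <- -(p$lambda + p$mu) * D + as.numeric(p$Q %*% D) +
      2 * p$lambda * E * D
    list(c(dE, dD))
  }
  y0 <- c(0.1, 0.4, 1, 0.2)
  for (t in c(0.5, 3, 12)) {
    ref <- deSolve::ode(y0, c(0, t), rhs, NULL, rtol = 1e-10,
                        atol = 1e-12)[2, 2:5]
    out <- integrate_branch(list(E = y0[1:2], D = y0[3:4]), p, t)
    expect_equal(out$E, unname(ref[1:2]), tolerance = 1e-6)
    expect_equal(out$D * exp(out$logcomp), unname(ref[3:4]),
                 tolerance = 1e-6)
  }
})

test_that("E trajectories are monotone and bounded in [0, 1]", {
  sp <- sse_state_space(1)
  p <- sse_parameters(c(0.2, 0.35), c(0.1, 0.02),
                      list(q01 = 0.04, q10 = 0.09), sp)
  ts <- seq(0, 40, by = 2)
  prev <- c(0, 0)
  for (t in ts[-1]) {
    out <- integrate_branch(list(E = c(0, 0), D = c(1, 1)), p, t)
    expect_true(all(out$E >= prev - 1e-8))
    expect_true(all(out$E >= 0 & out$E <= 1))
    prev <- out$E
  }
})

test_that("the cherry likelihood matches its closed form with and without conditioning", {
  tr <- read_tree("(A:10,B:10);")
  ch <- c(A = "0", B = "0")
  p <- sse_parameters(c(0.1, 0.1), c(0, 0), list(q01 = 0, q10 = 0))
  expect_equal(sse_loglik(tr, ch, p, condition_on_survival = FALSE),
               log(0.1) - 2, tolerance = 1e-7)
  expect_equal(sse_loglik(tr, ch, p), -2, tolerance = 1e-7)
})

test_that("state-independent rates factorize into birth-death plus Mk", {
  set.seed(99)
  lam <- 0.12
  mu <- 0.04
  q01 <- 0.05
  q10 <- 0.08
  p <- sse_parameters(c(lam, lam), c(mu, mu),
                      list(q01 = q01, q10 = q10))
  errs <- replicate(50, {
    tr <- random_ultra_tree(10)
    st <- random_states(tr)
    a <- sse_loglik(tr, st, p, root_weighting = "equal")
    b <- desolve_bd_loglik(tr, lam, mu) +
      mk_loglik(tr, st, q01, q10, "uniform")
    abs(a - b)
  })
  expect_lt(max(errs), 1e-5)
})

test_that("tied hidden rates collapse to the observed-state likelihood", {
  set.seed(17)
  tr <- random_ultra_tree(20)
  st <- random_states(tr)
  p4 <- sse_parameters(rep(0.15, 4), rep(0.03, 4),
                       list(q01 = 0.02, q10 = 0.03, qh = 0.7),
                       sse_state_space(2))
  p2 <- sse_parameters(rep(0.15, 2), rep(0.03, 2),
                       list(q01 = 0.02, q10 = 0.03))
  expect_equal(sse_loglik(tr, st, p4), sse_loglik(tr, st, p2),
               tolerance = 1e-6)
  # with per-observed-state rates too
  p4b <- sse_parameters(c(0.1, 0.2, 0.1, 0.2), c(0.02, 0.05, 0.02, 0.05),
                        list(q01 = 0.02, q10 = 0.03, qh = 0.4),
                        sse_state_space(2))
  p2b <- sse_parameters(c(0.1, 0.2), c(0.02, 0.05),
                        list(q01 = 0.02, q10 = 0.03))
  expect_equal(sse_loglik(tr, st, p4b), sse_loglik(tr, st, p2b),
               tolerance = 1e-6)
})

test_that("the likelihood is invariant to permuting hidden-state labels", {
  set.seed(23)
  tr <- random_ultra_tree(12)
  st <- random_states(tr)
  sp <- sse_state_space(2)
  lam <- c(0.1, 0.2, 0.3, 0.15)
  mu <- c(0.02, 0.04, 0.06, 0.01)
  Qargs <- list(q01 = 0.03, q10 = 0.05, qh = 0.08)
  p <- sse_parameters(lam, mu, Qargs, sp)
  # swap hidden states 1 and 2: permute combined indices (1,2,3,4)->(3,4,1,2)
  perm <- c(3, 4, 1, 2)
  p_swapped <- sse_parameters(lam[perm], mu[perm], Qargs, sp)
  expect_equal(sse_loglik(tr, st, p), sse_loglik(tr, st, p_swapped),
               tolerance = 1e-8)
})

test_that("SSE parameters round-trip through YAML", {
  p <- sse_parameters(c(0.1, 0.2, 0.3, 0.15), c(0.02, 0.04, 0.06, 0.01),
                      list(q01 = 0.03, q10 = 0.05, qh = 0.08),
                      sse_state_space(2))
  txt <- params_to_yaml(p)
  p2 <- params_from_yaml(txt)
  expect_equal(p2$lambda, p$lambda)
  expect_equal(p2$mu, p$mu)
  expect_equal(p2$Q, p$Q, tolerance = 1e-12)
})
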