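test_that("mk_loglik handles zero-rate degeneracies", {
  tr <- read_tree("(A:1,B:1);")
  expect_equal(exp(mk_loglik(tr, c(A = "0", B = "0"), 0, 0)), 0.5)
  expect_equal(mk_loglik(tr, c(A = "0", B = "1"), 0, 0), -Inf)
  expect_error(mk_loglik(tr, c(A = "0", B = "0"), -0.1, 0.2), "rates")
})

test_that("mk_loglik matches brute-force enumeration on all small trees", {
  rates <- c(0.02, 0.1, 0.3, 0.8, 2)
  set.seed(11)
  for (nwk in small_tree_set()) {
    tr <- read_tree(nwk)
    st <- random_states(tr)
    for (q01 in rates) {
      for (q10 in rates) {
        expect_equal(mk_loglik(tr, st, q01, q10),
                     brute_mk_loglik(tr, st, q01, q10),
                     tolerance = 1e-8)
      }
    }
    # ambiguous tips enter as (1,1) partials
    st[1] <- "ambiguous"
    expect_equal(mk_loglik(tr, st, 0.3, 0.8),
                 brute_mk_loglik(tr, st, 0.3, 0.8), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to swapping state labels and rates", {
  set.seed(3)
  tr <- random_ultra_tree(8)
  st <- random_states(tr)
  flipped <- stats::setNames(ifelse(st == "0", "1", "0"), names(st))
  for (r in list(c(0.1, 0.4), c(0.6, 0.05))) {
    expect_equal(mk_loglik(tr, st, r[1], r[2]),
                 mk_loglik(tr, flipped, r[2], r[1]), tolerance = 1e-12)
  }
})

test_that("stationary root prior requires positive total rate", {
  tr <- read_tree("(A:1,B:1);")
  expect_error(mk_loglik(tr, c(A = "0", B = "0"), 0, 0,
                         root_prior = "stationary"), "undefined")
})

test_that("marginal node posteriors equal the clamped-likelihood oracle", {
  set.seed(21)
  tr <- random_ultra_tree(7, age = 5)
  st <- random_states(tr)
  q01 <- 0.12
  q10 <- 0.3
  m <- pollendiv:::asr_marginal_fixed(tr, st, q01, q10)
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-9)
  for (nd in (ape::Ntip(tr) + 1L):(ape::Ntip(tr) + tr$Nnode)) {
    l0 <- mk_loglik(tr, st, q01, q10, fix_node = nd, fix_state = 0)
    l1 <- mk_loglik(tr, st, q01, q10, fix_node = nd, fix_state = 1)
    expect_equal(m[as.character(nd), "P0"], 1 / (1 + exp(l1 - l0)),
                 tolerance = 1e-9)
  }
})

test_that("Bayesian ASR is seeded, symmetric where it should be, and sums to 1", {
  tr <- read_tree("(A:2,B:2);")
  st <- c(A = "0", B = "1")
  r1 <- asr_marginal_posteriors(tr, st, n_iter = 400, seed = 5,
                                rate_prior_mean = 0.5)
  r2 <- asr_marginal_posteriors(tr, st, n_iter = 400, seed = 5,
                                rate_prior_mean = 0.5)
  expect_identical(r1$rate_samples, r2$rate_samples)
  expect_equal(unname(rowSums(r1$node_posterior)), 1, tolerance = 1e-9)
  # symmetric data and prior: root posterior near (0.5, 0.5)
  expect_equal(unname(r1$node_posterior[1, "P0"]), 0.5, tolerance = 0.05)

  # uniform tip data pulls every node toward the shared state
  tr2 <- random_ultra_tree(6, age = 8)
  st2 <- stats::setNames(rep("0", 6), tr2$tip.label)
  # single observed state: rates identified only through the prior, warned
  expect_warning(
    r3 <- asr_marginal_posteriors(tr2, st2, n_iter = 400, seed = 7,
                                  rate_prior_mean = 0.05),
    "distinct")
  expect_true(all(r3$node_posterior[, "P0"] >= 0.5))
})

test_that("MCMC with flat data returns the exponential rate prior", {
  # a two-tip tree with both tips ambiguous has constant likelihood
  tr <- read_tree("(A:1,B:1);")
  st <- c(A = "ambiguous", B = "ambiguous")
  pm <- 0.4
  expect_warning(
    r <- asr_marginal_posteriors(tr, st, n_iter = 3000, seed = 13,
                                 rate_prior_mean = pm),
    "distinct")
  for (k in 1:2) {
    draws <- r$rate_samples[, k]
    mcse <- stats::sd(draws) / sqrt(length(draws) / 10) # crude ESS guard
    expect_lt(abs(mean(draws) - pm), 3 * mcse + 0.05 * pm)
  }
})

test_that("node Bayes factors follow the 2*delta-lnML definition and threshold", {
  # constructed case: symmetric cherry, perfectly symmetric data
  tr <- read_tree("(A:2,B:2);")
  st <- c(A = "0", B = "1")
  bf <- node_bayes_factor(tr, st, node = 3, n_rungs = 6, n_iter = 150,
                          seed = 31, rate_prior_mean = 0.5)
  expect_lt(bf$bayes_factor, 2) # ~0 up to stepping-stone noise
  expect_false(bf$significant && bf$bayes_factor <= 5)

  # strongly asymmetric data: eight tips all in state 0
  tr2 <- read_tree(paste0("(((A:0.1,B:0.1):0.4,(C:0.1,D:0.1):0.4):4.5,",
                          "((E:0.1,F:0.1):0.4,(G:0.1,H:0.1):0.4):4.5);"))
  st2 <- stats::setNames(rep("0", 8), LETTERS[1:8])
  bf2 <- node_bayes_factor(tr2, st2, node = 9, n_rungs = 6, n_iter = 150,
                           seed = 32, rate_prior_mean = 0.05)
  expect_equal(bf2$preferred_state, 0)
  expect_gt(bf2$bayes_factor, 5)
  expect_true(bf2$significant)

  # the threshold is strict: a BF at exactly 5 is not significant
  fake <- bf2
  fake$bayes_factor <- 5
  fake$significant <- is.finite(5) && 5 > 5
  expect_false(fake$significant)

  expect_error(node_bayes_factor(tr2, st2, node = 2), "internal")
})

test_that("an impossible fixation yields an infinite, flagged Bayes factor", {
  # zero-length terminal branches make the opposing root state impossible
  # for every rate value
  tr <- read_tree("(A:0,B:0);")
  st <- c(A = "0", B = "0")
  bf <- node_bayes_factor(tr, st, node = 3, n_rungs = 4, n_iter = 80,
                          seed = 41, rate_prior_mean = 0.5)
  expect_true(is.infinite(bf$bayes_factor))
  expect_true(bf$infinite)
  expect_equal(bf$preferred_state, 0)
})
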