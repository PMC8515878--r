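test_that("simulated trees are valid, ultrametric, and hit the tip target", {
  rep <- simulate_bisse_tree(c(0.15, 0.2), c(0.03, 0.05), c(0.05, 0.08),
                             stop_n = 40, seed = 1)
  expect_equal(ape::Ntip(rep$tree), 40)
  expect_equal(length(rep$tip_states), 40)
  expect_true(all(rep$tip_states %in% 0:1))
  validate_tree(rep$tree)
  expect_true(validate_ultrametric(rep$tree, rel_tol = 1e-9)$pass)
  # same seed, same replicate
  rep2 <- simulate_bisse_tree(c(0.15, 0.2), c(0.03, 0.05), c(0.05, 0.08),
                              stop_n = 40, seed = 1)
  expect_equal(write_tree(rep$tree), write_tree(rep2$tree))
  expect_identical(rep$tip_states, rep2$tip_states)
})

test_that("zero transition rate keeps every tip in the root state", {
  rep <- simulate_bisse_tree(c(0.2, 0.2), c(0, 0), c(0, 0), stop_n = 25,
                             root_state = 0, seed = 2)
  expect_true(all(rep$tip_states == 0))
})

test_that("a pure-birth time-stopped simulation matches the Yule expectation", {
  # crown start: E[tips] = 2 exp(lambda t)
  lam <- 0.1
  tt <- 10
  set.seed(31)
  sizes <- vapply(1:200, function(i) {
    r <- simulate_bisse_tree(c(lam, lam), c(0, 0), c(0, 0),
                             stop_time = tt, min_surviving_tips = 1)
    ape::Ntip(r$tree)
  }, 0)
  expected <- 2 * exp(lam * tt)
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("trait-only simulation respects degeneracies and CTMC expectations", {
  tr <- random_ultra_tree(12, age = 10)
  expect_true(all(simulate_mk_traits(tr, 0, 0, root_state = 0,
                                     seed = 3) == 0))
  # stationary frequency of state 1 is q01/(q01+q10) on long trees
  longtr <- random_ultra_tree(40, age = 400)
  set.seed(4)
  freq <- mean(replicate(30, mean(simulate_mk_traits(longtr, 0.2, 0.1))))
  expect_equal(freq, 2 / 3, tolerance = 0.1)
  # deterministic under a seed
  expect_identical(simulate_mk_traits(tr, 0.1, 0.2, seed = 5),
                   simulate_mk_traits(tr, 0.1, 0.2, seed = 5))
})

test_that("incomplete sampling derives state-specific rho from f", {
  # equal split with the empirical-style 89 kept of 397
  rep <- simulate_bisse_tree(c(0.15, 0.15), c(0.02, 0.02), c(0.1, 0.1),
                             stop_n = 120, seed = 6)
  ps <- apply_incomplete_sampling(rep, total_richness = 397, f = 0.5,
                                  n_keep = 89, seed = 7)
  expect_equal(ape::Ntip(ps$tree), 89)
  n0 <- ps$n_kept[["0"]]
  n1 <- ps$n_kept[["1"]]
  expect_equal(ps$rho[1], n0 / (n0 + 0.5 * 308))
  expect_equal(ps$rho[2], n1 / (n1 + 0.5 * 308))
  expect_true(validate_ultrametric(ps$tree, rel_tol = 1e-9)$pass)

  # the worked arithmetic case: 40 + 49 kept of 397 at f = 0.5
  expect_equal(40 / (40 + 0.5 * 308), 0.2062, tolerance = 1e-3)
  expect_equal(49 / (49 + 0.5 * 308), 0.2414, tolerance = 1e-3)

  # f = 0 means no unsampled accessible species, so rho_0 = 1
  ps0 <- apply_incomplete_sampling(rep, total_richness = 397, f = 0,
                                   n_keep = 89, seed = 8)
  expect_equal(ps0$rho[1], 1)

  expect_error(apply_incomplete_sampling(rep, total_richness = 100,
                                         f = 0.5, n_keep = 120),
               "infeasible|below")
})

test_that("the synthetic pollen generator is reproducible and within spec", {
  states <- stats::setNames(rep(c("A", "R", "AR"), length.out = 12),
                            paste0("sp", 1:12))
  g1 <- generate_synthetic_pollen_dataset(states, seed = 11)
  g2 <- generate_synthetic_pollen_dataset(states, seed = 11)
  expect_equal(length(g1$samples), length(g2$samples))
  expect_identical(g1$samples[[1]]$composition,
                   g2$samples[[1]]$composition)
  ns <- table(vapply(g1$samples, function(s) s$species, ""))
  expect_true(all(ns >= 1 & ns <= 22))
  # every sample sums to 100 and contaminants stay under the filter
  cat <- g1$catalog
  for (s in g1$samples) {
    expect_equal(sum(s$composition), 100, tolerance = 1e-9)
    truth <- states[[s$species]]
    acc <- cat[names(s$composition), "accessibility"]
    frac <- s$composition / 100
    if (truth == "A") {
      expect_lt(sum(frac[acc == "restricted"]), 0.05)
    } else if (truth == "R") {
      expect_lt(sum(frac[acc == "accessible"]), 0.05)
    } else {
      expect_gt(sum(frac[acc == "accessible"]), 0.05)
      expect_gt(sum(frac[acc == "restricted"]), 0.05)
    }
  }
})

test_that("coding the synthetic data recovers every true state", {
  set.seed(12)
  states <- stats::setNames(sample(c("A", "R", "AR"), 60, replace = TRUE),
                            paste0("sp", sprintf("%02d", 1:60)))
  gen <- generate_synthetic_pollen_dataset(states, seed = 13)
  coded <- code_pollen_dataset(gen$samples, gen$catalog)
  recovered <- stats::setNames(coded$accessibility, coded$species)
  expect_equal(recovered[names(states)], states)
})
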