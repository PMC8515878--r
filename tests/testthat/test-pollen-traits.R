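test_that("minor pollen types are excluded per sample and profiles renormalised", {
  s <- make_sample("bee1", "a", c(FabR = 60, AstA = 36, BraA = 4))
  prof <- aggregate_species_profile(list(s))
  expect_equal(sort(names(prof$proportions)), c("AstA", "FabR"))
  expect_equal(unname(prof$proportions["FabR"]), 0.625)
  expect_equal(unname(prof$proportions["AstA"]), 0.375)

  # identity on a pure sample
  p2 <- aggregate_species_profile(list(make_sample("bee1", "a",
                                                   c(AstA = 100))))
  expect_equal(unname(p2$proportions), 1)

  # load-size weighted combination
  p3 <- aggregate_species_profile(list(
    make_sample("bee1", "a", c(AstA = 100), w = 2),
    make_sample("bee1", "b", c(FabR = 100), w = 1)))
  expect_equal(unname(p3$proportions["AstA"]), 2 / 3)
  expect_equal(unname(p3$proportions["FabR"]), 1 / 3)
  expect_equal(sum(p3$proportions), 1)
})

test_that("aggregation rejects mixed species and fully-filtered input", {
  expect_error(aggregate_species_profile(list(
    make_sample("bee1", "a", c(AstA = 100)),
    make_sample("bee2", "b", c(AstA = 100)))), "mix")
  many <- paste0("T", 1:25)
  comp <- stats::setNames(rep(4, 25), many)
  expect_error(aggregate_species_profile(list(
    make_sample("bee1", "a", comp))), "filtered out")
})

test_that("the minor-type filter is idempotent", {
  set.seed(42)
  for (i in 1:20) {
    p <- stats::setNames(stats::runif(6), paste0("T", 1:6))
    p <- p / sum(p)
    once <- pollendiv:::filter_minor_types(p, 0.05)
    twice <- pollendiv:::filter_minor_types(once, 0.05)
    expect_equal(once, twice)
  }
})

test_that("accessibility classification distinguishes A, R, AR, data_deficient", {
  cat <- tiny_catalog()
  prof <- aggregate_species_profile(list(
    make_sample("b", "a", c(FabR = 62.5, AstA = 37.5))))
  expect_equal(classify_accessibility(prof, cat), "AR")

  pure <- aggregate_species_profile(list(make_sample("b", "a",
                                                     c(AstA = 100))))
  expect_equal(classify_accessibility(pure, cat), "A")
  purer <- aggregate_species_profile(list(make_sample("b", "a",
                                                      c(FabR = 100))))
  expect_equal(classify_accessibility(purer, cat), "R")

  unk <- aggregate_species_profile(list(make_sample("b", "a",
                                                    c(UnknownType = 100))))
  expect_equal(classify_accessibility(unk, cat), "data_deficient")
})

test_that("specificity uses the inclusive 95% single-family rule", {
  cat <- tiny_catalog()
  mk_prof <- function(comp) aggregate_species_profile(list(
    make_sample("b", "a", comp)))
  expect_equal(classify_specificity(mk_prof(c(AstA = 90, MalA = 7,
                                              FabR = 3)), cat,
                                    threshold = 0.95), "generalist")
  expect_equal(classify_specificity(mk_prof(c(AstA = 97, FabR = 3)), cat),
               "specialist")
  # exactly at the boundary counts as specialist
  expect_equal(classify_specificity(mk_prof(c(AstA = 95, FabR = 5)), cat),
               "specialist")
  expect_equal(classify_specificity(mk_prof(c(AstA = 60, FabR = 40)), cat),
               "generalist")
  # unresolvable family
  expect_equal(classify_specificity(mk_prof(c(UnknownType = 100)), cat),
               "data_deficient")
  # family shares pool across pollen types before the threshold test
  pooled <- mk_prof(c(AstA = 70, MalA = 26, FabR = 4))
  expect_equal(classify_specificity(pooled, cat), "generalist")
})

test_that("character matrices follow the four partition codings", {
  st <- c(sp1 = "A", sp2 = "R", sp3 = "AR", sp4 = "data_deficient")
  expect_equal(unname(build_character_matrix(st, "PA1")$states["sp3"]), "1")
  expect_equal(unname(build_character_matrix(st, "PA2")$states["sp3"]),
               "ambiguous")
  expect_equal(unname(build_character_matrix(st, "PA3")$states["sp3"]), "0")
  m <- build_character_matrix(st, "PA1")
  expect_equal(unname(m$states["sp1"]), "0")
  expect_equal(unname(m$states["sp2"]), "1")
  expect_equal(unname(m$states["sp4"]), "missing")

  ps <- build_character_matrix(c(x = "specialist", y = "generalist"), "PS")
  expect_equal(unname(ps$states), c("0", "1"))

  # unknown partition and illegal states error
  expect_error(build_character_matrix(st, "PA9"))
  expect_error(build_character_matrix(c(a = "blue"), "PA1"), "not legal")

  # tips absent from the state map are coded missing
  m2 <- build_character_matrix(st, "PA1", tip_labels = c(names(st), "sp5"))
  expect_equal(unname(m2$states["sp5"]), "missing")
})

test_that("PA1 dominates PA3 under the 0 < 1 state order for every species", {
  states <- c("A", "R", "AR")
  for (s in states) {
    st <- stats::setNames(s, "sp")
    v1 <- build_character_matrix(st, "PA1")$states
    v3 <- build_character_matrix(st, "PA3")$states
    expect_true(as.integer(v1) >= as.integer(v3))
    if (s != "AR") expect_equal(v1, v3)
  }
})

test_that("pollen tables and catalogs round-trip through CSV", {
  td <- withr::local_tempdir()
  states <- c(bee1 = "A", bee2 = "AR", bee3 = "R")
  gen <- generate_synthetic_pollen_dataset(states, n_samples_range = c(2, 4),
                                           seed = 5)
  f <- file.path(td, "pollen.csv")
  write_pollen_table(gen$samples, f)
  back <- read_pollen_table(f)
  expect_equal(length(back), length(gen$samples))
  one <- back[[1]]
  orig <- gen$samples[[which(vapply(gen$samples, function(s)
    s$sample_id == one$sample_id, TRUE))]]
  expect_equal(sort(names(one$composition)), sort(names(orig$composition)))
  expect_equal(one$composition[order(names(one$composition))],
               orig$composition[order(names(orig$composition))],
               tolerance = 1e-8)

  fc <- file.path(td, "catalog.csv")
  utils::write.csv(as.data.frame(gen$catalog), fc, row.names = FALSE)
  cat2 <- read_pollen_catalog(fc)
  expect_equal(nrow(cat2), nrow(gen$catalog))

  m <- build_character_matrix(c(bee1 = "A", bee2 = "AR"), "PA2")
  fnex <- file.path(td, "chars.nex")
  write_character_matrix(m, fnex, format = "nexus")
  expect_true(any(grepl("\\{01\\}", readLines(fnex))))
})
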