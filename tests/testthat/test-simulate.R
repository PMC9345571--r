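test_that("simulation is reproducible and drops unobservable histories", {
  spec <- generator_spec("Mtbh", 500, 0.1, seed = 11)
  a <- simulate_sample(spec)
  b <- simulate_sample(spec)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(rowSums(a) > 0))
  expect_lte(nrow(a), 500)
  expect_identical(attr(a, "true_N"), 500L)
})

test_that("degenerate specs behave as the pattern dictates", {
  # near-certain capture: everyone observed on every list
  all_in <- simulate_sample(generator_spec("Mh", 300, 1 - 1e-9, cv = 0,
                                           seed = 2))
  expect_equal(nrow(all_in), 300)
  expect_true(all(all_in == 1L))
  # a behavioral multiplier of zero halts recapture entirely
  mb0 <- simulate_sample(generator_spec("Mb", 2000, 0.3, cv = 0,
                                        behavior_multiplier = 0, seed = 3))
  expect_true(all(rowSums(mb0) == 1L))
})

test_that("observed fraction under Mh matches the closed form", {
  # Monte-Carlo mean over replicates vs the cumulative first-encounter
  # expectation, within 3 standard errors
  expected <- expected_observed_fraction(beta_shapes(0.1, 0.85), 5)
  fr <- vapply(1:100, function(r) {
    nrow(simulate_sample(generator_spec("Mh", 10000, 0.1, seed = 1000 + r))) /
      10000
  }, numeric(1))
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), 3 * se)
  expect_equal(round(expected, 3), 0.363)
})

test_that("list-wise probabilities keep the Beta marginal in every pattern", {
  # the generator guarantees each p_jk ~ Beta(shapes); check first-capture
  # probabilities empirically through capture rates on list 1
  sh <- beta_shapes(0.2, 0.85)
  for (p in c("Mh", "Mt", "Mth", "Mtbh")) {
    hits <- vapply(1:60, function(r) {
      y <- simulate_sample(generator_spec(p, 5000, 0.2, seed = 7000 + r))
      # list-1 capture rate over the whole population (observed rows only
      # miss all-zero individuals, so count captures over true N)
      sum(y[, 1]) / 5000
    }, numeric(1))
    se <- stats::sd(hits) / sqrt(length(hits))
    expect_lt(abs(mean(hits) - 0.2), max(3 * se, 1e-3))
  }
})

test_that("behavioral reduction halves recapture rates on average", {
  # under Mb with cv = 0 the second-list capture probability is p for the
  # unseen and p/2 for those captured on list 1
  y <- simulate_sample(generator_spec("Mb", 50000, 0.2, cv = 0, seed = 5))
  caught1 <- y[, 1] == 1
  r_caught <- mean(y[caught1, 2])
  expect_lt(abs(r_caught - 0.1), 0.01)
})

test_that("frequency collapse counts truncated histories correctly", {
  m <- rbind(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0), c(0, 1, 0, 0, 0))
  tab5 <- collapse_frequencies(m, 5)
  expect_equal(unname(tab5$counts["10110"]), 2L)
  expect_equal(unname(tab5$counts["01000"]), 1L)
  expect_equal(tab5$n, 3L)
  tab2 <- collapse_frequencies(m, 2)
  expect_equal(unname(tab2$counts["10"]), 2L)
  expect_equal(unname(tab2$counts["01"]), 1L)
  # individuals seen only on dropped lists disappear
  m2 <- rbind(m, c(0, 0, 0, 0, 1))
  expect_equal(collapse_frequencies(m2, 2)$n, 3L)
  expect_error(collapse_frequencies(m, 6))
})

test_that("collapse agrees with a brute-force recount on random matrices", {
  set.seed(42)
  for (rep in 1:10) {
    y <- matrix(rbinom(40 * 5, 1, 0.3), 40, 5)
    y <- y[rowSums(y) > 0, , drop = FALSE]
    for (K_use in 2:5) {
      tab <- collapse_frequencies(y, K_use)
      strings <- apply(y[, 1:K_use, drop = FALSE], 1, paste, collapse = "")
      strings <- strings[strings != strrep("0", K_use)]
      expect_equal(tab$n, length(strings))
      brute <- table(strings)
      expect_equal(unname(tab$counts[names(brute)]),
                   unname(as.integer(brute)))
      expect_equal(sum(tab$counts) - tab$n, 0L)
    }
  }
})

test_that("encounter matrices and frequency tables survive CSV round trips", {
  dir <- withr::local_tempdir()
  em <- simulate_sample(generator_spec("Mbh", 400, 0.15, seed = 9))
  p1 <- file.path(dir, "em.csv")
  write_encounter_matrix(em, p1)
  back <- read_encounter_matrix(p1)
  expect_equal(unclass(back), unclass(em), ignore_attr = TRUE)
  expect_equal(attr(back, "true_N"), 400L)
  expect_equal(attr(back, "spec")$pattern, "Mbh")

  tab <- collapse_frequencies(em, 4)
  p2 <- file.path(dir, "tab.csv")
  write_frequency_table(tab, p2)
  expect_equal(read_frequency_table(p2)$counts, tab$counts)
})
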