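# independent oracle: marginal likelihood via full-table array margins and
# plain Dirichlet-multinomial normalizers per clique/separator
oracle_log_marginal <- function(model, table, n0, delta) {
  K <- table$K
  arr <- array(0, dim = rep(2, K))
  hist <- capture_histories(K)
  arr[1] <- n0  # all-zero cell: first element (R arrays are column-major)
  for (i in seq_len(nrow(hist)))
    arr[matrix(hist[i, ] + 1, 1)] <- table$counts[i]
  N <- sum(arr)
  dm <- function(members) {
    x <- if (length(members)) apply(arr, members, sum) else sum(arr)
    a <- rep(delta * 2^(K - length(members)), length(x))
    lgamma(sum(a)) - lgamma(sum(a) + N) + sum(lgamma(a + x) - lgamma(a))
  }
  out <- lgamma(N + 1) - sum(lgamma(arr + 1))
  for (cl in model$cliques) out <- out + dm(cl)
  for (sp in model$separators) out <- out - dm(sp)
  # a junction tree over all cliques needs n_components - 1 empty
  # separators, each contributing exactly zero
  out
}

test_that("saturated-model marginal equals the plain Dirichlet-multinomial", {
  tab <- frequency_table(stats::setNames(c(3, 1, 2, 0, 1, 2, 4),
                                         rownames(capture_histories(3))), 3)
  models <- enumerate_decomposable(3)
  sat <- models[[length(models)]]
  delta <- 2^-3
  for (n0 in c(0, 4, 17)) {
    x <- c(n0, as.numeric(tab$counts))
    N <- sum(x)
    direct <- lgamma(N + 1) - sum(lgamma(x + 1)) +
      lgamma(8 * delta) - lgamma(8 * delta + N) +
      sum(lgamma(delta + x) - lgamma(delta))
    expect_equal(log_marginal(sat, tab, n0, delta), direct,
                 tolerance = 1e-10)
  }
})

test_that("marginal likelihood matches the array-margin oracle on all models", {
  set.seed(8)
  tab <- frequency_table(rpois(7, 3), 3)
  for (m in enumerate_decomposable(3)) {
    for (n0 in c(0, 5)) {
      expect_equal(log_marginal(m, tab, n0),
                   oracle_log_marginal(m, tab, n0, 2^-3),
                   tolerance = 1e-10)
    }
  }
})

test_that("marginal likelihoods sum to one over the table partition", {
  # enumerate every completed two-list table with a fixed total: the
  # marginal must define a proper distribution over them
  K <- 2; total <- 6; delta <- 2^-K
  indep <- recapsim:::new_decomposable(K, matrix(integer(), 0, 2))
  sat <- recapsim:::new_decomposable(K, rbind(c(1, 2)))
  for (model in list(indep, sat)) {
    s <- 0
    for (n0 in 0:total) for (a in 0:(total - n0))
      for (b in 0:(total - n0 - a)) {
        cc <- total - n0 - a - b
        tab <- frequency_table(stats::setNames(c(b, a, cc),
                                               c("01", "10", "11")), K)
        s <- s + exp(log_marginal(model, tab, n0, delta))
      }
    expect_equal(s, 1, tolerance = 1e-10)
  }
})

test_that("list swap leaves a symmetric independence marginal unchanged", {
  indep <- recapsim:::new_decomposable(2, matrix(integer(), 0, 2))
  tab <- frequency_table(c("10" = 7, "01" = 2, "11" = 3), 2)
  swapped <- frequency_table(c("10" = 2, "01" = 7, "11" = 3), 2)
  expect_equal(log_marginal(indep, tab, 4), log_marginal(indep, swapped, 4),
               tolerance = 1e-12)
})

test_that("model-averaged posterior matches a brute-force computation", {
  set.seed(14)
  tab <- frequency_table(rpois(7, 4), 3)
  n0_max <- 60
  post <- bma_posterior(tab, n0_max)
  models <- enumerate_decomposable(3)
  # direct double loop, no caching, reciprocal prior
  W <- matrix(NA_real_, length(models), n0_max + 1)
  for (i in seq_along(models)) for (n0 in 0:n0_max)
    W[i, n0 + 1] <- oracle_log_marginal(models[[i]], tab, n0, 2^-3) -
      log(tab$n + n0)
  W <- exp(W - max(W))
  expect_equal(post$averaged_posterior, colSums(W) / sum(W),
               tolerance = 1e-10)
  expect_equal(post$model_posteriors, rowSums(W) / sum(W),
               tolerance = 1e-10)
  N <- tab$n + 0:n0_max
  cdf <- cumsum(colSums(W) / sum(W))
  expect_equal(post$N_hat, N[which(cdf >= 0.5)[1]])
})

test_that("posteriors are proper and single-model averaging collapses", {
  set.seed(2)
  tab <- frequency_table(rpois(7, 5) + 1L, 3)
  post <- bma_posterior(tab, 100)
  expect_equal(sum(post$averaged_posterior), 1, tolerance = 1e-12)
  expect_equal(sum(post$model_posteriors), 1, tolerance = 1e-12)
  expect_true(post$lower <= post$N_hat && post$N_hat <= post$upper)
  sat <- enumerate_decomposable(3)[[8]]
  single <- bma_posterior(tab, 100, models = list(sat))
  direct <- exp(vapply(0:100, function(n0)
    log_marginal(sat, tab, n0) - log(tab$n + n0), numeric(1)))
  expect_equal(single$averaged_posterior, direct / sum(direct),
               tolerance = 1e-10)
})

test_that("relabeling lists permutes models but not the averaged posterior", {
  set.seed(9)
  tab <- frequency_table(rpois(7, 6), 3)
  perm <- c(2, 3, 1)
  hist <- capture_histories(3)
  tab2 <- frequency_table(stats::setNames(
    as.integer(tab$counts),
    apply(hist[, perm], 1, paste, collapse = "")), 3)
  p1 <- bma_posterior(tab, 50)
  p2 <- bma_posterior(tab2, 50)
  expect_equal(p1$averaged_posterior, p2$averaged_posterior,
               tolerance = 1e-9)
  expect_equal(p1$N_hat, p2$N_hat)
})

test_that("estimate_bma respects the list-range restriction", {
  tab2 <- frequency_table(c("10" = 5, "01" = 5, "11" = 5), 2)
  est <- estimate_bma(tab2, 100)
  expect_true(est$failed)
  em <- simulate_sample(generator_spec("Mt", 500, 0.2, seed = 4))
  est3 <- estimate_bma(collapse_frequencies(em, 3), n0_max = 5000)
  expect_false(est3$failed)
  expect_gte(est3$N_hat, est3$n_observed)
})
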