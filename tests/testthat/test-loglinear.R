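test_that("design matrices have the documented columns", {
  expect_equal(ncol(llm_design("Mt", 3)), 4)       # intercept + 3 lists
  expect_equal(ncol(llm_design("M0", 2)), 2)       # intercept + captures
  expect_equal(ncol(llm_design("Mh", 5, "Poisson2")), 3)
  expect_equal(ncol(llm_design("Mbh", 5, "Darroch")), 4)
  expect_equal(ncol(llm_design("Mth", 4, "Gamma3.5")), 6)
  X <- llm_design("Mh", 5, "Poisson2")
  expect_equal(unname(X["11111", "Poisson2"]), 2^5 - 1)
  expect_equal(unname(X["00001", "Poisson2"]), 1)   # 2^1 - 1
  XD <- llm_design("Mh", 5, "Darroch")
  expect_equal(unname(XD["11111", "Darroch"]), 25 / 2)
  XG <- llm_design("Mh", 5, "Gamma3.5")
  expect_equal(unname(XG["00111", "Gamma3.5"]), -log(6.5) + log(3.5))
  Xb <- llm_design("Mb", 5)
  expect_equal(unname(Xb["01000", "behavioral"]), 3)  # first capture on list 2
  expect_error(llm_design("Mh", 5), "correction")
  expect_error(llm_design("Mt", 5, "Poisson2"), "correction")
  expect_error(llm_design("Mth", 2, "Poisson2"), "over-saturated")
})

test_that("two-list loglinear estimation equals the Petersen closed form", {
  tab <- frequency_table(c("10" = 20, "01" = 30, "11" = 10), 2)
  fit <- fit_loglinear(tab, "Mt")
  expect_equal(fit$N_hat, 30 * 40 / 10)  # n1 n2 / m
  # saturated model: fitted equals observed and the likelihood is maximal
  expect_equal(fit$loglik,
               sum(stats::dpois(c(20, 30, 10), c(20, 30, 10), log = TRUE)))
  set.seed(7)
  for (i in 1:20) {
    counts <- c(rpois(2, 30) + 1L, rpois(1, 10) + 1L)
    tab <- frequency_table(stats::setNames(counts, c("10", "01", "11")), 2)
    n1 <- counts[1] + counts[3]; n2 <- counts[2] + counts[3]
    expect_equal(fit_loglinear(tab, "Mt")$N_hat, n1 * n2 / counts[3],
                 tolerance = 1e-8)
  }
})

test_that("scaling a two-list table scales the unobserved part exactly", {
  tab1 <- frequency_table(c("10" = 12, "01" = 18, "11" = 6), 2)
  tab3 <- frequency_table(c("10" = 36, "01" = 54, "11" = 18), 2)
  f1 <- fit_loglinear(tab1, "Mt"); f3 <- fit_loglinear(tab3, "Mt")
  expect_equal(3 * (f1$N_hat - tab1$n), f3$N_hat - tab3$n, tolerance = 1e-8)
})

test_that("IRLS maximum matches a brute-force optimizer", {
  set.seed(31)
  cases <- list(list("Mh", "Poisson2", 4), list("Mb", "none", 4),
                list("Mt", "none", 3), list("Mbh", "Darroch", 5))
  for (cs in cases) {
    tab <- random_table(cs[[3]])
    fit <- fit_loglinear(tab, cs[[1]], cs[[2]])
    X <- llm_design(cs[[1]], cs[[3]], cs[[2]])
    opt <- stats::optim(rep(0, ncol(X)), pois_loglik, X = X,
                        y = as.numeric(tab$counts),
                        control = list(fnscale = -1, maxit = 5000,
                                       reltol = 1e-14),
                        method = "BFGS")
    expect_equal(fit$loglik, opt$value, tolerance = 1e-6)
  }
})

test_that("fitted totals preserve the observed count", {
  set.seed(12)
  for (i in 1:5) {
    tab <- random_table(4)
    for (lab in c("M0", "Mt", "Mh", "Mb")) {
      corr <- if (lab == "Mh") "Poisson2" else "none"
      fit <- fit_loglinear(tab, lab, corr)
      X <- llm_design(lab, 4, corr)
      mu <- exp(drop(X %*% fit$coefficients))
      expect_equal(sum(mu), tab$n, tolerance = 1e-6)
    }
  }
})

test_that("AIC of exchangeable models is invariant to list relabeling", {
  set.seed(5)
  tab <- random_table(4)
  perm <- c(3, 1, 4, 2)
  hist <- capture_histories(4)
  permuted <- hist[, perm]
  relabeled <- stats::setNames(
    as.integer(tab$counts),
    apply(permuted, 1, paste, collapse = ""))
  tab2 <- frequency_table(relabeled, 4)
  for (lab in c("M0", "Mh")) {
    corr <- if (lab == "Mh") "Poisson2" else "none"
    expect_equal(fit_loglinear(tab, lab, corr)$aic,
                 fit_loglinear(tab2, lab, corr)$aic, tolerance = 1e-8)
    expect_equal(fit_loglinear(tab, lab, corr)$N_hat,
                 fit_loglinear(tab2, lab, corr)$N_hat, tolerance = 1e-8)
  }
})

test_that("the behavioral-model estimator is consistent under its model", {
  # expected cell means under homogeneous Mb (p = 0.2 first capture,
  # halved afterwards): the corrected extrapolation recovers N exactly
  K <- 5; N <- 1000; p <- 0.2; pb <- 0.1
  hist <- capture_histories(K)
  mu <- N * apply(hist, 1, function(w) {
    f <- which.max(w == 1); cc <- sum(w)
    (1 - p)^(f - 1) * p * pb^(cc - 1) * (1 - pb)^(K - f - (cc - 1))
  })
  tab <- frequency_table(round(mu * 1e6), K)  # huge table kills MC error
  fit <- fit_loglinear(tab, "Mb")
  expect_equal(fit$N_hat / 1e6, N, tolerance = 1e-3)
})

test_that("AIC selection obeys the tie-breaking rules", {
  fake <- function(label, aic, npar) {
    structure(list(label = label, correction = "none", K = 5,
                   loglik = 0, aic = aic, n_observed = 10, N_hat = 20,
                   converged = TRUE, npar = npar), class = "llm_fit")
  }
  expect_equal(select_best(list(fake("Mh", 10, 3), fake("Mt", 12, 6)))$label,
               "Mh")
  # exact tie: fewer parameters wins
  expect_equal(select_best(list(fake("Mbh", 10, 4), fake("Mh", 10, 3)))$label,
               "Mh")
  # full tie: fixed label order
  expect_equal(select_best(list(fake("Mh", 10, 3), fake("Mb", 10, 3)))$label,
               "Mb")
  bad <- fake("Mt", 1, 6); bad$converged <- FALSE
  expect_equal(select_best(list(bad, fake("Mh", 10, 3)))$label, "Mh")
  expect_error(select_best(list(bad)), "converged")
})

test_that("candidate sets depend on the number of lists", {
  expect_setequal(llm_candidates(2)$label, c("M0", "Mt"))
  c5 <- llm_candidates(5)
  expect_setequal(c5$label, c("Mb", "Mt", "Mh", "Mbh", "Mth"))
  expect_true(all(c5$correction[grepl("h", c5$label)] == "Poisson2"))
  expect_true(all(c5$correction[!grepl("h", c5$label)] == "none"))
})

test_that("profile intervals behave around the point estimate", {
  tab <- frequency_table(c("10" = 20, "01" = 30, "11" = 10), 2)
  ci <- profile_ci(tab, "Mt")
  expect_lte(ci$lower, 120); expect_gte(ci$upper, 120)
  expect_false(ci$capped)
  # deviance at the profile maximizer is within the chi-square threshold
  # of itself by construction; the reported maximizer is near N_hat
  expect_lt(abs(ci$N_profile - 120), 10)
  # a monotone/flat profile hits the cap and is flagged
  flat <- frequency_table(c("10" = 20, "01" = 30, "11" = 0), 2)
  expect_error(fit_loglinear(flat, "Mt"), NA)
  ci2 <- profile_ci(flat, "Mt", N_max = 2000)
  expect_true(ci2$capped)
  expect_equal(ci2$upper, 2000)
})

test_that("profile interval coverage is near nominal under a true M0", {
  # correctly specified homogeneous model: coverage should sit near 0.95
  hits <- 0; reps <- 60; N <- 400
  for (r in 1:60) {
    em <- simulate_sample(generator_spec("Mh", N, 0.2, K = 3, cv = 0,
                                         seed = 400 + r))
    tab <- collapse_frequencies(em, 3)
    ci <- profile_ci(tab, "M0")
    hits <- hits + (ci$lower <= N && ci$upper >= N)
  }
  expect_gte(hits / reps, 0.85)
})

test_that("estimate_llm_aic returns a full result row", {
  em <- simulate_sample(generator_spec("Mh", 800, 0.2, seed = 21))
  tab <- collapse_frequencies(em, 5)
  est <- estimate_llm_aic(tab)
  expect_s3_class(est, "estimate_result")
  expect_false(est$failed)
  expect_true(est$model_label %in% c("Mb", "Mt", "Mh", "Mbh", "Mth"))
  expect_true(est$ci_low <= est$N_hat || is.na(est$ci_low))
  expect_gte(est$N_hat, tab$n)
})
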