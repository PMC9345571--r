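LLM_LABELS <- c("M0", "Mt", "Mb", "Mh", "Mbh", "Mth")
LLM_CORRECTIONS <- c("none", "Poisson2", "Darroch", "Gamma3.5")

correction_column <- function(correction, caps) {
  switch(correction,
         none = NULL,
         Poisson2 = 2^caps - 1,
         Darroch = caps^2 / 2,
         Gamma3.5 = -log(caps + 3.5) + log(3.5))
}

#' Loglinear design matrix over the observable capture histories
#'
#' Builds the model matrix of the Poisson loglinear model for the
#' \eqn{2^K - 1} observable histories (row order as in
#' [capture_histories()]).  All covariates vanish at the unobservable
#' all-zero history, so the intercept alone extrapolates to the unobserved
#' cell and \eqn{\hat N = n + e^{\hat\beta_0}}.
#'
#' Columns by model label (c = number of captures in the history):
#' * `M0`, `Mh`: intercept + c;
#' * `Mt`, `Mth`: intercept + one indicator per list;
#' * `Mb`, `Mbh`: intercept + c + behavioral exposure `K - f` where `f` is
#'   the list of first capture;
#' * models containing `h` append one heterogeneity-correction column, a
#'   fixed function of c: `Poisson2` \eqn{2^c - 1}, `Darroch` \eqn{c^2/2},
#'   `Gamma3.5` \eqn{-\log(c + 3.5) + \log 3.5}.
#'
#' @param label one of `"M0"`, `"Mt"`, `"Mb"`, `"Mh"`, `"Mbh"`, `"Mth"`.
#' @param K number of lists.
#' @param correction heterogeneity correction, required for labels
#'   containing `h` and disallowed otherwise.
#' @return numeric design matrix with `2^K - 1` rows.
#' @export
llm_design <- function(label, K, correction = "none") {
  label <- match.arg(label, LLM_LABELS)
  correction <- match.arg(correction, LLM_CORRECTIONS)
  has_h <- grepl("h", label)
  if (has_h && correction == "none")
    stop("heterogeneity models need a correction column")
  if (!has_h && correction != "none")
    stop("correction only applies to models containing \"h\"")
  hist <- capture_histories(K)
  caps <- rowSums(hist)
  cols <- list(`(Intercept)` = rep(1, nrow(hist)))
  if (label %in% c("Mt", "Mth")) {
    for (k in seq_len(K)) cols[[paste0("list_", k)]] <- hist[, k]
  } else {
    cols$captures <- caps
  }
  if (grepl("b", label)) {
    first <- apply(hist == 1L, 1L, which.max)
    cols$behavioral <- K - first
  }
  if (has_h) cols[[correction]] <- correction_column(correction, caps)
  X <- do.call(cbind, cols)
  if (ncol(X) > 2^K - 1)
    stop("model over-saturated for K = ", K)
  rownames(X) <- rownames(hist)
  X
}

# Estimated mean of the unobservable all-zero cell.  Every covariate
# vanishes on the all-zero history, so for most models this is
# exp(intercept).  For the behavioral models the intercept alone is not a
# consistent extrapolation: under the Mb likelihood the slope of the
# capture count is logit(p_b) (the post-first-capture log-odds) and the
# slope of the behavioral-exposure column is log(1-p_b) - log(1-p), which
# identify both probabilities, and the all-zero-cell mean
# N (1-p)^K equals exp(intercept) * (p_b / (1-p_b)) * ((1-p) / p).
# Applying that factor makes the Mb estimator exact under its own model.
# It is NOT applied to Mbh: there the heterogeneity-correction column
# contaminates the slope-based recovery of (p, p_b), and the factor
# over-corrects (asymptotically about -32% under beta-heterogeneous Mbh
# truth versus about -10% for the plain intercept extrapolation).
unobserved_cell_mean <- function(label, coefs) {
  mu0 <- exp(coefs[["(Intercept)"]])
  if (label != "Mb") return(mu0)
  p_b <- stats::plogis(coefs[["captures"]])
  q <- (1 - p_b) * exp(-coefs[["behavioral"]])  # estimate of 1 - p
  if (!is.finite(q) || q <= 0 || q >= 1) return(NaN)
  mu0 * (p_b / (1 - p_b)) * (q / (1 - q))
}

#' Fit a closed-population loglinear model by Poisson regression
#'
#' Maximizes the Poisson likelihood of the observed cell counts over the
#' design of [llm_design()] (iteratively reweighted least squares, as in
#' standard GLM fitting).  The abundance estimate is
#' \eqn{\hat N = n + e^{\hat\beta_0}}: the intercept estimates the log mean
#' of the unobservable all-zero cell.  Zero-heavy tables can produce
#' astronomically large (effectively infinite) estimates; these are
#' reported as-is, never truncated.
#'
#' @param table a [frequency_table()].
#' @param label model label, see [llm_design()].
#' @param correction heterogeneity correction for `h` models.
#' @return object of class `llm_fit`: list with `label`, `correction`, `K`,
#'   `coefficients`, `loglik`, `aic`, `n_observed`, `N_hat`, `converged`,
#'   `npar`.
#' @export
#' @examples
#' # two-list table: equivalent to the Petersen estimator n1 * n2 / m
#' tab <- frequency_table(c("10" = 20, "01" = 30, "11" = 10), K = 2)
#' fit_loglinear(tab, "Mt")$N_hat  # 120
fit_loglinear <- function(table, label, correction = "none") {
  stopifnot(inherits(table, "frequency_table"))
  X <- llm_design(label, table$K, correction)
  y <- as.numeric(table$counts)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::poisson())),
    error = function(e) NULL)
  npar <- ncol(X)
  if (is.null(fit) || fit$rank < npar ||
      !all(is.finite(fit$coefficients))) {
    return(structure(list(label = label, correction = correction,
                          K = table$K, coefficients = NULL, loglik = NA_real_,
                          aic = NA_real_, n_observed = table$n,
                          N_hat = NA_real_, converged = FALSE, npar = npar),
                     class = "llm_fit"))
  }
  mu <- fit$fitted.values
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  coefs <- stats::setNames(fit$coefficients, colnames(X))
  structure(list(label = label, correction = correction, K = table$K,
                 coefficients = coefs, loglik = ll,
                 aic = -2 * ll + 2 * npar, n_observed = table$n,
                 N_hat = table$n + unobserved_cell_mean(label, coefs),
                 converged = isTRUE(fit$converged), npar = npar),
            class = "llm_fit")
}

#' @export
print.llm_fit <- function(x, ...) {
  cat(sprintf("Loglinear fit %s%s (K = %d): N_hat = %.1f, AIC = %.2f%s\n",
              x$label,
              if (x$correction != "none") paste0("/", x$correction) else "",
              x$K, x$N_hat, x$aic,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Candidate model set for AIC selection
#'
#' For three or more lists the candidate set is `{Mb, Mt, Mh, Mbh, Mth}`
#' with the chosen heterogeneity correction.  With only two lists just
#' `{M0, Mt}` are estimable from the three observable cells, so the set is
#' restricted to those.
#'
#' @param K number of lists.
#' @param correction heterogeneity correction used for `h` models.
#' @return data frame with columns `label` and `correction`.
#' @export
llm_candidates <- function(K, correction = "Poisson2") {
  if (K < 2) stop("need at least two lists")
  if (K == 2) {
    data.frame(label = c("M0", "Mt"), correction = "none")
  } else {
    labels <- c("Mb", "Mt", "Mh", "Mbh", "Mth")
    data.frame(label = labels,
               correction = ifelse(grepl("h", labels), correction, "none"))
  }
}

#' Select the AIC-best loglinear fit
#'
#' Returns the converged fit with the smallest AIC.  Exact ties go to the
#' model with fewer parameters, then to the fixed label order
#' `M0, Mt, Mb, Mh, Mbh, Mth`.
#'
#' @param fits list of `llm_fit` objects.
#' @return the selected `llm_fit`.
#' @export
select_best <- function(fits) {
  ok <- Filter(function(f) isTRUE(f$converged) && is.finite(f$aic), fits)
  if (!length(ok)) stop("no converged loglinear fit to select from")
  aic <- vapply(ok, `[[`, numeric(1), "aic")
  npar <- vapply(ok, `[[`, numeric(1), "npar")
  rank <- match(vapply(ok, `[[`, character(1), "label"), LLM_LABELS)
  ok[[order(aic, npar, rank)[1]]]
}

# multinomial profile log-likelihood of a candidate total N:
# Poisson GLM over all 2^K cells with the all-zero cell holding N - n,
# corrected by the Poisson-to-multinomial term in the total.
profile_loglik <- function(N, X0, y_obs, n) {
  yy <- c(N - n, y_obs)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X0, yy, family = stats::poisson())),
    error = function(e) NULL)
  if (is.null(fit)) return(-Inf)
  mu <- fit$fitted.values
  sum(ifelse(yy > 0, yy * log(mu), 0)) - sum(mu) - sum(lgamma(yy + 1)) +
    lgamma(N + 1) - N * log(N) + N
}

#' Profile-likelihood interval for the population size
#'
#' Profiles the multinomial likelihood of a loglinear model over candidate
#' integer totals \eqn{N}: for each \eqn{N} the all-zero cell is completed
#' with \eqn{N - n} and the loglinear parameters are re-maximized.  The
#' interval is the set of \eqn{N} whose profile deviance lies within the
#' \eqn{\chi^2_1} quantile of the maximum.  The search is a coarse
#' geometric grid refined by bisection; the upper bound is capped at
#' `N_max` (default `21 * n`) and the cap is flagged when hit.
#'
#' @param table a [frequency_table()].
#' @param label,correction model specification as in [fit_loglinear()].
#' @param level confidence level (0.95 in the study).
#' @param N_max ceiling on the profiled total.
#' @return list with `lower`, `upper`, `N_profile` (profile maximizer),
#'   `capped` (logical), `level`.
#' @export
profile_ci <- function(table, label, correction = "none", level = 0.95,
                       N_max = NULL) {
  stopifnot(inherits(table, "frequency_table"))
  X <- llm_design(label, table$K, correction)
  X0 <- rbind(c(1, rep(0, ncol(X) - 1)), X)  # all-zero cell first
  y <- as.numeric(table$counts)
  n <- table$n
  if (n == 0) stop("empty table")
  if (is.null(N_max)) N_max <- 21 * n
  N_max <- max(N_max, n + 1)

  ll <- function(N) profile_loglik(N, X0, y, n)
  grid <- unique(round(exp(seq(log(n), log(N_max), length.out = 80))))
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  # refine the maximizer between the neighbours of the best grid point
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  while (hi - lo > 2) {
    m1 <- lo + (hi - lo) %/% 3; m2 <- hi - (hi - lo) %/% 3
    if (ll(m1) < ll(m2)) lo <- m1 else hi <- m2
  }
  cand <- lo:hi
  best <- cand[which.max(vapply(cand, ll, numeric(1)))]
  ll_max <- max(ll(best), vals[i])
  thresh <- ll_max - stats::qchisq(level, 1) / 2

  bisect <- function(inside, outside) {
    # invariant: ll(inside) >= thresh > ll(outside)
    while (abs(inside - outside) > 1) {
      mid <- (inside + outside) %/% 2
      if (ll(mid) >= thresh) inside <- mid else outside <- mid
    }
    inside
  }
  lower <- if (ll(n) >= thresh) n else bisect(best, n)
  capped <- FALSE
  if (ll(N_max) >= thresh) {
    upper <- N_max; capped <- TRUE
  } else {
    upper <- bisect(best, N_max)
  }
  list(lower = lower, upper = upper, N_profile = best, capped = capped,
       level = level)
}

#' AIC-selected loglinear estimate of population size (LLM-AIC)
#'
#' Fits the candidate set of [llm_candidates()], selects the AIC-best
#' converged model and (optionally) computes its profile-likelihood
#' interval.
#'
#' @param table a [frequency_table()].
#' @param correction heterogeneity correction for `h` models (`"Poisson2"`,
#'   the study default, `"Darroch"` or `"Gamma3.5"`).
#' @param level confidence level for the interval.
#' @param ci compute the profile interval? (skipping it is much faster when
#'   only point estimates are needed).
#' @param N_max cap passed to [profile_ci()].
#' @return an `estimate_result` (see [estimate_result()]): method
#'   `"LLM-AIC"`, the selected model label, point estimate and interval.
#' @export
estimate_llm_aic <- function(table, correction = "Poisson2", level = 0.95,
                             ci = TRUE, N_max = NULL) {
  cand <- llm_candidates(table$K, correction)
  fits <- Map(function(l, co) fit_loglinear(table, l, co),
              cand$label, cand$correction)
  best <- tryCatch(select_best(fits), error = function(e) NULL)
  if (is.null(best)) {
    return(estimate_result("LLM-AIC", NA_real_, NA_real_, NA_real_,
                           n_observed = table$n, failed = TRUE))
  }
  lowup <- c(NA_real_, NA_real_)
  if (ci) {
    pci <- tryCatch(
      profile_ci(table, best$label, best$correction, level, N_max),
      error = function(e) NULL)
    if (!is.null(pci)) lowup <- c(pci$lower, pci$upper)
  }
  estimate_result("LLM-AIC", best$N_hat, lowup[1], lowup[2],
                  n_observed = table$n, model_label = best$label,
                  aic = best$aic, failed = !is.finite(best$N_hat))
}
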