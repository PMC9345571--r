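subset_mask <- function(members) sum(2^(members - 1))

# Margin bookkeeping for one subset of lists: total prior mass is spread as
# delta per full-table cell, so a margin cell over subset A carries
# delta * 2^(K - |A|).  Only the all-zero margin cell absorbs the
# unobserved count n0, which keeps the grid computation cheap.
margin_info <- function(table, members, delta) {
  K <- table$K
  hist <- capture_histories(K)
  a <- delta * 2^(K - length(members))
  sub <- hist[, members, drop = FALSE]
  idx <- as.integer(sub %*% 2^(seq_along(members) - 1))  # 0 = all-zero margin
  x <- vapply(0:(2^length(members) - 1),
              function(i) sum(table$counts[idx == i]), numeric(1))
  list(alpha = a,
       x0 = x[1],
       const = sum(lgamma(a + x[-1]) - lgamma(a)))
}

# log Dirichlet-multinomial contribution of one subset, vectorized over n0;
# the lgamma(M) - lgamma(M + N) normalizer is accounted for separately
# (once per connected component of the model graph).
margin_term <- function(info, n0) {
  info$const + lgamma(info$alpha + info$x0 + n0) - lgamma(info$alpha)
}

#' Hyper-Dirichlet log marginal likelihood of a completed table
#'
#' Log marginal likelihood of the observed capture-history counts completed
#' with `n0` individuals in the unobservable all-zero cell, under a
#' decomposable loglinear model with a hyper-Dirichlet prior whose
#' hyperparameter is `delta` per cell of the full \eqn{2^K} table
#' (clique and separator margins inherit consistent sums of the cell
#' masses).  The value is
#' \deqn{\log \binom{N}{x_1 \cdots x_{2^K}} + \sum_C \log DM(x_C) -
#'       \sum_S \log DM(x_S),}
#' with \eqn{N = n + n_0}, computed entirely in log-Gamma space; the
#' saturated model (single clique of all lists) reduces to the plain
#' Dirichlet-multinomial marginal of the full table.
#'
#' @param model a `decomposable_model` from [enumerate_decomposable()].
#' @param table a [frequency_table()] on the same number of lists.
#' @param n0 nonnegative unobserved count (vectorized).
#' @param delta prior mass per full-table cell; the study uses
#'   \eqn{2^{-K}} so the total prior mass is 1.
#' @return log marginal likelihood, same length as `n0`.
#' @export
log_marginal <- function(model, table, n0, delta = 2^-table$K) {
  stopifnot(inherits(model, "decomposable_model"),
            inherits(table, "frequency_table"), model$K == table$K)
  if (any(n0 < 0)) stop("n0 must be nonnegative")
  N <- table$n + n0
  M <- delta * 2^table$K
  out <- model$n_components * (lgamma(M) - lgamma(M + N)) +
    lgamma(N + 1) - lgamma(n0 + 1) - sum(lgamma(table$counts + 1))
  for (cl in model$cliques)
    out <- out + margin_term(margin_info(table, cl, delta), n0)
  for (sp in model$separators)
    out <- out - margin_term(margin_info(table, sp, delta), n0)
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bayesian model averaging over decomposable loglinear models (LLM-BMA)
#'
#' Computes, on an exact integer grid of the unobserved count
#' \eqn{n_0 = 0, \dots, n_{0,max}}, the posterior
#' \eqn{p(n_0, m \mid x) \propto p(N) \, p(x, n_0 \mid m)} for every
#' decomposable model \eqn{m} (uniform model prior), and averages the
#' model-specific posteriors by their posterior model probabilities.  The
#' point estimate is the posterior median of \eqn{N = n + n_0} and the
#' interval the central `level` quantiles.
#'
#' The prior on \eqn{N} is either reciprocal (\eqn{p(N) \propto 1/N},
#' the default) or uniform, truncated to the grid; the study caps the grid
#' at ten times the true population size.
#'
#' @param table a [frequency_table()] on 3-5 lists.
#' @param n0_max grid cap on the unobserved count.
#' @param delta hyper-Dirichlet cell mass, default \eqn{2^{-K}}.
#' @param prior `"reciprocal"` or `"uniform"` prior on N.
#' @param models optional model list (defaults to the full enumeration);
#'   a single-model list collapses the average onto that model.
#' @param level credible level for the interval.
#' @return object of class `bma_posterior`: list with `n0_values`,
#'   `averaged_posterior` (probabilities over the grid), `model_posteriors`,
#'   `models`, `N_hat`, `lower`, `upper`, `n_observed`, `level`.
#' @export
bma_posterior <- function(table, n0_max, delta = 2^-table$K,
                          prior = c("reciprocal", "uniform"),
                          models = NULL, level = 0.95) {
  stopifnot(inherits(table, "frequency_table"), n0_max >= 0)
  prior <- match.arg(prior)
  if (is.null(models)) {
    if (table$K < 3 || table$K > 5)
      stop("model averaging supports 3-5 lists")
    models <- enumerate_decomposable(table$K)
  }
  n <- table$n
  n0 <- 0:n0_max
  N <- n + n0
  M <- delta * 2^table$K
  log_prior <- if (prior == "reciprocal") -log(N) else rep(0, length(N))
  shared <- lgamma(M) - lgamma(M + N)
  coeff <- lgamma(N + 1) - lgamma(n0 + 1) - sum(lgamma(table$counts + 1))

  # models share margins heavily: compute one grid vector per distinct
  # subset of lists and combine them per model with a +1 (clique) / -1
  # (separator) coefficient matrix, so the whole model sweep is one
  # matrix product
  masks <- sort(unique(unlist(lapply(models, function(m)
    c(vapply(m$cliques, subset_mask, numeric(1)),
      vapply(m$separators, subset_mask, numeric(1)))))))
  members_of <- function(mask) which(bitwAnd(mask, 2^(0:(table$K - 1))) > 0)
  term_mat <- t(vapply(masks, function(mask)
    margin_term(margin_info(table, members_of(mask), delta), n0),
    numeric(length(n0))))
  coef_mat <- matrix(0, length(models), length(masks))
  comp <- integer(length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    comp[i] <- m$n_components
    for (cl in m$cliques) {
      j <- match(subset_mask(cl), masks)
      coef_mat[i, j] <- coef_mat[i, j] + 1
    }
    for (sp in m$separators) {
      j <- match(subset_mask(sp), masks)
      coef_mat[i, j] <- coef_mat[i, j] - 1
    }
  }
  L <- coef_mat %*% term_mat + outer(comp, shared)
  L <- sweep(L, 2, coeff + log_prior, "+")
  shift <- max(L)
  if (!is.finite(shift)) stop("all models degenerate on this table")
  W <- exp(L - shift)
  model_post <- rowSums(W)
  averaged <- colSums(W)
  model_post <- model_post / sum(model_post)
  averaged <- averaged / sum(averaged)

  cdf <- cumsum(averaged)
  qn <- function(p) N[which(cdf >= p)[1]]
  structure(list(n0_values = n0, averaged_posterior = averaged,
                 model_posteriors = model_post, models = models,
                 N_hat = qn(0.5),
                 lower = qn((1 - level) / 2), upper = qn(1 - (1 - level) / 2),
                 n_observed = n, level = level),
            class = "bma_posterior")
}

#' @export
print.bma_posterior <- function(x, ...) {
  cat(sprintf("Model-averaged posterior over %d decomposable models: N_hat = %d (%g%% interval %d-%d)\n",
              length(x$models), x$N_hat, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' Write an averaged posterior as CSV (`n0`, `probability`)
#' @param x a `bma_posterior`.
#' @param path file path.
#' @export
write_bma_posterior <- function(x, path) {
  utils::write.csv(data.frame(n0 = x$n0_values,
                              probability = x$averaged_posterior),
                   path, row.names = FALSE)
  invisible(path)
}

#' LLM-BMA estimate of population size
#'
#' Wrapper around [bma_posterior()] returning an [estimate_result()].
#'
#' @inheritParams bma_posterior
#' @export
estimate_bma <- function(table, n0_max, delta = 2^-table$K,
                         prior = "reciprocal", level = 0.95) {
  post <- tryCatch(
    bma_posterior(table, n0_max, delta, prior, level = level),
    error = function(e) NULL)
  if (is.null(post)) {
    return(estimate_result("LLM-BMA", NA_real_, NA_real_, NA_real_,
                           n_observed = table$n, failed = TRUE))
  }
  estimate_result("LLM-BMA", post$N_hat, post$lower, post$upper,
                  n_observed = table$n)
}
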