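#' Chain control for the Bayesian latent-class estimator
#'
#' The study configuration (`preset = "paper_full"`) discards 500,000
#' burn-in iterations and retains 50,000 of 5,000,000 post-burn-in
#' iterations after thinning by 100; it takes hours per sample.  Far fewer
#' iterations are typically required in practice, so the default preset
#' uses a 10,000-iteration burn-in and 10,000 retained draws (100,000
#' iterations thinned by 10), and `"desk"` is a lighter setting suited to
#' replicated simulation sweeps.
#'
#' @param max_classes truncation level of the stick-breaking mixture
#'   (10 in the study).
#' @param a,b shape and rate of the Gamma hyperprior on the Dirichlet
#'   process concentration (both 0.25 in the study).
#' @param burn_in,iterations,thin chain lengths; `iterations / thin` draws
#'   are kept.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param preset `"default"`, `"desk"` or `"paper_full"` chain lengths,
#'   overridden by any explicitly supplied value.
#' @return object of class `blcm_config`.
#' @export
blcm_config <- function(max_classes = 10L, a = 0.25, b = 0.25,
                        burn_in = NULL, iterations = NULL, thin = NULL,
                        seed = NULL,
                        preset = c("default", "desk", "paper_full")) {
  preset <- match.arg(preset)
  len <- switch(preset,
                default = c(10000L, 100000L, 10L),
                desk = c(2000L, 20000L, 10L),
                paper_full = c(500000L, 5000000L, 100L))
  burn_in <- as.integer(if (is.null(burn_in)) len[1] else burn_in)
  iterations <- as.integer(if (is.null(iterations)) len[2] else iterations)
  thin <- as.integer(if (is.null(thin)) len[3] else thin)
  stopifnot(max_classes >= 1, a > 0, b > 0, burn_in >= 0, thin >= 1,
            iterations >= thin)
  structure(list(max_classes = as.integer(max_classes), a = a, b = b,
                 burn_in = burn_in, iterations = iterations, thin = thin,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "blcm_config")
}

#' Bayesian nonparametric latent-class estimation of population size (BLCM)
#'
#' Fits a truncated stick-breaking Dirichlet-process mixture of
#' product-Bernoulli capture profiles to individual capture histories by
#' Gibbs sampling, augmenting the data with the unobserved (all-zero)
#' individuals.  One sweep updates, in turn: class assignments (observed
#' individuals grouped by distinct history, plus the augmented all-zero
#' group), per-class per-list capture probabilities (conjugate Beta),
#' stick-breaking fractions, the concentration parameter (Gamma
#' conditional), and the unobserved count \eqn{n_0} from its
#' negative-binomial conditional given the mixture probability of the
#' all-zero history under a reciprocal prior on \eqn{N}.
#'
#' The point estimate is the posterior median of \eqn{N = n + n_0} and the
#' interval the central `level` quantiles of the retained draws.
#'
#' @param matrix an `encounter_matrix` (or 0/1 matrix) of observed
#'   individual histories; truncate with [truncate_lists()] first if fewer
#'   lists are to be used.
#' @param config a [blcm_config()].
#' @param level credible level.
#' @return object of class `blcm_fit`: list with posterior draws (`N`,
#'   `n0`, `alpha`, `p0`, `occupied`), `N_hat`, `lower`, `upper`,
#'   `n_observed`, `config`.
#' @export
run_blcm <- function(matrix, config = blcm_config(), level = 0.95) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2, nrow(matrix) >= 1,
            inherits(config, "blcm_config"))
  y <- unclass(matrix)
  storage.mode(y) <- "integer"
  if (any(rowSums(y) == 0)) stop("all-zero histories are unobservable")
  idx <- history_index(y)
  tab <- table(idx)
  hidx <- as.integer(names(tab))
  hist <- capture_histories(ncol(y))[hidx, , drop = FALSE]
  freq <- as.integer(tab)
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- blcm_gibbs(hist, freq, config$max_classes, config$a, config$b,
                    config$burn_in, config$iterations, config$thin)
  if (out$underflow > 0)
    warning(sprintf("all-zero-history probability underflowed to 0 in %d iterations; n0 drawn as 0 there",
                    out$underflow))
  q <- stats::quantile(out$N, c((1 - level) / 2, 0.5, 1 - (1 - level) / 2),
                       names = FALSE, type = 1)
  structure(list(N = out$N, n0 = out$n0, alpha = out$alpha, p0 = out$p0,
                 occupied = out$occupied,
                 N_hat = q[2], lower = q[1], upper = q[3],
                 n_observed = sum(freq), level = level, config = config),
            class = "blcm_fit")
}

#' @export
print.blcm_fit <- function(x, ...) {
  cat(sprintf("Latent-class posterior (%d draws): N_hat = %d (%g%% interval %d-%d)\n",
              length(x$N), x$N_hat, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' Convergence diagnostics for a posterior trace
#'
#' Effective sample size from the initial positive sequence of
#' autocorrelations, the lag-1 autocorrelation, and the split-chain
#' potential scale reduction factor computed on `log(trace)`.
#' A constant trace is flagged as degenerate.
#'
#' @param trace numeric vector of posterior draws (e.g. `fit$N`).
#' @return list with `ess`, `lag1_autocorr`, `rhat`, `degenerate`.
#' @export
trace_diagnostics <- function(trace) {
  stopifnot(is.numeric(trace), length(trace) >= 2)
  m <- length(trace)
  if (stats::var(trace) == 0)
    return(list(ess = NA_real_, lag1_autocorr = NA_real_, rhat = NA_real_,
                degenerate = TRUE))
  rho <- stats::acf(trace, lag.max = min(m - 1, 1000), plot = FALSE)$acf[-1]
  lag1 <- rho[1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  ess <- m / (1 + 2 * sum(rho))
  # scale reduction on the log scale (population sizes are positive);
  # fall back to the raw scale for traces that are not
  lt <- if (all(trace > 0)) log(trace) else trace
  half <- m %/% 2
  chains <- list(lt[seq_len(half)], lt[(m - half + 1):m])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  rhat <- if (W > 0) sqrt(((half - 1) / half * W + B / half) / W) else NA_real_
  list(ess = ess, lag1_autocorr = lag1, rhat = rhat, degenerate = FALSE)
}

#' BLCM estimate of population size
#'
#' Wrapper around [run_blcm()] returning an [estimate_result()].
#'
#' @inheritParams run_blcm
#' @export
estimate_blcm <- function(matrix, config = blcm_config(), level = 0.95) {
  fit <- tryCatch(run_blcm(matrix, config, level), error = function(e) NULL)
  if (is.null(fit)) {
    return(estimate_result("BLCM", NA_real_, NA_real_, NA_real_,
                           n_observed = nrow(matrix), failed = TRUE))
  }
  estimate_result("BLCM", fit$N_hat, fit$lower, fit$upper,
                  n_observed = fit$n_observed)
}
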