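#' Beta shape parameters from a mean and coefficient of variation
#'
#' Solves for the shape parameters \eqn{(\beta_1, \beta_2)} of a Beta
#' distribution with the requested mean \eqn{m} and coefficient of variation
#' \eqn{cv} (standard deviation divided by the mean).  The closed form is
#' \deqn{s = (1 - m) / (m\,cv^2) - 1, \quad \beta_1 = m s, \quad
#'   \beta_2 = (1 - m) s,}
#' which exists whenever \eqn{m (1 + cv^2) < 1}.
#'
#' These Beta distributions drive the encounter-probability heterogeneity of
#' the simulated populations: the study design uses means 0.025, 0.050,
#' 0.100, 0.150 and 0.200 with a common coefficient of variation of 0.85.
#'
#' @param mean_p mean encounter probability, in (0, 1).
#' @param cv coefficient of variation of the encounter probability, > 0.
#' @return object of class `beta_shape`: list with fields `beta1`, `beta2`.
#' @export
#' @examples
#' beta_shapes(0.025, 0.85)   # beta1 = 1.3245, beta2 = 51.6548
beta_shapes <- function(mean_p, cv) {
  stopifnot(is.numeric(mean_p), length(mean_p) == 1L,
            is.numeric(cv), length(cv) == 1L)
  if (mean_p <= 0 || mean_p >= 1) stop("`mean_p` must lie in (0, 1)")
  if (cv <= 0) stop("`cv` must be positive")
  if (mean_p * (1 + cv^2) >= 1)
    stop("infeasible (mean, cv): need mean_p * (1 + cv^2) < 1")
  s <- (1 - mean_p) / (mean_p * cv^2) - 1
  beta_shape(mean_p * s, (1 - mean_p) * s)
}

#' @rdname beta_shapes
#' @param beta1,beta2 positive shape parameters.
#' @export
beta_shape <- function(beta1, beta2) {
  stopifnot(is.numeric(beta1), is.numeric(beta2),
            length(beta1) == 1L, length(beta2) == 1L)
  if (!is.finite(beta1) || !is.finite(beta2) || beta1 <= 0 || beta2 <= 0)
    stop("shape parameters must be positive and finite")
  structure(list(beta1 = beta1, beta2 = beta2), class = "beta_shape")
}

#' @export
print.beta_shape <- function(x, ...) {
  cat(sprintf("Beta(%.4f, %.4f): mean %.4f, sd %.4f\n",
              x$beta1, x$beta2, beta_shape_mean(x), beta_shape_sd(x)))
  invisible(x)
}

#' Moments of a `beta_shape`
#' @param shape a `beta_shape`.
#' @return the mean or standard deviation of the Beta distribution.
#' @export
beta_shape_mean <- function(shape) shape$beta1 / (shape$beta1 + shape$beta2)

#' @rdname beta_shape_mean
#' @export
beta_shape_sd <- function(shape) {
  a <- shape$beta1; b <- shape$beta2
  sqrt(a * b / ((a + b)^2 * (a + b + 1)))
}

#' Expected proportion of the population first encountered on list k
#'
#' For an individual with a constant encounter probability \eqn{p} the
#' chance of being seen for the first time on list \eqn{k} is
#' \eqn{p (1 - p)^{k-1}}.  Averaging over \eqn{p \sim
#' \mathrm{Beta}(\beta_1, \beta_2)} gives the closed form
#' \deqn{E[p_1(k)] = B(\beta_1 + 1, \beta_2 + k - 1) / B(\beta_1, \beta_2),}
#' evaluated here in log-Gamma space.  At \eqn{k = 1} this reduces to the
#' Beta mean.
#'
#' @param shape a `beta_shape`.
#' @param k list index (vectorized), each at least 1.
#' @return expected first-encounter probabilities, same length as `k`.
#' @export
expected_first_encounter <- function(shape, k) {
  stopifnot(inherits(shape, "beta_shape"), all(k >= 1), all(k == round(k)))
  exp(lbeta(shape$beta1 + 1, shape$beta2 + k - 1) -
        lbeta(shape$beta1, shape$beta2))
}

#' Expected fraction of the population observed at least once over K lists
#'
#' Sum of [expected_first_encounter()] over lists \eqn{1, \dots, K}; for an
#' individual-heterogeneity population this is the expected proportion of
#' population members appearing on at least one list.
#'
#' @param shape a `beta_shape`.
#' @param K number of lists.
#' @return a probability.
#' @export
#' @examples
#' expected_observed_fraction(beta_shapes(0.2, 0.85), 5)  # 0.547
expected_observed_fraction <- function(shape, K) {
  stopifnot(K >= 1, K == round(K))
  sum(expected_first_encounter(shape, seq_len(K)))
}
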