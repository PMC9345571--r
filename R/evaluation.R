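#' A single population-size estimate
#'
#' Common result row shared by the three estimators, used by the study
#' driver and the performance summaries.
#'
#' @param method `"LLM-AIC"`, `"LLM-BMA"` or `"BLCM"`.
#' @param N_hat point estimate.
#' @param lower,upper 0.95 uncertainty interval (NA when unavailable).
#' @param n_observed number of observed individuals.
#' @param model_label selected loglinear model (LLM-AIC only).
#' @param aic AIC of the selected model (LLM-AIC only).
#' @param failed estimation failure flag; failed estimates count as
#'   non-covering in coverage summaries.
#' @return one-row data frame of class `estimate_result`.
#' @export
estimate_result <- function(method, N_hat, lower, upper, n_observed,
                            model_label = NA_character_, aic = NA_real_,
                            failed = FALSE) {
  stopifnot(method %in% c("LLM-AIC", "LLM-BMA", "BLCM"))
  out <- data.frame(method = method, N_hat = as.numeric(N_hat),
                    ci_low = as.numeric(lower), ci_high = as.numeric(upper),
                    n_observed = n_observed,
                    model_label = model_label, aic = aic, failed = failed,
                    stringsAsFactors = FALSE)
  class(out) <- c("estimate_result", class(out))
  out
}

#' Root mean-squared error of replicate estimates
#'
#' \eqn{\sqrt{m^{-1} \sum_i (N - \hat N_i)^2}}.  Non-finite estimates
#' (failures, unbounded loglinear fits) propagate to an infinite RMSE,
#' which the table renderer prints with the `"> 10^9"` sentinel.
#'
#' @param estimates numeric vector of replicate point estimates.
#' @param true_N true population size.
#' @return nonnegative number (possibly `Inf`).
#' @export
rmse <- function(estimates, true_N) {
  if (!length(estimates)) stop("no estimates")
  est <- ifelse(is.na(estimates), Inf, estimates)
  sqrt(mean((true_N - est)^2))
}

#' Bias of replicate estimates
#'
#' Mean estimate minus the true size, with the same propagation of
#' non-finite estimates as [rmse()].
#'
#' @inheritParams rmse
#' @export
bias <- function(estimates, true_N) {
  if (!length(estimates)) stop("no estimates")
  est <- ifelse(is.na(estimates), Inf, estimates)
  mean(est) - true_N
}

#' Empirical coverage of uncertainty intervals
#'
#' Fraction of intervals containing the true size.  Missing bounds (failed
#' estimates) count as non-covering.
#'
#' @param lower,upper interval endpoints per replicate.
#' @param true_N true population size.
#' @export
coverage <- function(lower, upper, true_N) {
  stopifnot(length(lower) == length(upper))
  if (!length(lower)) stop("no intervals")
  hit <- !is.na(lower) & !is.na(upper) & lower <= true_N & upper >= true_N
  mean(hit)
}

#' Model-matching percentages for AIC selection
#'
#' Cross-tabulates the data-generating pattern of each sample against the
#' AIC-best loglinear label and reports, per generating pattern, the
#' percentage of samples whose selected label equals it, together with the
#' full percentage cross-tabulation.
#'
#' @param generating character vector of generating patterns (restricted to
#'   the loglinear ones: Mb, Mbh, Mh, Mth, Mt).
#' @param selected character vector of AIC-best labels, same length.
#' @return list with `match_percent` (named vector, diagonal) and
#'   `crosstab` (percentage matrix, rows = generating pattern).
#' @export
match_table <- function(generating, selected) {
  stopifnot(length(generating) == length(selected))
  keep <- c("Mb", "Mbh", "Mh", "Mth", "Mt")
  bad <- setdiff(unique(generating), keep)
  if (length(bad))
    stop("generating patterns without a loglinear counterpart: ",
         paste(bad, collapse = ", "))
  tab <- table(factor(generating, keep), factor(selected, LLM_LABELS))
  pct <- 100 * prop.table(tab, 1)
  pct[is.nan(pct)] <- NA_real_
  diag_pct <- vapply(keep, function(g) pct[g, g], numeric(1))
  list(match_percent = diag_pct, crosstab = as.matrix(pct))
}

#' Render a value with the overflow sentinel convention
#'
#' Effectively infinite summaries are printed as `"> 10^9"` (or
#' `"< -10^9"`) instead of a meaningless number.
#'
#' @param x numeric vector.
#' @param threshold overflow threshold (default `1e9`).
#' @param digits rounding for in-range values.
#' @export
format_magnitude <- function(x, threshold = 1e9, digits = 0) {
  out <- format(round(x, digits), trim = TRUE, scientific = FALSE)
  out[is.na(x)] <- "NA"
  out[!is.na(x) & x > threshold] <- "> 10^9"
  out[!is.na(x) & x < -threshold] <- "< -10^9"
  out
}

#' Aggregate replicate estimates into performance summaries
#'
#' Pools the estimates of each (N, mean_p, K_use, method) design cell over
#' the data-generating patterns -- mirroring how the study reports
#' performance, since the generating process is unknown for real
#' populations -- and computes RMSE, bias, interval coverage, relative RMSE
#' (RMSE / N) and the replicate count.
#'
#' @param results data frame of study results as produced by [run_study()]:
#'   columns `method`, `pattern`, `N_true`, `mean_p`, `K_use`, `N_hat`,
#'   `ci_low`, `ci_high`, `failed`.
#' @param by extra grouping columns (e.g. `"pattern"` to avoid pooling).
#' @return data frame with one row per cell: `N_true`, `mean_p`, `K_use`,
#'   `method`, `rmse`, `bias`, `coverage`, `rel_rmse`, `m`, plus rendered
#'   `rmse_label`/`bias_label` using the overflow sentinel.
#' @export
aggregate_tables <- function(results, by = character()) {
  need <- c("method", "N_true", "mean_p", "K_use", "N_hat",
            "ci_low", "ci_high")
  missing_cols <- setdiff(c(need, by), names(results))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  keys <- c("N_true", "mean_p", "K_use", "method", by)
  split_idx <- split(seq_len(nrow(results)), results[keys], drop = TRUE)
  rows <- lapply(split_idx, function(i) {
    d <- results[i, ]
    cell <- d[1, keys, drop = FALSE]
    cell$rmse <- rmse(d$N_hat, d$N_true[1])
    cell$bias <- bias(d$N_hat, d$N_true[1])
    cell$coverage <- coverage(d$ci_low, d$ci_high, d$N_true[1])
    cell$rel_rmse <- cell$rmse / d$N_true[1]
    cell$m <- nrow(d)
    cell
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$N_true, out$mean_p, out$K_use, out$method), ]
  out$rmse_label <- format_magnitude(out$rmse)
  out$bias_label <- format_magnitude(out$bias)
  out
}

#' Write study estimates or summaries as CSV
#' @param x data frame.
#' @param path file path.
#' @export
write_estimates <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
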