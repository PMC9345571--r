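PATTERNS <- c("Mh", "Mt", "Mb", "Mth", "Mbh", "Mtbh")

pattern_effects <- function(pattern) {
  pattern <- match.arg(pattern, PATTERNS)
  list(h = grepl("h", pattern),
       t = grepl("t", pattern),
       b = grepl("b", pattern))
}

#' Specify a data-generating model for encounter histories
#'
#' Defines one cell of the simulation design: an inhomogeneity pattern, a
#' true population size, the number of lists and the marginal Beta
#' distribution of encounter probabilities.
#'
#' The six patterns combine three effects:
#' * individual heterogeneity (`h`): each individual draws a personal
#'   encounter probability from the Beta distribution once and keeps it
#'   across lists;
#' * temporal variation (`t`): each list draws a shared probability level
#'   from the same Beta distribution;
#' * a behavioral response (`b`): after an individual's first encounter its
#'   probability is multiplied by `behavior_multiplier` (0.5 in the study,
#'   a 50\% reduction) on all subsequent lists.
#'
#' `cv = 0` is accepted as a degenerate special case in which every draw
#' from the "Beta" distribution equals `mean_p` exactly; it is useful for
#' homogeneous-population checks.
#'
#' @param pattern one of `"Mh"`, `"Mt"`, `"Mb"`, `"Mth"`, `"Mbh"`, `"Mtbh"`.
#' @param N true population size (positive integer).
#' @param mean_p expected per-list encounter probability, in (0, 1).
#' @param K number of lists (the study generates 5 and truncates downstream).
#' @param cv coefficient of variation of the Beta distribution (0.85 in the
#'   study design).
#' @param behavior_multiplier multiplicative change in encounter probability
#'   after first capture, in `[0, 1]`.
#' @param seed integer seed making the sample reproducible; `NULL` leaves
#'   the RNG state alone.
#' @return object of class `generator_spec`.
#' @export
#' @examples
#' generator_spec("Mh", N = 1000, mean_p = 0.2, seed = 1)
generator_spec <- function(pattern, N, mean_p, K = 5L, cv = 0.85,
                           behavior_multiplier = 0.5, seed = NULL) {
  pattern <- match.arg(pattern, PATTERNS)
  stopifnot(N >= 1, N == round(N), K >= 2, K == round(K),
            mean_p > 0, mean_p < 1, cv >= 0,
            behavior_multiplier >= 0, behavior_multiplier <= 1)
  if (cv > 0 && mean_p * (1 + cv^2) >= 1)
    stop("infeasible (mean_p, cv): need mean_p * (1 + cv^2) < 1")
  if (!is.null(seed)) stopifnot(seed == round(seed))
  structure(list(pattern = pattern, N = as.integer(N),
                 mean_p = mean_p, K = as.integer(K), cv = cv,
                 behavior_multiplier = behavior_multiplier,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "generator_spec")
}

# First-capture probability matrix (N x K) before any behavioral effect.
# Active Gaussian factors (individual a_j under "h", temporal b_k under
# "t") are averaged with equal weights and mapped through the Beta
# quantile, so every p_jk is marginally Beta(beta1, beta2) -- the list-wise
# distribution the design specifies -- whatever the pattern, while shared
# factors induce the within-individual / within-list dependence.  With no
# active factor (pattern Mb) the probability is the constant mean; cv = 0
# degenerates every draw to the mean.
first_capture_probs <- function(spec, eff) {
  N <- spec$N; K <- spec$K
  if (spec$cv == 0 || !(eff$h || eff$t))
    return(matrix(spec$mean_p, N, K))
  sh <- beta_shapes(spec$mean_p, spec$cv)
  z <- matrix(0, N, K)
  nf <- eff$h + eff$t
  if (eff$h) z <- z + stats::rnorm(N)          # recycled down columns
  if (eff$t) z <- z + rep(stats::rnorm(K), each = N)
  stats::qbeta(stats::pnorm(z / sqrt(nf)), sh$beta1, sh$beta2)
}

#' Simulate a beta-Bernoulli encounter-history sample
#'
#' Draws capture indicators \eqn{y_{jk} \sim \mathrm{Bernoulli}(p_{jk})} for
#' every population member \eqn{j} and list \eqn{k}.  The first-capture
#' probabilities are marginally \eqn{\mathrm{Beta}(\beta_1, \beta_2)}
#' whatever the pattern: active Gaussian factors (one per individual under
#' `h`, one per list under `t`) are averaged and mapped through the Beta
#' quantile function, so `Mh` reduces to one Beta draw per individual held
#' constant across lists, `Mt` to one Beta draw per list shared by all
#' individuals, and the combined patterns share the heterogeneity between
#' both sources while keeping the specified list-wise Beta distribution.
#' Under `b` the probability is multiplied by `behavior_multiplier` on
#' every list after the individual's first capture (`Mb` itself uses the
#' constant mean before first capture).  Individuals never captured are
#' unobservable and their all-zero rows are removed.
#'
#' @param spec a [generator_spec()].
#' @return object of class `encounter_matrix`: a binary matrix
#'   (observed individuals x K) with attributes `true_N` and `spec`.
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  eff <- pattern_effects(spec$pattern)
  N <- spec$N; K <- spec$K
  base <- first_capture_probs(spec, eff)  # N x K first-capture probabilities

  y <- matrix(0L, N, K)
  caught <- rep(FALSE, N)
  for (k in seq_len(K)) {
    p <- base[, k]
    if (eff$b) p[caught] <- p[caught] * spec$behavior_multiplier
    y[, k] <- stats::rbinom(N, 1L, p)
    caught <- caught | y[, k] == 1L
  }
  out <- y[caught, , drop = FALSE]
  colnames(out) <- paste0("list_", seq_len(K))
  structure(out, true_N = N, spec = spec, class = "encounter_matrix")
}

#' @export
print.encounter_matrix <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Encounter matrix: %d of %d individuals observed (%s, E(p) = %g, %d lists)\n",
              nrow(x), attr(x, "true_N"), spec$pattern, spec$mean_p, ncol(x)))
  invisible(x)
}

#' Collapse an encounter matrix to a capture-history frequency table
#'
#' Keeps the first `K_use` lists, drops individuals whose truncated history
#' is all zeros (unobservable in a `K_use`-list analysis even if they were
#' seen on a later list), and tabulates the remaining histories over the
#' \eqn{2^{K_{use}} - 1} observable cells.
#'
#' @param matrix an `encounter_matrix` (or any 0/1 matrix).
#' @param K_use number of leading lists to retain, between 2 and `ncol(matrix)`.
#' @return a [frequency_table()].
#' @export
collapse_frequencies <- function(matrix, K_use = ncol(matrix)) {
  stopifnot(is.matrix(matrix), K_use >= 2, K_use <= ncol(matrix),
            K_use == round(K_use))
  K_use <- as.integer(K_use)
  y <- matrix[, seq_len(K_use), drop = FALSE]
  idx <- history_index(y)
  counts <- tabulate(idx[idx > 0L], nbins = 2L^K_use - 1L)
  frequency_table(counts, K_use)
}

#' Truncate an encounter matrix to its first K_use lists
#'
#' Individual-level analogue of [collapse_frequencies()], for estimators
#' that need histories rather than frequencies.
#'
#' @inheritParams collapse_frequencies
#' @return an `encounter_matrix` over `K_use` lists with all-zero rows removed.
#' @export
truncate_lists <- function(matrix, K_use = ncol(matrix)) {
  stopifnot(is.matrix(matrix), K_use >= 2, K_use <= ncol(matrix))
  K_use <- as.integer(K_use)
  y <- matrix[, seq_len(K_use), drop = FALSE]
  y <- y[rowSums(y) > 0, , drop = FALSE]
  structure(y, true_N = attr(matrix, "true_N"), spec = attr(matrix, "spec"),
            class = "encounter_matrix")
}

#' Write or read an encounter matrix as CSV plus a JSON metadata sidecar
#'
#' The CSV holds the 0/1 columns `list_1 .. list_K`; the sidecar
#' (`<path>.json`) records the generator fields, the seed and the true
#' population size so a sample is fully re-identifiable.
#'
#' @param x an `encounter_matrix`.
#' @param path CSV path; the sidecar is written next to it.
#' @export
write_encounter_matrix <- function(x, path) {
  stopifnot(inherits(x, "encounter_matrix"))
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  spec <- attr(x, "spec")
  meta <- c(unclass(spec), list(true_N = attr(x, "true_N")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_encounter_matrix
#' @export
read_encounter_matrix <- function(path) {
  y <- as.matrix(utils::read.csv(path))
  storage.mode(y) <- "integer"
  meta_path <- paste0(path, ".json")
  true_N <- NA_integer_; spec <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    true_N <- meta$true_N
    spec <- generator_spec(meta$pattern, meta$N, meta$mean_p, meta$K,
                           meta$cv, meta$behavior_multiplier, meta$seed)
  }
  structure(y, true_N = true_N, spec = spec, class = "encounter_matrix")
}
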