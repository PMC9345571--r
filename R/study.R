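#' Configure a replicated simulation study
#'
#' One configuration object drives the whole pipeline: simulate encounter
#' histories for every (pattern, mean_p, N, replicate) cell, truncate to
#' each requested number of lists, estimate with the enabled methods and
#' collect tidy results.  The full study design is 400 replicates of six
#' patterns, five expected encounter probabilities and three population
#' sizes (36,000 samples), each analysed with 2-5 cumulative lists.
#'
#' @param replicates samples per design cell (400 in the full study).
#' @param patterns subset of `c("Mh","Mt","Mb","Mth","Mbh","Mtbh")`.
#' @param N_values true population sizes.
#' @param mean_p_values expected per-list encounter probabilities.
#' @param cv coefficient of variation of the Beta distributions.
#' @param behavior_multiplier post-first-capture multiplier.
#' @param K_range numbers of lists to estimate from (within 2-5; samples
#'   are always generated with 5 lists and truncated).
#' @param methods any of `"llm_aic"`, `"bma"`, `"blcm"`.
#' @param correction LLM heterogeneity correction.
#' @param llm_ci compute profile intervals for LLM-AIC?
#' @param bma_prior prior on N for model averaging.
#' @param n0_max_factor BMA grid cap as a multiple of the true size
#'   (10 in the study).
#' @param blcm a [blcm_config()] (its seed field is ignored; per-sample
#'   seeds are derived).
#' @param master_seed integer master seed; every sample's seed is derived
#'   deterministically from it and the cell coordinates.
#' @param output_dir optional directory for CSV outputs.
#' @param verbose print progress messages?
#' @return object of class `study_config`.
#' @export
study_config <- function(replicates = 400L,
                         patterns = PATTERNS,
                         N_values = c(1000L, 10000L, 20000L),
                         mean_p_values = c(0.025, 0.05, 0.1, 0.15, 0.2),
                         cv = 0.85, behavior_multiplier = 0.5,
                         K_range = 2:5,
                         methods = c("llm_aic", "bma", "blcm"),
                         correction = "Poisson2", llm_ci = TRUE,
                         bma_prior = "reciprocal", n0_max_factor = 10,
                         blcm = blcm_config(),
                         master_seed = 1L, output_dir = NULL,
                         verbose = FALSE) {
  cfg <- structure(list(replicates = as.integer(replicates),
                        patterns = patterns, N_values = N_values,
                        mean_p_values = mean_p_values, cv = cv,
                        behavior_multiplier = behavior_multiplier,
                        K_range = as.integer(K_range), methods = methods,
                        correction = correction, llm_ci = llm_ci,
                        bma_prior = bma_prior,
                        n0_max_factor = n0_max_factor, blcm = blcm,
                        master_seed = as.integer(master_seed),
                        output_dir = output_dir, verbose = verbose),
                   class = "study_config")
  errs <- validate_config(cfg)
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  cfg
}

#' Ready-made study configurations
#'
#' `"paper_full"` is the complete design (400 replicates, full-length
#' latent-class chains) and is far beyond interactive scale; `"desk"`
#' trims it to 50 replicates with short chains for replication exercises
#' and tests.
#'
#' @param name `"paper_full"` or `"desk"`.
#' @param ... overrides passed to [study_config()].
#' @export
study_preset <- function(name = c("desk", "paper_full"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    paper_full = list(replicates = 400L,
                      blcm = blcm_config(preset = "paper_full")),
    desk = list(replicates = 50L, blcm = blcm_config(preset = "desk")))
  do.call(study_config, utils::modifyList(args, list(...)))
}

#' Validate a study configuration
#'
#' Checks every feasibility constraint and returns a character vector of
#' human-readable problems (empty when the configuration is valid).
#'
#' @param config a [study_config()] (or a bare list with the same fields).
#' @export
validate_config <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(config$replicates >= 1, "replicates must be at least 1")
  chk(all(config$patterns %in% PATTERNS),
      paste("unknown patterns:",
            paste(setdiff(config$patterns, PATTERNS), collapse = ", ")))
  chk(all(config$N_values >= 1), "population sizes must be positive")
  chk(all(config$mean_p_values > 0 & config$mean_p_values < 1),
      "mean encounter probabilities must lie in (0, 1)")
  if (config$cv > 0) {
    bad <- config$mean_p_values[config$mean_p_values *
                                  (1 + config$cv^2) >= 1]
    chk(!length(bad),
        paste0("infeasible Beta for mean(s) ",
               paste(bad, collapse = ", "), " at cv = ", config$cv,
               ": need mean * (1 + cv^2) < 1"))
  }
  chk(all(config$K_range >= 2 & config$K_range <= 5),
      "K_range must lie within 2-5")
  chk(all(config$methods %in% c("llm_aic", "bma", "blcm")),
      "methods must be among llm_aic, bma, blcm")
  if ("bma" %in% config$methods)
    chk(any(config$K_range >= 3),
        "model averaging supports 3-5 lists only; requested K_range has none")
  if (!is.null(config$blcm))
    chk(inherits(config$blcm, "blcm_config"), "blcm must be a blcm_config")
  errs
}

#' Number of samples implied by a study configuration
#'
#' `replicates x patterns x mean_p values x population sizes`; the full
#' design gives 36,000.
#'
#' @param config a [study_config()].
#' @export
study_cardinality <- function(config) {
  config$replicates * length(config$patterns) *
    length(config$mean_p_values) * length(config$N_values)
}

#' Deterministic per-sample seed
#'
#' Mixes the master seed with the cell coordinates (replicate, pattern,
#' mean encounter probability, population size) so that any single sample
#' can be regenerated in isolation.  The result is a positive integer
#' below \eqn{2^{31} - 1}.
#'
#' @param master_seed integer master seed.
#' @param replicate replicate index.
#' @param pattern generating pattern.
#' @param mean_p mean encounter probability.
#' @param N true population size.
#' @export
derive_seed <- function(master_seed, replicate, pattern, mean_p, N) {
  m <- 2147483647
  mix <- function(h, v) ((h * 48271) %% m + (v %% m)) %% m
  h <- master_seed %% m
  h <- mix(h, replicate)
  h <- mix(h, match(pattern, PATTERNS) * 2654435)
  h <- mix(h, round(mean_p * 1e6))
  h <- mix(h, N)
  as.integer(max(h, 1))
}

#' Run a replicated simulation study
#'
#' For every design cell: simulate a five-list sample with its derived
#' seed, truncate to each requested number of lists, and apply the enabled
#' estimators.  Model averaging is only applied at three or more lists.
#' Per-sample estimator failures are recorded in the `failed` column rather
#' than aborting the run.  When `config$output_dir` is set, the tidy
#' estimates, the pooled summaries, the model-matching tables and a
#' manifest (configuration echo) are written there as CSV/JSON.
#'
#' @param config a [study_config()].
#' @return list with `estimates` (tidy data frame, one row per sample x
#'   K_use x method), `summary` (pooled [aggregate_tables()] output),
#'   `matching` ([match_table()] output per (N, mean_p, K_use) for samples
#'   generated by loglinear patterns, as a long data frame) and `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  cells <- expand.grid(pattern = config$patterns,
                       mean_p = config$mean_p_values,
                       N = config$N_values,
                       stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(cells))) {
    pattern <- cells$pattern[ci]; mean_p <- cells$mean_p[ci]
    N <- cells$N[ci]
    if (config$verbose)
      message(sprintf("cell %d/%d: %s, E(p) = %g, N = %d",
                      ci, nrow(cells), pattern, mean_p, N))
    for (rep_i in seq_len(config$replicates)) {
      seed <- derive_seed(config$master_seed, rep_i, pattern, mean_p, N)
      spec <- generator_spec(pattern, N, mean_p, K = 5L, cv = config$cv,
                             behavior_multiplier = config$behavior_multiplier,
                             seed = seed)
      em <- simulate_sample(spec)
      for (K_use in sort(config$K_range)) {
        tab <- collapse_frequencies(em, K_use)
        ests <- list()
        if ("llm_aic" %in% config$methods)
          ests$llm <- estimate_llm_aic(tab, config$correction,
                                       ci = config$llm_ci)
        if ("bma" %in% config$methods && K_use >= 3)
          ests$bma <- estimate_bma(tab,
                                   n0_max = config$n0_max_factor * N,
                                   prior = config$bma_prior)
        if ("blcm" %in% config$methods) {
          bc <- config$blcm
          bc$seed <- derive_seed(seed, K_use, pattern, mean_p, N)
          ests$blcm <- estimate_blcm(truncate_lists(em, K_use), bc)
        }
        for (e in ests) {
          e$pattern <- pattern; e$mean_p <- mean_p; e$N_true <- N
          e$K_use <- K_use; e$replicate <- rep_i; e$seed <- seed
          rows[[length(rows) + 1L]] <- e
        }
      }
    }
  }
  estimates <- do.call(rbind, rows)
  class(estimates) <- "data.frame"
  summary <- aggregate_tables(estimates)
  matching <- matching_summary(estimates)
  out <- list(estimates = estimates, summary = summary,
              matching = matching, config = config)
  if (!is.null(config$output_dir)) write_study(out, config$output_dir)
  out
}

# long-format model-matching percentages per (N, mean_p, K_use) for
# samples generated by patterns in the loglinear candidate set
matching_summary <- function(estimates) {
  d <- estimates[estimates$method == "LLM-AIC" &
                   estimates$pattern %in% c("Mb", "Mbh", "Mh", "Mth", "Mt") &
                   !is.na(estimates$model_label), ]
  if (!nrow(d)) return(NULL)
  keys <- c("N_true", "mean_p", "K_use")
  groups <- split(seq_len(nrow(d)), d[keys], drop = TRUE)
  rows <- lapply(groups, function(i) {
    g <- d[i, ]
    mt <- match_table(g$pattern, g$model_label)
    pats <- names(mt$match_percent)
    cbind(g[rep(1, length(pats)), keys, drop = FALSE],
          data.frame(pattern = pats,
                     match_percent = unname(mt$match_percent),
                     m = as.integer(table(factor(g$pattern, pats)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[!is.na(out$match_percent), ]
}

write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_estimates(study$estimates, file.path(dir, "estimates.csv"))
  write_estimates(study$summary, file.path(dir, "summary.csv"))
  if (!is.null(study$matching))
    write_estimates(study$matching, file.path(dir, "matching.csv"))
  cfg <- study$config
  cfg$blcm <- unclass(cfg$blcm)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read a study configuration from YAML
#'
#' Convenience front end for scripted runs: top-level keys are
#' [study_config()] arguments; an optional `blcm` mapping is passed to
#' [blcm_config()].
#'
#' @param path YAML file path.
#' @return a validated [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$blcm)) y$blcm <- do.call(blcm_config, y$blcm)
  do.call(study_config, y)
}
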