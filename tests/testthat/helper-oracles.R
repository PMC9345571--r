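# Shared fixtures and independent oracles used across the suite.

# Table of the study's Beta shape parameters and first-encounter
# expectations, as printed (shapes to 4 decimals, expectations to 3).
study_shape_table <- data.frame(
  mean_p = c(0.025, 0.050, 0.100, 0.150, 0.200),
  beta1 = c(1.3245, 1.2649, 1.1457, 1.0265, 0.9073),
  beta2 = c(51.6548, 24.0327, 10.3111, 5.8167, 3.6291)
)
study_first_encounter <- rbind(
  c(0.025, 0.024, 0.023, 0.022, 0.021),
  c(0.050, 0.046, 0.042, 0.039, 0.036),
  c(0.100, 0.083, 0.070, 0.059, 0.051),
  c(0.150, 0.111, 0.086, 0.068, 0.055),
  c(0.200, 0.131, 0.093, 0.069, 0.054)
)
study_cumulative <- rbind(
  c(0.025, 0.049, 0.072, 0.094, 0.115),
  c(0.050, 0.096, 0.138, 0.176, 0.212),
  c(0.100, 0.183, 0.252, 0.312, 0.363),
  c(0.150, 0.261, 0.347, 0.415, 0.470),
  c(0.200, 0.331, 0.424, 0.493, 0.547)
)

# independent chordality oracle: a graph is chordal iff it has no induced
# cycle of length >= 4 (checked by exhausting vertex subsets)
oracle_is_chordal <- function(adj) {
  K <- nrow(adj)
  if (K < 4) return(TRUE)
  for (size in 4:K) {
    for (j in seq_len(ncol(utils::combn(K, size)))) {
      s <- utils::combn(K, size)[, j]
      sub <- adj[s, s]
      if (!all(rowSums(sub) == 2)) next
      seen <- 1L; frontier <- 1L
      while (length(frontier)) {
        nb <- which(colSums(sub[frontier, , drop = FALSE]) > 0)
        new <- setdiff(nb, seen)
        seen <- c(seen, new); frontier <- new
      }
      if (length(seen) == size) return(FALSE)  # induced chordless cycle
    }
  }
  TRUE
}

adj_from_code <- function(code, K) {
  E <- utils::combn(K, 2)
  adj <- matrix(0L, K, K)
  bits <- as.integer(intToBits(code))[seq_len(ncol(E))]
  for (e in which(bits == 1L)) {
    adj[E[1, e], E[2, e]] <- 1L
    adj[E[2, e], E[1, e]] <- 1L
  }
  adj
}

# random small frequency table with every cell positive
random_table <- function(K, lambda = 8) {
  frequency_table(stats::rpois(2^K - 1, lambda) + 1L, K)
}

# Poisson log-likelihood of a loglinear design, for the optimizer oracle
pois_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - exp(eta) - lgamma(y + 1))
}
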