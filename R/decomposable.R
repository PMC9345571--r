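# Maximum-cardinality search on an adjacency matrix.  Returns the visit
# order and whether the graph is chordal (at each visit the previously
# numbered neighbours must form a clique).
mcs <- function(adj) {
  K <- nrow(adj)
  numbered <- logical(K)
  order <- integer(K)
  chordal <- TRUE
  for (i in seq_len(K)) {
    score <- adj %*% numbered
    score[numbered] <- -1
    v <- which.max(score)
    prev <- which(numbered & adj[v, ] == 1L)
    if (length(prev) > 1) {
      sub <- adj[prev, prev]
      if (any(sub[upper.tri(sub)] == 0L)) chordal <- FALSE
    }
    numbered[v] <- TRUE
    order[i] <- v
  }
  list(order = order, chordal = chordal)
}

# all maximal cliques by exhaustive subset search (fine for K <= 5)
maximal_cliques <- function(adj) {
  K <- nrow(adj)
  subsets <- lapply(seq_len(2^K - 1), function(i) which(as.logical(intToBits(i)[seq_len(K)])))
  is_clique <- vapply(subsets, function(s) {
    if (length(s) == 1) return(TRUE)
    sub <- adj[s, s]
    all(sub[upper.tri(sub)] == 1L)
  }, logical(1))
  cl <- subsets[is_clique]
  keep <- vapply(seq_along(cl), function(i) {
    !any(vapply(seq_along(cl), function(j)
      j != i && all(cl[[i]] %in% cl[[j]]), logical(1)))
  }, logical(1))
  cl[keep]
}

# junction forest of the maximal cliques: maximum-weight spanning forest of
# the clique graph with edge weight = |intersection| (Kruskal).  Returns the
# nonempty separators (with multiplicity) and the number of components.
junction_forest <- function(cliques) {
  m <- length(cliques)
  if (m == 1) return(list(separators = list(), n_components = 1L))
  pairs <- utils::combn(m, 2)
  w <- apply(pairs, 2, function(p)
    length(intersect(cliques[[p[1]]], cliques[[p[2]]])))
  ord <- order(-w)
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  separators <- list()
  for (e in ord) {
    if (w[e] == 0) break
    a <- find(pairs[1, e]); b <- find(pairs[2, e])
    if (a != b) {
      parent[a] <- b
      separators[[length(separators) + 1L]] <-
        intersect(cliques[[pairs[1, e]]], cliques[[pairs[2, e]]])
    }
  }
  roots <- unique(vapply(seq_len(m), find, integer(1)))
  list(separators = separators, n_components = length(roots))
}

# model constructor from an edge list (2-column matrix of vertex pairs)
new_decomposable <- function(K, edges) {
  adj <- matrix(0L, K, K)
  if (length(edges)) {
    adj[edges] <- 1L
    adj[edges[, 2:1, drop = FALSE]] <- 1L
  }
  if (!mcs(adj)$chordal) stop("graph is not chordal")
  cl <- maximal_cliques(adj)
  jf <- junction_forest(cl)
  structure(list(K = K, edges = edges, adj = adj, cliques = cl,
                 separators = jf$separators,
                 n_components = jf$n_components),
            class = "decomposable_model")
}

#' @export
print.decomposable_model <- function(x, ...) {
  fmt <- function(s) paste0("{", paste(s, collapse = ","), "}")
  cat(sprintf("Decomposable model on %d lists: cliques %s%s\n", x$K,
              paste(vapply(x$cliques, fmt, character(1)), collapse = " "),
              if (length(x$separators))
                paste0(", separators ",
                       paste(vapply(x$separators, fmt, character(1)),
                             collapse = " ")) else ""))
  invisible(x)
}

enum_cache <- new.env(parent = emptyenv())

#' Enumerate all decomposable (chordal) loglinear models on K lists
#'
#' Every labeled graph on `K` vertices is tested for chordality by
#' maximum-cardinality search; chordal graphs are returned with their
#' maximal cliques and the separators of a junction forest, which together
#' define the hyper-Dirichlet factorization used by [log_marginal()].
#' The counts are 8, 61 and 822 models for K = 3, 4, 5.  Order is
#' deterministic (by the integer encoding of the edge set).
#'
#' @param K number of lists, between 3 and 5.
#' @return list of `decomposable_model` objects.
#' @export
enumerate_decomposable <- function(K) {
  stopifnot(K >= 3, K <= 5, K == round(K))
  key <- as.character(K)
  if (!is.null(enum_cache[[key]])) return(enum_cache[[key]])
  all_edges <- t(utils::combn(K, 2))
  nE <- nrow(all_edges)
  models <- list()
  for (code in 0:(2^nE - 1)) {
    sel <- as.logical(intToBits(code)[seq_len(nE)])
    m <- tryCatch(new_decomposable(K, all_edges[sel, , drop = FALSE]),
                  error = function(e) NULL)
    if (!is.null(m)) models[[length(models) + 1L]] <- m
  }
  enum_cache[[key]] <- models
  models
}
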