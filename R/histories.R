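#' Enumerate the observable capture histories for K lists
#'
#' Returns the \eqn{2^K - 1} observable capture histories (the all-zero
#' history is unobservable and excluded) as a binary matrix.  Rows are
#' ordered by the integer value of the history string with list 1 as the
#' most significant bit, so the ordering is deterministic and shared by
#' every function in the package that indexes cells of a frequency table.
#'
#' @param K number of lists (at least 1).
#' @return integer matrix with \eqn{2^K - 1} rows and `K` columns named
#'   `list_1 ... list_K`; row names are the history strings (e.g. `"10110"`).
#' @export
#' @examples
#' capture_histories(2)
capture_histories <- function(K) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 1, K == round(K))
  K <- as.integer(K)
  idx <- seq_len(2L^K - 1L)
  bits <- vapply(idx, function(x) as.integer(intToBits(x))[seq_len(K)],
                 integer(K))
  m <- t(bits)[, K:1, drop = FALSE]  # column 1 = most significant bit
  colnames(m) <- paste0("list_", seq_len(K))
  rownames(m) <- apply(m, 1L, paste, collapse = "")
  m
}

# integer cell index (1 .. 2^K - 1) of each row of a 0/1 matrix; 0 for the
# all-zero history
history_index <- function(y) {
  K <- ncol(y)
  as.integer(y %*% 2^((K - 1):0))
}

#' Construct a capture-history frequency table
#'
#' @param counts nonnegative integer vector of length \eqn{2^K - 1}, ordered
#'   as in [capture_histories()], or a named vector whose names are history
#'   strings (missing histories default to zero).
#' @param K number of lists.
#' @return object of class `frequency_table`: a list with elements `K`,
#'   `counts` (named full-length vector) and `n` (total observed).
#' @export
frequency_table <- function(counts, K) {
  K <- as.integer(K)
  hist <- capture_histories(K)
  full <- stats::setNames(integer(nrow(hist)), rownames(hist))
  if (!is.null(names(counts))) {
    bad <- setdiff(names(counts), rownames(hist))
    if (length(bad)) stop("unknown capture histories: ",
                          paste(bad, collapse = ", "))
    full[names(counts)] <- as.integer(counts)
  } else {
    if (length(counts) != nrow(hist))
      stop("`counts` must have length 2^K - 1 when unnamed")
    full[] <- as.integer(counts)
  }
  if (any(full < 0)) stop("counts must be nonnegative")
  structure(list(K = K, counts = full, n = sum(full)),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("Capture-history frequency table:", x$K, "lists,",
      x$n, "individuals observed\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) print(nz) else cat("(all cells zero)\n")
  invisible(x)
}

#' Write or read a frequency table as CSV
#'
#' The file has columns `history` (e.g. `"10110"`) and `count`, one row per
#' observable history.
#'
#' @param x a `frequency_table`.
#' @param path file path.
#' @return `read_frequency_table` returns a `frequency_table`.
#' @export
write_frequency_table <- function(x, path) {
  stopifnot(inherits(x, "frequency_table"))
  utils::write.csv(data.frame(history = names(x$counts),
                              count = unname(x$counts)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  d <- utils::read.csv(path, colClasses = c("character", "integer"))
  K <- nchar(d$history[1])
  frequency_table(stats::setNames(d$count, d$history), K)
}
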