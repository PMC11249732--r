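#' Initialise a PBWT state
#'
#' Creates the positional Burrows-Wheeler transform state "before site 0":
#' the prefix array is the identity permutation (every sequence ties on the
#' empty reversed prefix) and all divergence values are 0.
#'
#' The state is a list with elements
#' * `k` -- the 0-based site index the state is valid before,
#' * `a` -- the prefix array: sequence indices (1-based) ordered by reversed
#'   prefix ending at `k`, ties broken by original index,
#' * `d` -- the divergence array: `d[i]` is the smallest 0-based site `s` such
#'   that sequences `a[i]` and `a[i-1]` agree on columns `[s, k)`;
#'   `d[1] == k` by convention (no predecessor).
#'
#' @param M Number of sequences (at least 1).
#' @return A `pbwt_state` object.
#' @seealso [pbwt_advance()], [pbwt_oracle_sort()]
#' @export
pbwt_init <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || is.na(M) || M < 1) {
    stop("M must be a single integer >= 1")
  }
  M <- as.integer(M)
  structure(list(k = 0L, a = seq_len(M), d = integer(M)), class = "pbwt_state")
}

#' Advance a PBWT state by one site
#'
#' Updates the prefix and divergence arrays from the state before site `k` to
#' the state before site `k+1`, given the alleles of column `k` in original
#' sequence order.  Sequences carrying allele 0 at column `k` precede those
#' carrying allele 1, each sub-list preserving its prior order (a stable
#' bucket step), and divergences are recomputed so that consecutive entries
#' `a[i-1]`, `a[i]` agree exactly on columns `[d[i], k+1)`.  Each site costs
#' O(M log M) work, so a whole panel is processed in near-linear total time.
#'
#' Columns over larger non-negative integer alphabets are accepted; buckets
#' are then ordered by ascending symbol.  This is used internally to exclude
#' heterozygous cells from ground-truth matching.
#'
#' @param state A `pbwt_state` from [pbwt_init()] or a previous advance.
#' @param column Integer vector of length M with the alleles of site
#'   `state$k`, indexed by original sequence.
#' @return The `pbwt_state` before site `k+1`.
#' @export
pbwt_advance <- function(state, column) {
  stopifnot(inherits(state, "pbwt_state"))
  column <- as.integer(column)
  if (length(column) != length(state$a)) {
    stop(sprintf("column has %d entries but the panel has %d sequences",
                 length(column), length(state$a)))
  }
  if (anyNA(column) || any(column < 0L)) {
    stop("column values must be non-negative integers")
  }
  res <- pbwt_advance_cpp(state$a - 1L, state$d, state$k, column)
  structure(list(k = res$k, a = res$a + 1L, d = res$d), class = "pbwt_state")
}

#' Brute-force reversed-prefix sort (test oracle)
#'
#' Computes the prefix and divergence arrays at site `k` directly from the
#' definition: sequences are ordered by their reversed prefix (columns
#' `k-1, k-2, ..., 0` as successive sort keys, ties broken by original
#' index) and each divergence is found by scanning the two neighbouring rows
#' backwards from column `k-1`.  Quadratic time; this is the normative
#' reference that [pbwt_advance()] must reproduce.
#'
#' @param panel A `binary_panel` or plain integer matrix.
#' @param k 0-based site index, `0 <= k <= N`.
#' @return A `pbwt_state` at site `k`.
#' @export
pbwt_oracle_sort <- function(panel, k) {
  X <- as_binary_matrix_any(panel)
  M <- nrow(X)
  N <- ncol(X)
  if (k < 0 || k > N) stop("k out of range [0, N]")
  k <- as.integer(k)
  if (k == 0L) {
    a <- seq_len(M)
  } else {
    keys <- lapply(k:1, function(j) X[, j])
    a <- do.call(order, c(keys, list(seq_len(M))))
  }
  d <- integer(M)
  d[1] <- k
  if (M > 1L) {
    for (i in 2:M) {
      s <- k
      while (s > 0L && X[a[i], s] == X[a[i - 1], s]) s <- s - 1L
      d[i] <- s
    }
  }
  structure(list(k = k, a = a, d = d), class = "pbwt_state")
}

# Like as_binary_matrix() but admits any non-negative integer alphabet.
as_binary_matrix_any <- function(panel) {
  m <- if (inherits(panel, "binary_panel")) panel$values else as.matrix(panel)
  storage.mode(m) <- "integer"
  m
}

#' @export
print.pbwt_state <- function(x, ...) {
  cat(sprintf("<pbwt_state> before site k=%d, %d sequences\n", x$k, length(x$a)))
  invisible(x)
}
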