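#' Enumerate block-maximal matches in a binary panel
#'
#' Finds all clusters of at least `W` sequences that are identical over at
#' least `L` consecutive sites, under one of two objectives:
#'
#' * `"width"` -- at every end position `e` the PBWT-sorted sequences are
#'   partitioned into runs separated by entries whose divergence exceeds
#'   `e - L`; each run of at least `W` sequences is a candidate block whose
#'   start is the largest divergence inside the run (so the whole run is
#'   identical over at least `L` sites), and it is reported as soon as some
#'   member leaves the run (or the panel ends).  This maximises the number of
#'   individuals per block.
#' * `"length"` -- every triple `(s, e, S)` is reported for which `S` is the
#'   full set of sequences identical on `[s, e)`, `|S| >= W`, `e - s >= L`,
#'   and no subset of at least `W` members remains identical when the span is
#'   grown by one site on either side.  This maximises the number of sites.
#'
#' Site indices are 0-based and spans are half-open `[start, end)`; member
#' indices are 1-based row numbers.  The scan runs in O(NM log M) time via
#' compiled code; [oracle_blocks()] is the quadratic reference definition.
#'
#' @param panel A `binary_panel` or plain \{0,1\} integer matrix.
#' @param L Minimum number of sites per block (>= 1).
#' @param W Minimum number of sequences per block (>= 2).
#' @param objective `"width"` or `"length"`.
#' @return A tibble with columns `start`, `end`, `members` (list of sorted
#'   integer vectors) and `consensus` (character), deduplicated and ordered by
#'   `(start, end, smallest member)`.  `W > M` or `L > N` yield zero rows.
#' @export
find_blocks <- function(panel, L, W, objective = c("width", "length")) {
  objective <- match.arg(objective)
  X <- as_binary_matrix_any(panel)
  check_block_params(L, W)
  if (W > nrow(X) || L > ncol(X)) return(empty_blocks())
  res <- pbwt_scan_cpp(X, as.integer(L), as.integer(W), objective)
  blocks_tibble(res$start, res$end, lapply(res$members, function(m) m + 1L), X)
}

#' @rdname find_blocks
#' @export
find_width_maximal <- function(panel, L, W) find_blocks(panel, L, W, "width")

#' @rdname find_blocks
#' @export
find_length_maximal <- function(panel, L, W) find_blocks(panel, L, W, "length")

check_block_params <- function(L, W) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1) {
    stop("L must be a single integer >= 1")
  }
  if (!is.numeric(W) || length(W) != 1L || is.na(W) || W < 2) {
    stop("W must be a single integer >= 2")
  }
}

empty_blocks <- function() {
  tibble::tibble(start = integer(), end = integer(),
                 members = list(), consensus = character())
}

# Assemble, deduplicate and canonically order a set of blocks.  Blocks with
# the same span but different member sets (hence different consensus) stay
# distinct.
blocks_tibble <- function(start, end, members, X) {
  if (length(start) == 0L) return(empty_blocks())
  consensus <- vapply(seq_along(start), function(b) {
    cols <- (start[b] + 1L):end[b]
    paste0(X[members[[b]][1], cols], collapse = "")
  }, character(1))
  key <- vapply(seq_along(start), function(b) {
    paste(start[b], end[b], paste(members[[b]], collapse = ","))
  }, character(1))
  keep <- !duplicated(key)
  start <- start[keep]; end <- end[keep]
  members <- members[keep]; consensus <- consensus[keep]
  first_member <- vapply(members, min, integer(1))
  o <- order(start, end, first_member)
  tibble::tibble(start = as.integer(start[o]), end = as.integer(end[o]),
                 members = members[o], consensus = consensus[o])
}

#' Brute-force block enumeration (normative test oracle)
#'
#' Applies the block definitions of [find_blocks()] literally, using the
#' quadratic [pbwt_oracle_sort()] for the width objective and exhaustive
#' enumeration of all `(start, end)` spans for the length objective.  Only
#' suitable for small panels (roughly M <= 20, N <= 40); its output is the
#' definition of correctness for the compiled scan.
#'
#' @inheritParams find_blocks
#' @return A tibble in the format of [find_blocks()].
#' @export
oracle_blocks <- function(panel, L, W, objective = c("width", "length")) {
  objective <- match.arg(objective)
  X <- as_binary_matrix_any(panel)
  check_block_params(L, W)
  M <- nrow(X)
  N <- ncol(X)
  if (W > M || L > N) return(empty_blocks())
  if (any(X > 9L)) stop("oracle_blocks expects single-digit symbols")
  rowstr <- apply(X, 1L, paste0, collapse = "")
  slice <- function(s, e) substr(rowstr, s + 1L, e) # [s,e) 0-based

  starts <- integer(); ends <- integer(); members <- list()
  add <- function(s, e, S) {
    starts[[length(starts) + 1L]] <<- s
    ends[[length(ends) + 1L]] <<- e
    members[[length(members) + 1L]] <<- sort(S)
  }

  if (objective == "width") {
    run_info <- function(e) {
      st <- pbwt_oracle_sort(X, e)
      bnd <- which(st$d > e - L)
      rstart <- bnd
      rend <- c(bnd[-1] - 1L, M)
      runid <- integer(M)
      runid[st$a] <- rep(seq_along(rstart), rend - rstart + 1L)
      cands <- list()
      for (r in seq_along(rstart)) {
        i0 <- rstart[r]; i1 <- rend[r]
        if (i1 - i0 + 1L >= W) {
          cands[[length(cands) + 1L]] <-
            list(s = max(st$d[(i0 + 1L):i1]), rows = st$a[i0:i1])
        }
      }
      list(runid = runid, cands = cands)
    }
    prev <- NULL
    for (e in L:N) {
      info <- run_info(e)
      if (!is.null(prev)) {
        for (cand in prev$cands) {
          rid <- info$runid[cand$rows]
          if (length(unique(rid)) > 1L) add(cand$s, e - 1L, cand$rows)
        }
      }
      prev <- info
    }
    for (cand in prev$cands) add(cand$s, N, cand$rows)
  } else {
    for (e in L:N) {
      for (s in 0:(e - L)) {
        grp <- split(seq_len(M), slice(s, e))
        for (S in grp) {
          if (length(S) < W) next
          leftext <- s > 0L && max(table(slice(s - 1L, e)[S])) >= W
          rightext <- e < N && max(table(slice(s, e + 1L)[S])) >= W
          if (!leftext && !rightext) add(s, e, S)
        }
      }
    }
  }
  blocks_tibble(starts, ends, members, X)
}

#' Select the c-th smallest value
#'
#' Quickselect with random pivots: partitions the input around a pivot and
#' recurses into the side holding the requested rank, O(n) on average.  This
#' is the selection primitive behind rank queries on divergence values in the
#' length-maximal formulation.
#'
#' @param values Numeric vector.
#' @param c Rank, 1-based; duplicates count with multiplicity.
#' @return The c-th smallest element of `values`.
#' @export
quickselect <- function(values, c) {
  if (!is.numeric(values) || length(values) == 0L) stop("values must be a non-empty numeric vector")
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 1 || c > length(values)) {
    stop("rank c must lie in 1..length(values)")
  }
  v <- as.numeric(values)
  c <- as.integer(c)
  repeat {
    if (length(v) == 1L) return(v)
    pivot <- v[sample.int(length(v), 1L)]
    lo <- v[v < pivot]
    eq <- v[v == pivot]
    if (c <= length(lo)) {
      v <- lo
    } else if (c <= length(lo) + length(eq)) {
      return(pivot)
    } else {
      c <- c - length(lo) - length(eq)
      v <- v[v > pivot]
    }
  }
}
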