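#' Compress a genotype panel to a binary pseudo-haplotype panel
#'
#' Maps homozygous reference (0) to allele 0 and homozygous alternative (2)
#' to allele 1 deterministically; every heterozygous cell (1) is assigned
#' allele 0 or 1 with probability 1/2 each from a seeded generator.  The
#' returned panel records the heterozygous cells in its `het_mask`, which the
#' cluster caller uses for the per-member heterozygosity filter.  True ROH
#' diplotypes consist almost entirely of homozygous sites, so they survive
#' this compression intact with high probability, while the randomisation
#' makes spurious long wide matches between non-ROH individuals vanishingly
#' unlikely.
#'
#' @param panel A [genotype_panel()].
#' @param seed Integer seed governing all heterozygote assignments.
#' @return A [binary_panel()] with the same shape, sample ids and metadata.
#' @export
compress_genotypes <- function(panel, seed) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$values
  het <- g == 1L
  y <- g
  y[g == 2L] <- 1L
  nh <- sum(het)
  if (nh > 0L) {
    y[het] <- with_seed(seed, rbinom(nh, 1L, 0.5))
  }
  binary_panel(y, het_mask = het, sample_ids = panel$sample_ids, meta = panel$site_meta)
}

#' Consensus sequence of a matching block
#'
#' Returns the allele sequence shared by all members of a block over its
#' span.  Within a block every member is identical by construction, so the
#' majority allele is the unanimous one; disagreement indicates an internal
#' inconsistency and raises an error.
#'
#' @param block A one-row block (a list or one-row tibble with `start`,
#'   `end`, `members`).
#' @param panel The `binary_panel` (or matrix) the block was found in.
#' @return A \{0,1\} character string of length `end - start`.
#' @export
consensus_of <- function(block, panel) {
  X <- as_binary_matrix_any(panel)
  if (is.data.frame(block)) {
    stopifnot(nrow(block) == 1L)
    block <- list(start = block$start[[1]], end = block$end[[1]],
                  members = block$members[[1]])
  }
  cols <- (block$start + 1L):block$end
  slice <- X[block$members, cols, drop = FALSE]
  if (nrow(slice) > 1L &&
      !all(slice == rep(slice[1L, ], each = nrow(slice)))) {
    stop("block members disagree on the span: internal consistency error")
  }
  paste0(slice[1L, ], collapse = "")
}

#' Call ROH diplotype clusters from a genotype panel
#'
#' The end-to-end caller: compresses the genotype panel with
#' [compress_genotypes()], enumerates matching blocks per chromosome with
#' [find_blocks()], then applies post-processing: every member whose
#' fraction of (pre-compression) heterozygous sites inside the block span
#' exceeds `max_member_het` is removed; clusters whose width falls below `W`
#' after the filter are dropped; clusters with identical span and consensus
#' are merged by uniting their member sets.  Genomic coordinates (1-based
#' inclusive) are attached from the site metadata, and genetic lengths in cM
#' are interpolated from a genetic map when one is supplied (or taken from
#' the metadata's `cm` column); otherwise `genetic_length_cm` is `NA`.
#'
#' @param panel A [genotype_panel()].
#' @param L Minimum number of consecutive sites per cluster (>= 1).
#' @param W Minimum number of individuals per cluster (>= 2).
#' @param objective Block objective, `"width"` (default; maximises the member
#'   count, the choice for association work) or `"length"`.
#' @param seed Integer seed for the heterozygote compression.
#' @param max_member_het Maximum tolerated per-member in-block heterozygous
#'   fraction (default 0.01).
#' @param genetic_map Optional data frame with columns `chrom`, `pos`, `cm`
#'   for genetic-length interpolation.
#' @return A tibble of class `roh_clusters` with one row per cluster:
#'   `cluster_id`, `chrom`, `start_site`, `end_site` (0-based half-open,
#'   panel-global), `bp_start`, `bp_end` (1-based inclusive), `n_members`,
#'   `genetic_length_cm`, `consensus`, `members` (list of row indices),
#'   `member_ids` (list of sample ids) and `member_het` (list of per-member
#'   in-block heterozygous fractions).  Calling parameters are stored in
#'   attribute `params`.
#' @export
call_roh_clusters <- function(panel, L, W, objective = c("width", "length"),
                              seed = 1L, max_member_het = 0.01,
                              genetic_map = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  objective <- match.arg(objective)
  check_block_params(L, W)
  if (max_member_het < 0 || max_member_het > 1) {
    stop("max_member_het must lie in [0, 1]")
  }
  compressed <- compress_genotypes(panel, seed)
  clusters_from_binary(compressed, L = L, W = W, objective = objective,
                       seed = seed, max_member_het = max_member_het,
                       genetic_map = genetic_map)
}

# Shared core: block discovery + post-processing on an already-compressed
# panel.  Chromosomes are scanned independently; block coordinates are
# reported on the panel-global site grid.
clusters_from_binary <- function(compressed, L, W, objective, seed,
                                 max_member_het, genetic_map = NULL,
                                 scan_values = NULL) {
  meta <- compressed$site_meta
  chroms <- rle(meta$chrom)$values
  X <- scan_values %||% compressed$values

  rows <- list()
  for (ch in chroms) {
    idx <- which(meta$chrom == ch)
    blocks <- find_blocks(X[, idx, drop = FALSE], L, W, objective)
    if (nrow(blocks) == 0L) next
    offset <- idx[1] - 1L
    blocks$start <- blocks$start + offset
    blocks$end <- blocks$end + offset
    blocks$chrom <- ch
    rows[[length(rows) + 1L]] <- blocks
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else {
    cbind(empty_blocks(), tibble::tibble(chrom = character()))
  }

  # per-member heterozygosity filter, then re-check the width
  keep <- logical(nrow(blocks))
  member_het <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    cols <- (blocks$start[b] + 1L):blocks$end[b]
    m <- blocks$members[[b]]
    het <- rowMeans(compressed$het_mask[m, cols, drop = FALSE])
    ok <- het <= max_member_het
    blocks$members[[b]] <- m[ok]
    member_het[[b]] <- het[ok]
    keep[b] <- sum(ok) >= W
  }
  blocks <- blocks[keep, , drop = FALSE]
  member_het <- member_het[keep]

  # recompute consensus on the compressed panel (blocks found on an
  # extended-alphabet panel report their consensus on the compressed one)
  consensus <- vapply(seq_len(nrow(blocks)), function(b) {
    paste0(compressed$values[blocks$members[[b]][1],
                             (blocks$start[b] + 1L):blocks$end[b]], collapse = "")
  }, character(1))
  blocks$consensus <- consensus

  merged <- merge_clusters(blocks, member_het)
  blocks <- merged$blocks
  member_het <- merged$member_het

  n <- nrow(blocks)
  bp_start <- bp_end <- integer(n)
  cm_len <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    sites <- c(blocks$start[b] + 1L, blocks$end[b])
    bp_start[b] <- meta$pos[sites[1]]
    bp_end[b] <- meta$pos[sites[2]]
    cm_len[b] <- genetic_length_cm(meta, genetic_map, blocks$chrom[b],
                                   bp_start[b], bp_end[b], sites)
  }

  out <- tibble::tibble(
    cluster_id = if (n) paste0("roh", seq_len(n)) else character(),
    chrom = blocks$chrom,
    start_site = blocks$start,
    end_site = blocks$end,
    bp_start = bp_start,
    bp_end = bp_end,
    n_members = vapply(blocks$members, length, integer(1)),
    genetic_length_cm = cm_len,
    consensus = blocks$consensus,
    members = blocks$members,
    member_ids = lapply(blocks$members, function(m) compressed$sample_ids[m]),
    member_het = member_het
  )
  attr(out, "params") <- list(L = L, W = W, objective = objective, seed = seed,
                              max_member_het = max_member_het)
  class(out) <- c("roh_clusters", class(out))
  out
}

# Merge clusters sharing (chrom, start, end, consensus) by uniting members.
# Idempotent: merging an already merged set changes nothing.
merge_clusters <- function(blocks, member_het) {
  if (nrow(blocks) == 0L) return(list(blocks = blocks, member_het = member_het))
  key <- paste(blocks$chrom, blocks$start, blocks$end, blocks$consensus)
  groups <- split(seq_len(nrow(blocks)), key)
  idx <- integer(0)
  new_members <- list()
  new_het <- list()
  for (g in groups) {
    first <- g[1]
    mem <- unlist(lapply(g, function(i) blocks$members[[i]]))
    het <- unlist(lapply(g, function(i) member_het[[i]]))
    o <- !duplicated(mem)
    ord <- order(mem[o])
    idx <- c(idx, first)
    new_members[[length(new_members) + 1L]] <- mem[o][ord]
    new_het[[length(new_het) + 1L]] <- het[o][ord]
  }
  blocks <- blocks[idx, , drop = FALSE]
  blocks$members <- new_members
  o <- order(blocks$chrom, blocks$start, blocks$end,
             vapply(new_members, min, integer(1)))
  list(blocks = blocks[o, , drop = FALSE], member_het = new_het[o])
}

# Genetic length of [bp_start, bp_end]: from an explicit map by linear
# interpolation, else from per-site cM metadata; NA when neither is present.
genetic_length_cm <- function(meta, genetic_map, chrom, bp_start, bp_end, sites) {
  if (!is.null(genetic_map)) {
    gm <- genetic_map[genetic_map$chrom == chrom, , drop = FALSE]
    if (nrow(gm) >= 2L) {
      cms <- approx(gm$pos, gm$cm, xout = c(bp_start, bp_end), rule = 2)$y
      return(max(0, cms[2] - cms[1]))
    }
    return(NA_real_)
  }
  cm <- meta$cm[sites]
  if (anyNA(cm)) NA_real_ else max(0, cm[2] - cm[1])
}

#' @export
print.roh_clusters <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<roh_clusters> %d cluster(s) [L=%s, W=%s, objective=%s, seed=%s]\n",
              nrow(x), p$L, p$W, p$objective, p$seed))
  NextMethod()
}
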