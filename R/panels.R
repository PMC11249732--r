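#' Per-site metadata table
#'
#' Builds the site metadata tibble carried by genotype and binary panels:
#' chromosome, 1-based physical position, site identifier and (optionally)
#' genetic position in centimorgans.  Positions must be strictly increasing
#' within each chromosome, and all sites of a chromosome must be contiguous
#' (chromosomes are processed independently downstream).
#'
#' @param pos Integer vector of 1-based base-pair positions.
#' @param chrom Chromosome label(s); recycled to the number of sites.
#' @param id Site identifiers; defaults to `"<chrom>:<pos>"`.
#' @param cm Optional genetic positions in centimorgans (`NA` when unknown).
#' @return A tibble with columns `chrom`, `pos`, `id`, `cm`.
#' @export
site_meta <- function(pos, chrom = "1", id = NULL, cm = NA_real_) {
  pos <- as.integer(pos)
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  cm <- rep_len(as.numeric(cm), n)
  meta <- tibble::tibble(chrom = chrom, pos = pos, id = as.character(id), cm = cm)
  validate_site_meta(meta)
  meta
}

validate_site_meta <- function(meta) {
  stopifnot(all(c("chrom", "pos", "id", "cm") %in% names(meta)))
  r <- rle(meta$chrom)
  if (anyDuplicated(r$values)) {
    stop("sites of one chromosome must be contiguous in the panel")
  }
  for (ch in r$values) {
    p <- meta$pos[meta$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("bp positions must be strictly increasing within chromosome ", ch)
    }
  }
  invisible(meta)
}

#' Diploid genotype panel
#'
#' An M-individual by N-site matrix of alternative-allele counts (0, 1 or 2)
#' plus sample identifiers and per-site metadata.  This is the input container
#' for ROH cluster calling.
#'
#' @param values Integer matrix over \{0,1,2\}, individuals in rows.
#' @param sample_ids Character vector of M sample identifiers.
#' @param meta Site metadata built with [site_meta()]; defaults to positions
#'   `1..N` on chromosome `"1"`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(values, sample_ids = NULL, meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("a genotype panel needs at least one individual and one site")
  }
  bad <- which(!(values %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("genotype value outside {0,1,2} at individual %d, site %d", i, j))
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%04d", seq_len(nrow(values)))
  stopifnot(length(sample_ids) == nrow(values))
  if (is.null(meta)) meta <- site_meta(seq_len(ncol(values)))
  validate_site_meta(meta)
  stopifnot(nrow(meta) == ncol(values))
  structure(
    list(values = values, sample_ids = as.character(sample_ids), site_meta = meta),
    class = "genotype_panel"
  )
}

#' Compressed binary panel
#'
#' The pseudo-haplotype panel obtained by compressing a genotype panel:
#' homozygous reference maps to 0, homozygous alternative to 1 and each
#' heterozygous cell to a random allele.  `het_mask` records which cells were
#' heterozygous before compression; it is all-`FALSE` for true haplotype data.
#'
#' @param values Integer matrix over \{0,1\}.
#' @param het_mask Logical matrix of the same shape.
#' @param sample_ids,meta As in [genotype_panel()].
#' @return An object of class `binary_panel`.
#' @export
binary_panel <- function(values, het_mask = NULL, sample_ids = NULL, meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("a binary panel needs at least one sequence and one site")
  }
  if (!all(values %in% c(0L, 1L))) stop("binary panel values must be 0 or 1")
  if (is.null(het_mask)) het_mask <- matrix(FALSE, nrow(values), ncol(values))
  het_mask <- as.matrix(het_mask)
  if (!is.logical(het_mask) || !identical(dim(het_mask), dim(values))) {
    stop("het_mask must be a logical matrix with the same shape as values")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%04d", seq_len(nrow(values)))
  stopifnot(length(sample_ids) == nrow(values))
  if (is.null(meta)) meta <- site_meta(seq_len(ncol(values)))
  validate_site_meta(meta)
  stopifnot(nrow(meta) == ncol(values))
  structure(
    list(values = values, het_mask = het_mask,
         sample_ids = as.character(sample_ids), site_meta = meta),
    class = "binary_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d sites, %d chromosome(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$site_meta$chrom))))
  invisible(x)
}

#' @export
print.binary_panel <- function(x, ...) {
  cat(sprintf("<binary_panel> %d sequences x %d sites (%.1f%% cells were heterozygous)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$het_mask)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$values)

#' @export
dim.binary_panel <- function(x) dim(x$values)

# Accept a binary_panel or a plain {0,1} matrix and return the integer matrix.
as_binary_matrix <- function(panel) {
  if (inherits(panel, "binary_panel")) return(panel$values)
  m <- as.matrix(panel)
  storage.mode(m) <- "integer"
  m
}
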