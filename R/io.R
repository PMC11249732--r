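# Standard-format I/O.  bp coordinates are 1-based inclusive in all files
# (VCF convention); internally sites are 0-based half-open.  Every writer
# stamps a comment header with the package version and the run parameters so
# that outputs are reproducible from their own metadata.

tsv_write <- function(df, path, config = list()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(paste0("#rohdice_version=", as.character(packageVersion("rohdice"))), con)
  for (k in names(config)) {
    writeLines(paste0("#", k, "=", as.character(config[[k]])), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tsv_read <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  run <- rle(is_hdr)
  n_hdr <- if (run$values[1]) run$lengths[1] else 0L
  config <- list()
  if (n_hdr > 0L) {
    kv <- sub("^#", "", lines[seq_len(n_hdr)])
    parts <- strsplit(kv, "=", fixed = TRUE)
    for (p in parts) if (length(p) == 2L) config[[p[1]]] <- p[2]
  }
  df <- data.table::fread(text = lines[-seq_len(max(n_hdr, 0L))], sep = "\t",
                          header = TRUE, data.table = FALSE)
  attr(df, "config") <- config
  df
}

#' Read a diploid genotype panel from a VCF file
#'
#' Reads biallelic diploid GT records: `0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2` (phased separators accepted).  Multi-allelic records and
#' records with any missing genotype are skipped, with counts reported via
#' `message()`.  Unsorted positions within a chromosome are an error, as is
#' a VCF without samples.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF contains no sample genotypes")

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) | is.na(fix[, "ALT"])
  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dosage[gt_norm == "0/0"] <- 0L
  dosage[gt_norm %in% c("0/1", "1/0")] <- 1L
  dosage[gt_norm == "1/1"] <- 2L
  missing <- apply(is.na(dosage), 1L, any) & !multi

  keep <- !multi & !missing
  if (any(multi)) message(sum(multi), " multi-allelic record(s) skipped")
  if (any(missing)) message(sum(missing), " record(s) with missing/unsupported genotypes skipped")
  if (!any(keep)) stop("no usable biallelic records in VCF")

  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  for (ch in unique(chrom)) {
    if (any(diff(pos[chrom == ch]) <= 0)) {
      stop("VCF positions are not strictly increasing on chromosome ", ch)
    }
  }
  id <- fix[keep, "ID"]
  id[is.na(id) | id == "."] <- paste0(chrom, ":", pos)[is.na(id) | id == "."]
  genotype_panel(t(dosage[keep, , drop = FALSE]),
                 sample_ids = colnames(gt),
                 meta = site_meta(pos, chrom = chrom, id = id))
}

#' Write a genotype panel as VCF
#'
#' Emits a minimal VCF 4.2 with diploid unphased GT fields.  The panel does
#' not track the actual alleles, so REF/ALT are written as the placeholders
#' `A`/`G`.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @param config Optional named list recorded as `##` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, config = list()) {
  stopifnot(inherits(panel, "genotype_panel"))
  meta <- panel$site_meta
  gt <- matrix(c("0/0", "0/1", "1/1")[panel$values + 1L],
               nrow(panel$values), ncol(panel$values))
  body <- data.table::data.table(
    CHROM = meta$chrom, POS = meta$pos, ID = meta$id,
    REF = "A", ALT = "G", QUAL = ".", FILTER = "PASS", INFO = ".",
    FORMAT = "GT"
  )
  body <- cbind(body, data.table::as.data.table(t(gt)))
  data.table::setnames(body, c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO", "FORMAT", panel$sample_ids))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=rohdice_", as.character(packageVersion("rohdice"))),
           vapply(names(config), function(k) {
             paste0("##rohdice_", k, "=", as.character(config[[k]]))
           }, character(1)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  writeLines(hdr, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' Write / read ROH clusters as TSV
#'
#' The cluster dialect: columns `chrom`, `start_site`, `end_site` (0-based
#' half-open), `bp_start`, `bp_end` (1-based inclusive), `n_members`,
#' `genetic_length_cm`, `consensus`, `member_ids` (comma-separated); the
#' calling parameters (`L`, `W`, `objective`, `seed`, `max_member_het`) are
#' recorded as `#key=value` header lines.
#'
#' @param clusters An `roh_clusters` tibble.
#' @param path File path.
#' @return `write_clusters_tsv()`: `path`, invisibly.  `read_clusters_tsv()`:
#'   a cluster tibble whose `members` column holds sample-id vectors; header
#'   parameters in attribute `params`.
#' @export
write_clusters_tsv <- function(clusters, path) {
  p <- attr(clusters, "params") %||% list()
  df <- data.frame(
    chrom = clusters$chrom,
    start_site = clusters$start_site,
    end_site = clusters$end_site,
    bp_start = clusters$bp_start,
    bp_end = clusters$bp_end,
    n_members = clusters$n_members,
    genetic_length_cm = clusters$genetic_length_cm,
    consensus = clusters$consensus,
    member_ids = vapply(clusters$member_ids, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  tsv_write(df, path, p)
}

#' @rdname write_clusters_tsv
#' @export
read_clusters_tsv <- function(path) {
  df <- tsv_read(path)
  ids <- if (nrow(df)) strsplit(as.character(df$member_ids), ",", fixed = TRUE) else list()
  out <- tibble::tibble(
    cluster_id = paste0("roh", seq_len(nrow(df))),
    chrom = as.character(df$chrom),
    start_site = as.integer(df$start_site),
    end_site = as.integer(df$end_site),
    bp_start = as.integer(df$bp_start),
    bp_end = as.integer(df$bp_end),
    n_members = as.integer(df$n_members),
    genetic_length_cm = as.numeric(df$genetic_length_cm),
    consensus = as.character(df$consensus),
    members = ids,
    member_ids = ids
  )
  attr(out, "params") <- attr(df, "config")
  out
}

#' Write / read IBD segments as BED-like TSV
#'
#' Columns: `individual` (1-based), `bp_start`, `bp_end` (half-open bp
#' span), `group` (descent-group id).
#'
#' @param ibd Tibble of IBD segments.
#' @param path File path.
#' @export
write_ibd_tsv <- function(ibd, path, config = list()) {
  tsv_write(as.data.frame(ibd), path, config)
}

#' @rdname write_ibd_tsv
#' @export
read_ibd_tsv <- function(path) {
  df <- tsv_read(path)
  tibble::tibble(individual = as.integer(df$individual),
                 bp_start = as.integer(df$bp_start),
                 bp_end = as.integer(df$bp_end),
                 group = df$group)
}

#' Write / read a phenotype table
#'
#' Two-column TSV: `sample_id`, `value`.
#'
#' @param phenotype Data frame with `sample_id` and `value`.
#' @param path File path.
#' @export
write_phenotype_tsv <- function(phenotype, path, config = list()) {
  tsv_write(as.data.frame(phenotype)[, c("sample_id", "value")], path, config)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- tsv_read(path)
  tibble::tibble(sample_id = as.character(df$sample_id), value = df$value)
}

#' Read a genetic map
#'
#' Three-column TSV (`chrom`, `pos`, `cm`) used for linear interpolation of
#' cluster genetic lengths.
#'
#' @param path File path.
#' @export
read_genetic_map <- function(path) {
  df <- tsv_read(path)
  tibble::tibble(chrom = as.character(df$chrom), pos = as.integer(df$pos),
                 cm = as.numeric(df$cm))
}

#' Subset a genotype panel to a sample keep-list
#'
#' @param panel A [genotype_panel()].
#' @param ids Sample ids to retain.
#' @export
subset_samples <- function(panel, ids) {
  stopifnot(inherits(panel, "genotype_panel"))
  keep <- panel$sample_ids %in% ids
  if (!any(keep)) stop("no samples left after applying the keep-list")
  genotype_panel(panel$values[keep, , drop = FALSE],
                 sample_ids = panel$sample_ids[keep],
                 meta = panel$site_meta)
}
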