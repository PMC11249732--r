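#' Simulate a coalescent genotype panel with ROH ground truth
#'
#' Simulates `n_diploid` European-ancestry individuals over a `length_bp`
#' region under the Gutenkunst out-of-Africa demographic model (CEU deme,
#' mutation rate 2.36e-8, recombination rate 1e-8, generation time 25 y) by
#' driving `msprime` through the system `python`.  Sites with minor allele
#' frequency below `maf_min` are removed.  Within-individual IBD segments --
#' regions where an individual's two haplotypes descend from the same
#' ancestral node, i.e. true runs of homozygosity -- are extracted from the
#' simulated genealogies together with that ancestor's id, which groups
#' segments that share descent.  Optional genotyping errors re-draw each hit
#' cell uniformly from the other two genotype states.
#'
#' @param n_diploid Number of diploid individuals (>= 2).
#' @param length_bp Region length in bp (>= 1e5); default 10 Mbp.
#' @param error_rate Per-cell genotyping error probability (default 0).
#' @param seed Integer seed (drives both the simulator and the error draws).
#' @param maf_min Minor-allele-frequency cut-off (default 0.01).
#' @param min_ibd_bp Shortest IBD segment retained, in bp (default 5000;
#'   segments far below the span of any cluster of interest carry no
#'   ground-truth signal).
#' @param max_tmrca Optional ceiling on the common-ancestor time (in
#'   generations) for a segment to count as IBD (default `Inf`: descent as
#'   recorded by the simulated genealogy, regardless of age).  A finite
#'   ceiling restricts the truth to recent descent, for which genealogical
#'   identity also implies sequence identity at the retained sites.
#' @param python Path to the python interpreter; defaults to `python` on the
#'   PATH.  A missing interpreter or msprime installation raises an explicit
#'   dependency error; the planted-cluster generator ([plant_clusters()])
#'   needs no python.
#' @return A list with elements `panel` (a [genotype_panel()]) and `ibd`
#'   (a tibble with columns `individual`, `bp_start`, `bp_end`, `group`;
#'   bp spans are half-open).  The demographic model and rates are recorded
#'   in attribute `model`.
#' @export
simulate_coalescent_panel <- function(n_diploid, length_bp = 1e7,
                                      error_rate = 0, seed = 1L,
                                      maf_min = 0.01, min_ibd_bp = 5000,
                                      max_tmrca = Inf, python = NULL) {
  stopifnot(n_diploid >= 2, length_bp >= 1e5,
            error_rate >= 0, error_rate < 1)
  python <- python %||% Sys.which("python")
  if (!nzchar(python)) {
    stop("coalescent simulation needs a python interpreter with msprime; ",
         "none found on the PATH (the planted-cluster generator remains usable)")
  }
  script <- system.file("python", "simulate_panel.py", package = "rohdice")
  outdir <- tempfile("rohdice_sim_")
  dir.create(outdir)
  on.exit(unlink(outdir, recursive = TRUE), add = TRUE)
  status <- system2(python, c(
    shQuote(script),
    "--n-diploid", as.integer(n_diploid),
    "--length-bp", sprintf("%d", as.integer(length_bp)),
    "--seed", derive_seed(seed, 1L) %% 2147483646L + 1L,
    "--min-ibd-bp", sprintf("%d", as.integer(min_ibd_bp)),
    "--max-tmrca", sprintf("%f", max_tmrca),
    "--outdir", shQuote(outdir)
  ), stdout = FALSE, stderr = "")
  if (status != 0L) {
    stop("msprime simulation failed (is msprime installed for ", python, "?)")
  }

  sites <- data.table::fread(file.path(outdir, "sites.tsv"), sep = "\t")
  geno <- as.matrix(data.table::fread(file.path(outdir, "genotypes.tsv"),
                                      sep = "\t", header = FALSE))
  ibd <- data.table::fread(file.path(outdir, "ibd.tsv"), sep = "\t")

  storage.mode(geno) <- "integer"
  af <- colSums(geno) / (2 * nrow(geno))
  keep <- pmin(af, 1 - af) >= maf_min
  geno <- geno[, keep, drop = FALSE]
  meta <- site_meta(sites$pos[keep], chrom = "1")
  panel <- genotype_panel(geno, meta = meta)
  if (error_rate > 0) {
    panel <- apply_genotype_errors(panel, error_rate, derive_seed(seed, 2L))
  }
  out <- list(
    panel = panel,
    ibd = tibble::tibble(individual = ibd$individual + 1L,
                         bp_start = ibd$bp_start, bp_end = ibd$bp_end,
                         group = ibd$group)
  )
  attr(out, "model") <- list(demography = "Gutenkunst et al. 2009 out-of-Africa, CEU deme",
                             mutation_rate = 2.36e-8, recombination_rate = 1e-8,
                             maf_min = maf_min, min_ibd_bp = min_ibd_bp,
                             max_tmrca = max_tmrca)
  out
}

#' Perturb a genotype panel with random genotyping errors
#'
#' Each cell is hit independently with probability `rate`; a hit cell is
#' re-drawn uniformly from the other two genotype states.
#'
#' @param panel A [genotype_panel()].
#' @param rate Per-cell error probability.
#' @param seed Integer seed.
#' @return The perturbed panel.
#' @export
apply_genotype_errors <- function(panel, rate, seed) {
  stopifnot(inherits(panel, "genotype_panel"), rate >= 0, rate < 1)
  if (rate == 0) return(panel)
  v <- panel$values
  with_seed(seed, {
    hit <- which(runif(length(v)) < rate)
    if (length(hit)) {
      v[hit] <- (v[hit] + sample.int(2L, length(hit), replace = TRUE)) %% 3L
    }
  })
  genotype_panel(v, sample_ids = panel$sample_ids, meta = panel$site_meta)
}

#' Ground-truth ROH clusters from IBD segments
#'
#' Builds the interim panel of the evaluation protocol: every cell starts
#' heterozygous (excluded from matching); for each IBD segment the covered
#' individual is set homozygous over the covered sites, with alleles drawn
#' once per (descent group, site) so that individuals inheriting a region
#' from the same ancestor share the same homozygous alleles.  The block
#' finder is then run on this panel with heterozygous cells barred from
#' matching (each is given a per-individual sentinel symbol), yielding the
#' ground-truth clusters for the supplied `L` and `W`.
#'
#' @param ibd Tibble of IBD segments: `individual` (1-based), `bp_start`,
#'   `bp_end` (half-open bp span), `group` (descent-group id, e.g. the
#'   ancestral node).
#' @param meta Site metadata ([site_meta()]) of the panel under evaluation;
#'   a single chromosome.
#' @param L,W Cluster thresholds, as in [call_roh_clusters()].
#' @param seed Integer seed for the allele painting.
#' @param n_individuals Number of individuals; defaults to the largest index
#'   in `ibd`.
#' @return A list with `panel` (the interim [genotype_panel()]) and
#'   `clusters` (ground-truth clusters in the format of
#'   [call_roh_clusters()]).  Segments reaching outside the site grid are
#'   clipped with a warning.
#' @export
ground_truth_clusters <- function(ibd, meta, L, W, seed = 1L,
                                  n_individuals = NULL) {
  validate_site_meta(meta)
  if (length(unique(meta$chrom)) != 1L) {
    stop("ground-truth construction expects a single-chromosome site grid")
  }
  check_block_params(L, W)
  n_individuals <- n_individuals %||% max(ibd$individual)
  M <- as.integer(n_individuals)
  N <- nrow(meta)
  pos <- meta$pos

  lo <- findInterval(ibd$bp_start - 0.5, pos) + 1L
  hi <- findInterval(ibd$bp_end - 0.5, pos)
  outside <- sum(ibd$bp_start < pos[1] | ibd$bp_end > pos[N] + 1L)
  if (outside > 0L) {
    warning(outside, " IBD segment(s) reach outside the site grid; clipped")
  }
  covered <- which(hi >= lo)

  interim <- matrix(1L, M, N)
  for (g in split(covered, ibd$group[covered])) {
    usites <- sort(unique(unlist(lapply(g, function(i) lo[i]:hi[i]))))
    alleles <- integer(N)
    gid <- ibd$group[g[1]]
    alleles[usites] <- 2L * with_seed(derive_seed(seed, gid),
                                      rbinom(length(usites), 1L, 0.5))
    for (i in g) {
      cols <- lo[i]:hi[i]
      interim[ibd$individual[i], cols] <- alleles[cols]
    }
  }

  panel <- genotype_panel(interim, meta = meta)
  # homozygous cells compress to 0/1; heterozygous cells get a per-row
  # sentinel symbol so no two rows can ever match across one
  scan_values <- interim %/% 2L
  het <- interim == 1L
  scan_values[het] <- row(interim)[het] + 1L
  compressed <- binary_panel(interim %/% 2L, het_mask = het, meta = meta)
  clusters <- clusters_from_binary(compressed, L = L, W = W,
                                   objective = "width", seed = seed,
                                   max_member_het = 1, scan_values = scan_values)
  list(panel = panel, clusters = clusters)
}

#' Planted-cluster genotype fixtures
#'
#' Generates a background genotype panel with independent sites in
#' Hardy-Weinberg proportions (allele frequency `allele_freq`; the default
#' 0.1 gives the ~18% heterozygous cells typical of SNP-array data), then
#' overwrites the members of each planted cluster with one shared homozygous
#' diplotype over its span, and finally flips planted cells to heterozygous
#' at the requested noise rate.  Used as a download-free unit fixture with
#' exactly known truth.
#'
#' @param M,N Panel dimensions.
#' @param clusters List of planted clusters, each a list with `start`, `end`
#'   (0-based half-open site span), `n_members`, and optional `noise`
#'   (per-cell heterozygous noise rate inside the span, default 0).
#' @param seed Integer seed.
#' @param allele_freq Background alternative-allele frequency.
#' @return A list with `panel` (a [genotype_panel()]) and `truth` (a tibble
#'   with `start_site`, `end_site`, `members`, `n_members`, `consensus`).
#' @export
plant_clusters <- function(M, N, clusters = list(), seed = 1L,
                           allele_freq = 0.1) {
  for (cl in clusters) {
    stopifnot(cl$start >= 0, cl$end <= N, cl$end > cl$start,
              cl$n_members >= 1, cl$n_members <= M)
  }
  if (length(clusters) >= 2L) {
    spans <- vapply(clusters, function(cl) c(cl$start, cl$end), numeric(2))
    o <- order(spans[1, ])
    if (any(spans[2, o][-ncol(spans)] > spans[1, o][-1])) {
      stop("invalid planted specification: overlapping spans would plant ",
           "contradictory diplotypes")
    }
  }
  with_seed(seed, {
    values <- matrix(rbinom(M * N, 2L, allele_freq), M, N)
    truth_rows <- lapply(clusters, function(cl) {
      members <- sort(sample.int(M, cl$n_members))
      len <- cl$end - cl$start
      cons <- 2L * rbinom(len, 1L, 0.5)
      cols <- (cl$start + 1L):cl$end
      values[members, cols] <<- rep(cons, each = length(members))
      noise <- cl$noise %||% 0
      if (noise > 0) {
        flip <- runif(length(members) * len) < noise
        block <- values[members, cols, drop = FALSE]
        block[flip] <- 1L
        values[members, cols] <<- block
      }
      tibble::tibble(start_site = as.integer(cl$start),
                     end_site = as.integer(cl$end),
                     members = list(members),
                     n_members = length(members),
                     consensus = paste0(cons %/% 2L, collapse = ""))
    })
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else {
      tibble::tibble(start_site = integer(), end_site = integer(),
                     members = list(), n_members = integer(),
                     consensus = character())
    }
    list(panel = genotype_panel(values), truth = truth)
  })
}

# Normalise a cluster row (one-row tibble / list) to list(start, end, members).
as_cluster <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(list(start = x$start_site[[1]], end = x$end_site[[1]],
                members = x$members[[1]]))
  }
  list(start = x$start_site %||% x$start, end = x$end_site %||% x$end,
       members = x$members)
}

#' Overlap ratio between a reported and a truth cluster
#'
#' The overlap is measured in member-by-site cell space: the cells of a
#' cluster are all (individual, site) pairs with the individual among its
#' members and the site inside its span, and the ratio is the overlapping
#' cell count divided by the reported cluster's cell count.  `space =
#' "site"` ignores the membership dimension (span overlap over span length),
#' for sensitivity analysis.
#'
#' @param reported,truth Single clusters (one-row tibbles from
#'   [call_roh_clusters()] / [ground_truth_clusters()], or lists with
#'   `start_site`, `end_site`, `members`).
#' @param space `"cell"` (default) or `"site"`.
#' @return A fraction in `[0, 1]`.
#' @export
overlap_ratio <- function(reported, truth, space = c("cell", "site")) {
  space <- match.arg(space)
  r <- as_cluster(reported)
  t <- as_cluster(truth)
  ov <- overlap_cells(r, t, space)
  ov / cluster_cells(r, space)
}

overlap_cells <- function(r, t, space) {
  span <- max(0L, min(r$end, t$end) - max(r$start, t$start))
  if (space == "site") return(span)
  span * length(intersect(r$members, t$members))
}

cluster_cells <- function(c, space) {
  (c$end - c$start) * if (space == "site") 1L else length(c$members)
}

# All reported-vs-truth overlaps, with a span pre-filter so that only
# genuinely overlapping pairs pay the member-intersection cost.
pair_overlap_stats <- function(reported, truth, space) {
  R <- nrow(reported)
  T <- nrow(truth)
  rep_best <- numeric(R)
  truth_cum <- numeric(T)
  if (T > 0L && R > 0L) {
    ts <- truth$start_site
    te <- truth$end_site
    tcells <- (te - ts) *
      (if (space == "site") 1L else vapply(truth$members, length, integer(1)))
    for (i in seq_len(R)) {
      r <- as_cluster(reported[i, ])
      cand <- which(ts < r$end & te > r$start)
      if (!length(cand)) next
      ov <- vapply(cand, function(j) {
        overlap_cells(r, list(start = ts[j], end = te[j],
                              members = truth$members[[j]]), space)
      }, numeric(1))
      rep_best[i] <- max(ov) / cluster_cells(r, space)
      truth_cum[cand] <- truth_cum[cand] + ov / tcells[cand]
    }
  }
  list(rep_best = rep_best, truth_cum = pmin(1, truth_cum))
}

#' Detection accuracy of reported clusters
#'
#' For each reported cluster, the ground-truth cluster with the maximum cell
#' overlap is found and the overlap ratio computed; the accuracy is the mean
#' of these ratios, i.e. the average fraction of each reported cluster that
#' belongs to a single true cluster.
#'
#' @param reported,truth Cluster tibbles (`start_site`, `end_site`,
#'   `members`).  `reported` must be non-empty.
#' @inheritParams overlap_ratio
#' @return A fraction in `[0, 1]`.
#' @export
detection_accuracy <- function(reported, truth, space = c("cell", "site")) {
  space <- match.arg(space)
  if (nrow(reported) == 0L) stop("accuracy is undefined for an empty reported set")
  mean(pair_overlap_stats(reported, truth, space)$rep_best)
}

#' Detection power against ground-truth clusters
#'
#' For each ground-truth cluster, the overlaps with all reported clusters
#' are accumulated (a large true cluster may be recovered piecewise by
#' several reported ones) and capped at 1; the power is the mean of these
#' cumulative overlap ratios over the truth set.
#'
#' @inheritParams detection_accuracy
#' @return A fraction in `[0, 1]`.
#' @export
detection_power <- function(reported, truth, space = c("cell", "site")) {
  space <- match.arg(space)
  if (nrow(truth) == 0L) stop("power is undefined for an empty truth set")
  mean(pair_overlap_stats(reported, truth, space)$truth_cum)
}

#' Joint accuracy/power report
#'
#' @inheritParams detection_accuracy
#' @return A list with `accuracy`, `power`, `frac_half` (fraction of
#'   reported clusters whose best truth overlap ratio is at least 1/2),
#'   `n_reported` and `n_truth`.
#' @export
evaluate_detection <- function(reported, truth, space = c("cell", "site")) {
  space <- match.arg(space)
  if (nrow(reported) == 0L) stop("evaluation is undefined for an empty reported set")
  if (nrow(truth) == 0L) stop("evaluation is undefined for an empty truth set")
  st <- pair_overlap_stats(reported, truth, space)
  list(accuracy = mean(st$rep_best),
       power = mean(st$truth_cum),
       frac_half = mean(st$rep_best >= 0.5),
       n_reported = nrow(reported),
       n_truth = nrow(truth))
}
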