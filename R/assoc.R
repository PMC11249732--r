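#' Chi-squared association between cluster membership and a binary trait
#'
#' Builds the 2x2 contingency table
#' * `D1` -- cluster members with the disease,
#' * `N1` -- cluster members without it,
#' * `D2` -- diseased non-members (`|cases| - D1`),
#' * `N2` -- the remainder (`M - D1 - N1 - D2`),
#'
#' and applies Pearson's chi-squared test with 1 degree of freedom (no
#' continuity correction by default, matching a plain chi-squared test; set
#' `correct = TRUE` for Yates' correction).  A table with any zero expected
#' cell is flagged degenerate and gets an undefined p-value.
#'
#' @param members Cluster members (sample ids or indices).
#' @param cases Diseased samples, same identifier space.
#' @param M Cohort size (>= 4).
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return A list of class `assoc_result`: `D1`, `N1`, `D2`, `N2`, `M`,
#'   `statistic`, `p_value`, `odds_ratio` (`(D1*N2)/(N1*D2)`; `Inf` flagged
#'   when the denominator is 0), `carrier_freq` (`(D1+N1)/M`) and
#'   `degenerate`.
#' @export
chi_square_association <- function(members, cases, M, correct = FALSE) {
  stopifnot(M >= 4)
  M <- as.integer(M)
  members <- unique(members)
  cases <- unique(cases)
  D1 <- length(intersect(members, cases))
  N1 <- length(members) - D1
  D2 <- length(cases) - D1
  N2 <- M - D1 - N1 - D2
  if (N2 < 0) stop("counts exceed the cohort size M")
  tab <- matrix(c(D1, N1, D2, N2), nrow = 2)
  expected <- outer(rowSums(tab), colSums(tab)) / M
  degenerate <- any(expected == 0)
  if (degenerate) {
    stat <- NA_real_
    p <- NA_real_
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    stat <- unname(ct$statistic)
    p <- ct$p.value
  }
  or <- if (N1 * D2 == 0) Inf else (D1 * N2) / (N1 * D2)
  structure(list(D1 = D1, N1 = N1, D2 = D2, N2 = N2, M = M,
                 statistic = stat, p_value = p, odds_ratio = or,
                 carrier_freq = (D1 + N1) / M, degenerate = degenerate),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> chi2=%.4g p=%.3g OR=%.3g carrier=%.3g%% (D1=%d N1=%d D2=%d N2=%d)%s\n",
              x$statistic, x$p_value, x$odds_ratio, 100 * x$carrier_freq,
              x$D1, x$N1, x$D2, x$N2,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Test every cluster against a binary phenotype
#'
#' Applies [chi_square_association()] to each cluster of a
#' [call_roh_clusters()] result.
#'
#' @param clusters An `roh_clusters` tibble.
#' @param cases Sample ids of the diseased individuals.
#' @param sample_ids All sample ids in the cohort.
#' @return A tibble with one row per cluster: id, coordinates, the four
#'   counts, `chi2`, `p`, `odds_ratio`, `carrier_freq`.
#' @export
associate_clusters <- function(clusters, cases, sample_ids) {
  M <- length(sample_ids)
  res <- lapply(seq_len(nrow(clusters)), function(i) {
    a <- chi_square_association(clusters$member_ids[[i]],
                                intersect(cases, sample_ids), M)
    tibble::tibble(cluster_id = clusters$cluster_id[i],
                   chrom = clusters$chrom[i],
                   bp_start = clusters$bp_start[i],
                   bp_end = clusters$bp_end[i],
                   D1 = a$D1, N1 = a$N1, D2 = a$D2, N2 = a$N2,
                   chi2 = a$statistic, p = a$p_value,
                   odds_ratio = a$odds_ratio, carrier_freq = a$carrier_freq)
  })
  if (!length(res)) {
    return(tibble::tibble(cluster_id = character(), chrom = character(),
                          bp_start = integer(), bp_end = integer(),
                          D1 = integer(), N1 = integer(), D2 = integer(),
                          N2 = integer(), chi2 = numeric(), p = numeric(),
                          odds_ratio = numeric(), carrier_freq = numeric()))
  }
  do.call(rbind, res)
}

#' Linkage disequilibrium between a cluster and a SNP
#'
#' Adapts the two-locus D/D' measures to a cluster-membership "locus" and a
#' SNP: with `p_R` the cluster-membership frequency, `p_S` the alternative-
#' allele frequency and `p_RS` the joint frequency, `D = p_RS - p_R * p_S`.
#' The joint frequency is counted at the allele level (each individual
#' contributes two alleles, members contribute their alternative-allele
#' dosage), which keeps the implied 2x2 table consistent and `|D'| <= 1`.
#' Normalisation modes:
#' * `"standard"` -- the textbook normalisation, `D' = D / Dmax` with
#'   `Dmax = min(p_R p_s, p_r p_S)` for `D > 0` and
#'   `Dmax = min(p_R p_S, p_r p_s)` for `D < 0`; `D' = 0` when `D = 0`.
#' * `"max-form"` -- evaluates the max-based denominator form
#'   (`max(p_R p_S, p_r p_s)` resp. `max(-p_R p_S, -p_r p_s)`) literally,
#'   without division; provided for comparability only.
#'
#' The result is flagged undefined when either margin is fixed
#' (`p_R` or `p_S` in \{0, 1\}).
#'
#' @param members Cluster members (indices into the cohort or ids matching
#'   `names(snp_genotypes)`).
#' @param snp_genotypes Per-sample \{0,1,2\} genotypes at the SNP.
#' @param mode Normalisation mode, see above.
#' @return A list of class `linkage_result` with `p_R`, `p_S`, `p_RS`,
#'   `p_r`, `p_s`, `D`, `d_prime`, `mode` and `defined`.
#' @export
d_prime <- function(members, snp_genotypes, mode = c("standard", "max-form")) {
  mode <- match.arg(mode)
  M <- length(snp_genotypes)
  stopifnot(M >= 1, all(snp_genotypes %in% 0:2))
  if (is.character(members)) {
    stopifnot(!is.null(names(snp_genotypes)))
    members <- match(members, names(snp_genotypes))
    stopifnot(!anyNA(members))
  }
  p_R <- length(members) / M
  p_S <- sum(snp_genotypes) / (2 * M)
  p_RS <- sum(snp_genotypes[members]) / (2 * M)
  p_r <- 1 - p_R
  p_s <- 1 - p_S
  D <- p_RS - p_R * p_S
  defined <- !(p_R %in% c(0, 1)) && !(p_S %in% c(0, 1))
  dp <- NA_real_
  if (defined) {
    if (mode == "standard") {
      dp <- if (D > 0) {
        D / min(p_R * p_s, p_r * p_S)
      } else if (D < 0) {
        D / min(p_R * p_S, p_r * p_s)
      } else {
        0
      }
    } else {
      dp <- if (D < 0) max(-p_R * p_S, -p_r * p_s) else max(p_R * p_S, p_r * p_s)
    }
  }
  structure(list(p_R = p_R, p_S = p_S, p_RS = p_RS, p_r = p_r, p_s = p_s,
                 D = D, d_prime = dp, mode = mode, defined = defined),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage_result> D=%.4g D'=%.4g (p_R=%.3g p_S=%.3g p_RS=%.3g, %s%s)\n",
              x$D, x$d_prime, x$p_R, x$p_S, x$p_RS, x$mode,
              if (x$defined) "" else ", undefined"))
  invisible(x)
}

#' Per-site cluster score and hotspot/coldspot calls
#'
#' Assigns each site the member count of the largest cluster covering it (0
#' when none).  Hotspots are sites whose score strictly exceeds the 99.5th
#' percentile of all site scores; coldspots fall strictly below the 0.5th
#' percentile.
#'
#' @param clusters An `roh_clusters` tibble (needs `chrom`, `start_site`,
#'   `end_site`, `n_members`).
#' @param meta Site metadata of the scanned panel.
#' @param hot_q,cold_q Percentiles for the two calls.
#' @return A list with `scores` (tibble: `chrom`, `pos`, `score`),
#'   `hotspots`, `coldspots` (site indices) and the two thresholds.
#' @export
site_score_scan <- function(clusters, meta, hot_q = 0.995, cold_q = 0.005) {
  validate_site_meta(meta)
  score <- integer(nrow(meta))
  for (i in seq_len(nrow(clusters))) {
    idx <- which(meta$chrom == clusters$chrom[i])
    cols <- idx[(clusters$start_site[i] + 1L):clusters$end_site[i] - idx[1] + 1L]
    score[cols] <- pmax(score[cols], clusters$n_members[i])
  }
  hot_thr <- quantile(score, hot_q, names = FALSE)
  cold_thr <- quantile(score, cold_q, names = FALSE)
  list(scores = tibble::tibble(chrom = meta$chrom, pos = meta$pos, score = score),
       hotspots = which(score > hot_thr),
       coldspots = which(score < cold_thr),
       hot_threshold = hot_thr, cold_threshold = cold_thr)
}

#' Simulate a quantitative phenotype from cluster membership
#'
#' Draws `Y = X * beta + N(0, sigma2)` where `X` indicates membership in the
#' causal cluster.
#'
#' @param members Causal cluster members (indices in `1..M`).
#' @param M Cohort size.
#' @param beta Effect size.
#' @param sigma2 Noise variance (> 0; default 0.1).
#' @param seed Integer seed.
#' @return A list of class `phenotype_sim` with `X`, `Y`, `beta`, `sigma2`.
#' @export
simulate_phenotype <- function(members, M, beta, sigma2 = 0.1, seed = 1L) {
  stopifnot(sigma2 > 0, M >= 1)
  X <- integer(M)
  X[members] <- 1L
  Y <- with_seed(seed, X * beta + rnorm(M, 0, sqrt(sigma2)))
  structure(list(X = X, Y = Y, beta = beta, sigma2 = sigma2),
            class = "phenotype_sim")
}

# p-value of the slope of a simple linear regression of y on x, via the
# correlation form of the t-test (identical to the equal-variance two-group
# t-test when x is an indicator).  Vectorised over the columns of x.
slope_pvalues <- function(y, x) {
  n <- length(y)
  r <- suppressWarnings(as.numeric(stats::cor(y, x)))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[is.na(r)] <- NA_real_ # constant predictor
  p
}

#' Power comparison: cluster-level test versus single-SNP association models
#'
#' Per replicate, a causal cluster is drawn uniformly, a quantitative
#' phenotype `Y = X * beta + N(0, sigma2)` is simulated from its membership
#' indicator, and four tests are evaluated under Bonferroni correction:
#'
#' * `roh` -- membership/phenotype two-group test per cluster; success when
#'   the causal cluster's p-value beats `alpha / n_clusters`;
#' * `additive`, `dominant`, `recessive` -- per-site linear regression of
#'   `Y` on the 0/1/2 dosage, the carrier indicator (`dosage >= 1`), or the
#'   homozygous-alternative indicator (`dosage == 2`); success when any site
#'   inside the causal cluster's span beats `alpha / n_sites`.
#'
#' Power is the success fraction over replicates, per method and effect
#' size.  With `compute_fwe = TRUE` the family-wise error indicator (any
#' test anywhere significant) is tracked as well, which is the relevant
#' quantity at `beta = 0`.  Sites whose coding is constant are skipped.
#'
#' @param panel A [genotype_panel()].
#' @param clusters Clusters called on that panel ([call_roh_clusters()]).
#' @param betas Effect-size grid (default 0 to 0.3 in steps of 0.05).
#' @param n_reps Phenotype replicates per effect size (default 100).
#' @param alpha Family-wise significance level before correction.
#' @param sigma2 Phenotype noise variance.
#' @param seed Integer seed.
#' @param compute_fwe Also evaluate all tests genome-wide for the
#'   family-wise error rate (slower).
#' @return A tibble with columns `method`, `beta`, `power`, `n_reps` (and
#'   `fwe` when requested).
#' @export
power_comparison <- function(panel, clusters, betas = seq(0, 0.3, by = 0.05),
                             n_reps = 100, alpha = 0.05, sigma2 = 0.1,
                             seed = 1L, compute_fwe = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"), nrow(clusters) >= 1, n_reps >= 1)
  G <- panel$values
  M <- nrow(G)
  n_sites <- ncol(G)
  n_cl <- nrow(clusters)
  thr_cl <- alpha / n_cl
  thr_site <- alpha / n_sites

  codings <- list(
    additive = function(cols) G[, cols, drop = FALSE],
    dominant = function(cols) (G[, cols, drop = FALSE] >= 1L) * 1L,
    recessive = function(cols) (G[, cols, drop = FALSE] == 2L) * 1L
  )
  membership <- matrix(0L, M, n_cl)
  for (i in seq_len(n_cl)) membership[clusters$members[[i]], i] <- 1L

  methods <- c("roh", names(codings))
  success <- array(0, dim = c(length(methods), length(betas)),
                   dimnames = list(methods, NULL))
  fwe <- array(0, dim = dim(success), dimnames = dimnames(success))

  for (bi in seq_along(betas)) {
    beta <- betas[bi]
    for (rep in seq_len(n_reps)) {
      rs <- derive_seed(seed, bi * 100000L + rep)
      ci <- with_seed(rs, sample.int(n_cl, 1L))
      sim <- simulate_phenotype(clusters$members[[ci]], M, beta, sigma2,
                                seed = derive_seed(rs, 1L))
      Y <- sim$Y
      span <- (clusters$start_site[ci] + 1L):clusters$end_site[ci]

      p_causal <- slope_pvalues(Y, membership[, ci, drop = FALSE])
      if (!is.na(p_causal) && p_causal < thr_cl) {
        success["roh", bi] <- success["roh", bi] + 1
      }
      for (m in names(codings)) {
        p_span <- slope_pvalues(Y, codings[[m]](span))
        if (any(p_span < thr_site, na.rm = TRUE)) {
          success[m, bi] <- success[m, bi] + 1
        }
      }
      if (compute_fwe) {
        p_all_cl <- slope_pvalues(Y, membership)
        if (any(p_all_cl < thr_cl, na.rm = TRUE)) {
          fwe["roh", bi] <- fwe["roh", bi] + 1
        }
        for (m in names(codings)) {
          p_all <- slope_pvalues(Y, codings[[m]](seq_len(n_sites)))
          if (any(p_all < thr_site, na.rm = TRUE)) {
            fwe[m, bi] <- fwe[m, bi] + 1
          }
        }
      }
    }
  }

  # column-major unrolling of the methods x betas arrays
  out <- tibble::tibble(
    method = rep(methods, times = length(betas)),
    beta = rep(betas, each = length(methods)),
    power = as.numeric(success) / n_reps,
    n_reps = as.integer(n_reps)
  )
  if (compute_fwe) out$fwe <- as.numeric(fwe) / n_reps
  attr(out, "seed") <- seed
  out
}
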