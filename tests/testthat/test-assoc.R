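test_that("a perfectly balanced table gives chi2 = 0, p = 1, OR = 1", {
  r <- chi_square_association(members = 1:20, cases = c(1:10, 21:30), M = 40)
  expect_equal(r$D1, 10L)
  expect_equal(r$N1, 10L)
  expect_equal(r$D2, 10L)
  expect_equal(r$N2, 10L)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$carrier_freq, 0.5)
})

test_that("chi-squared matches the direct sum over (O-E)^2/E on the mortality-style table", {
  # carriers: 76 tested, 11 died; cohort: 8120 tested, 201 died
  members <- paste0("c", 1:76)
  cases <- c(paste0("c", 1:11), paste0("x", 1:190))
  cohort <- 8120
  r <- chi_square_association(members, cases, cohort)
  expect_identical(c(r$D1, r$N1, r$D2, r$N2), c(11L, 65L, 190L, 7854L))
  tab <- matrix(c(11, 65, 190, 7854), 2)
  E <- outer(rowSums(tab), colSums(tab)) / cohort
  stat <- sum((tab - E)^2 / E)
  expect_equal(r$statistic, stat, tolerance = 1e-9)
  expect_equal(r$p_value, stats::pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$odds_ratio, (11 * 7854) / (65 * 190), tolerance = 1e-12)
})

test_that("doubling every cell doubles the chi-squared statistic", {
  set.seed(19)
  for (i in 1:10) {
    cnt <- sample(5:50, 4)
    mk <- function(f) {
      D1 <- cnt[1] * f; N1 <- cnt[2] * f; D2 <- cnt[3] * f; N2 <- cnt[4] * f
      members <- seq_len(D1 + N1)
      cases <- c(seq_len(D1), D1 + N1 + seq_len(D2))
      chi_square_association(members, cases, D1 + N1 + D2 + N2)
    }
    expect_equal(mk(2)$statistic, 2 * mk(1)$statistic, tolerance = 1e-9)
  }
})

test_that("swapping disease and health labels leaves chi-squared unchanged", {
  members <- 1:30
  cases <- c(5:20, 60:90)
  M <- 120
  r1 <- chi_square_association(members, cases, M)
  r2 <- chi_square_association(members, setdiff(1:M, cases), M)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
})

test_that("degenerate tables are flagged instead of tested", {
  r <- chi_square_association(members = 1:5, cases = integer(0), M = 20)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
})

test_that("d-prime is 1 under perfect linkage and 0 under independence", {
  g <- c(rep(2L, 10), rep(0L, 30))
  perfect <- d_prime(members = 1:10, snp_genotypes = g)
  expect_equal(perfect$d_prime, 1)
  expect_equal(perfect$p_RS, perfect$p_R)
  expect_equal(perfect$p_S, perfect$p_R)

  # membership carrying the population allele frequency: D = 0
  g2 <- rep(c(0L, 1L, 2L, 1L), 25)
  ind <- d_prime(members = seq(1, 100, by = 4) + 1L, snp_genotypes = g2)
  expect_equal(ind$D, 0)
  expect_equal(ind$d_prime, 0)

  und <- d_prime(members = 1:4, snp_genotypes = rep(0L, 4))
  expect_false(und$defined)
  expect_true(is.na(und$d_prime))
})

test_that("standard-mode d-prime matches a textbook 2x2 table oracle and stays within [-1, 1]", {
  textbook_dprime <- function(members, g) {
    M <- length(g)
    nRS <- sum(g[members])
    nR <- 2 * length(members)
    nS <- sum(g)
    pRS <- nRS / (2 * M); pR <- nR / (2 * M); pS <- nS / (2 * M)
    D <- pRS - pR * pS
    if (D == 0) return(0)
    Dmax <- if (D > 0) min(pR * (1 - pS), (1 - pR) * pS)
            else min(pR * pS, (1 - pR) * (1 - pS))
    D / Dmax
  }
  set.seed(23)
  for (i in 1:50) {
    M <- 500
    g <- sample(0:2, M, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    members <- sample(M, sample(5:200, 1))
    r <- d_prime(members, g)
    if (!r$defined) next
    expect_equal(r$d_prime, textbook_dprime(members, g), tolerance = 1e-12)
    expect_lte(abs(r$d_prime), 1 + 1e-12)
  }
  # empty off-diagonal cell (no member lacks the allele) forces |D'| = 1
  g <- c(rep(2L, 20), sample(0:2, 80, replace = TRUE, prob = c(.6, .3, .1)))
  r <- d_prime(members = 1:20, snp_genotypes = g)
  expect_equal(abs(r$d_prime), 1, tolerance = 1e-12)
})

test_that("the max-form mode evaluates the printed denominator expression literally", {
  g <- c(rep(2L, 10), rep(1L, 10), rep(0L, 20))
  r <- d_prime(members = 1:10, snp_genotypes = g, mode = "max-form")
  pR <- 0.25; pS <- 30 / 80
  expect_equal(r$d_prime, max(pR * pS, (1 - pR) * (1 - pS)), tolerance = 1e-12)
})

test_that("site scores are the maximum member count over covering clusters", {
  meta <- site_meta(seq_len(10000))
  one <- tibble::tibble(chrom = "1", start_site = 9L, end_site = 19L,
                        n_members = 150L)
  scan1 <- site_score_scan(one, meta)
  # ten sites at 150 on a 10,000-site grid: the 99.5th percentile of the
  # score distribution is 0, so exactly those sites are the hotspots
  expect_setequal(scan1$hotspots, 10:19)
  expect_equal(length(scan1$coldspots), 0L) # floor of the distribution is 0

  clusters <- tibble::tibble(chrom = "1",
                             start_site = c(9L, 14L), end_site = c(19L, 25L),
                             n_members = c(150L, 40L))
  scan <- site_score_scan(clusters, meta)
  # the larger overlapping cluster wins on shared sites
  expect_equal(scan$scores$score[10:15], rep(150L, 6))
  expect_equal(scan$scores$score[20:25], rep(40L, 6))
  expect_equal(scan$scores$score[26], 0L)
  expect_setequal(scan$hotspots, 10:25)
  # order invariance
  scan2 <- site_score_scan(clusters[2:1, ], meta)
  expect_identical(scan$scores$score, scan2$scores$score)
  # no clusters: all zero, no hotspots
  scan0 <- site_score_scan(clusters[0, ], meta)
  expect_true(all(scan0$scores$score == 0L))
  expect_equal(length(scan0$hotspots), 0L)
})

test_that("phenotype simulation follows Y = X beta + noise", {
  s <- simulate_phenotype(members = 1:50, M = 10000, beta = 0, sigma2 = 0.1, seed = 3)
  expect_equal(sum(s$X), 50)
  expect_lt(abs(mean(s$Y)), 4 * sqrt(0.1 / 10000))
  v <- var(s$Y[s$X == 0])
  expect_gt(v, 0.09)
  expect_lt(v, 0.11)
  # near-zero noise separates carriers exactly
  s2 <- simulate_phenotype(members = 1:50, M = 200, beta = 0.3, sigma2 = 1e-12, seed = 4)
  expect_true(all(s2$Y[1:50] > 0.29))
  expect_true(all(abs(s2$Y[-(1:50)]) < 0.01))
  # determinism
  s3 <- simulate_phenotype(members = 1:50, M = 200, beta = 0.3, sigma2 = 0.1, seed = 7)
  s4 <- simulate_phenotype(members = 1:50, M = 200, beta = 0.3, sigma2 = 0.1, seed = 7)
  expect_identical(s3$Y, s4$Y)
})

test_that("association power rises to 1 in the vanishing-noise limit and is monotone in beta", {
  pf <- plant_clusters(120, 600,
                       clusters = list(list(start = 50, end = 200, n_members = 40),
                                       list(start = 300, end = 450, n_members = 25)),
                       seed = 19)
  cl <- call_roh_clusters(pf$panel, L = 100, W = 20, seed = 2)
  lim <- power_comparison(pf$panel, cl, betas = 0.3, n_reps = 20,
                          sigma2 = 1e-8, seed = 5)
  expect_equal(lim$power[lim$method == "roh"], 1)

  tab <- power_comparison(pf$panel, cl, betas = c(0, 0.15, 0.3), n_reps = 60,
                          seed = 6)
  for (m in unique(tab$method)) {
    p <- tab$power[tab$method == m]
    for (j in 2:length(p)) {
      # a drop must not be larger than binomial noise allows (1% one-sided)
      if (p[j] < p[j - 1]) {
        bt <- binom.test(round(p[j] * 60), 60, p = max(p[j - 1], 1e-9),
                         alternative = "less")
        expect_gt(bt$p.value, 0.01)
      }
    }
  }
})
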