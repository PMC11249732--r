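test_that("genotype compression is deterministic for homozygous cells and seeded for heterozygous ones", {
  hom <- genotype_panel(rbind(c(0L, 2L, 0L), c(2L, 2L, 0L)))
  a <- compress_genotypes(hom, seed = 1)
  b <- compress_genotypes(hom, seed = 99)
  expect_identical(a$values, rbind(c(0L, 1L, 0L), c(1L, 1L, 0L)))
  expect_identical(a$values, b$values)
  expect_false(any(a$het_mask))

  het <- genotype_panel(matrix(1L, 1, 1000))
  c1 <- compress_genotypes(het, seed = 5)
  c2 <- compress_genotypes(het, seed = 5)
  c3 <- compress_genotypes(het, seed = 6)
  expect_identical(c1$values, c2$values)
  expect_true(all(c1$het_mask))
  # Bernoulli(1/2) mean over 1000 draws: [0.45, 0.55] fails with p < 1e-3
  expect_gte(mean(c1$values), 0.45)
  expect_lte(mean(c1$values), 0.55)
  # differing seeds may differ only where the mask is true (everywhere here)
  mixed <- genotype_panel(rbind(c(0L, 1L, 2L)))
  m1 <- compress_genotypes(mixed, seed = 1)
  m2 <- compress_genotypes(mixed, seed = 2)
  expect_identical(m1$values[!m1$het_mask], m2$values[!m2$het_mask])

  expect_error(genotype_panel(rbind(c(0L, 3L))), "outside \\{0,1,2\\}")
})

test_that("consensus equals the shared sequence and flags disagreement", {
  X <- rbind(c(0L, 1L, 1L, 0L), c(0L, 1L, 1L, 0L), c(1L, 1L, 0L, 0L))
  blk <- list(start = 0L, end = 4L, members = c(1L, 2L))
  expect_identical(consensus_of(blk, X), "0110")
  single <- list(start = 1L, end = 3L, members = 3L)
  expect_identical(consensus_of(single, X), "10")
  bad <- list(start = 0L, end = 4L, members = c(1L, 3L))
  expect_error(consensus_of(bad, X), "disagree")
})

test_that("the caller recovers a planted cluster and excludes high-heterozygosity members", {
  pf <- planted_fixture(seed = 42)
  cl <- call_roh_clusters(pf$panel, L = 100, W = 100, seed = 9)
  expect_gte(nrow(cl), 1L)
  best <- which.max(vapply(seq_len(nrow(cl)), function(i)
    overlap_ratio(cl[i, ], pf$truth[1, ]), numeric(1)))
  expect_setequal(cl$members[[best]], pf$truth$members[[1]])
  expect_true(all(cl$member_het[[best]] <= 0.01))
  expect_identical(cl$chrom[best], "1")
  expect_identical(cl$bp_start[best], cl$start_site[best] + 1L)

  # corrupt one planted member with 2% in-block heterozygous sites: the
  # member must be filtered out of the cluster
  v <- pf$panel$values
  victim <- pf$truth$members[[1]][1]
  span_cols <- 401:550
  flip <- sample(span_cols, 3)
  v[victim, flip] <- 1L
  cl2 <- call_roh_clusters(genotype_panel(v), L = 100, W = 100, seed = 9)
  best2 <- which.max(vapply(seq_len(nrow(cl2)), function(i)
    overlap_ratio(cl2[i, ], pf$truth[1, ]), numeric(1)))
  expect_false(victim %in% cl2$members[[best2]])
})

test_that("recovery is robust to the compression seed", {
  pf <- planted_fixture(seed = 17)
  truth <- pf$truth[1, ]
  for (seed in 1:10) {
    cl <- call_roh_clusters(pf$panel, L = 100, W = 100, seed = seed)
    best <- which.max(vapply(seq_len(nrow(cl)), function(i)
      overlap_ratio(cl[i, ], truth), numeric(1)))
    expect_lte(abs(cl$start_site[best] - truth$start_site), 2L)
    expect_lte(abs(cl$end_site[best] - truth$end_site), 2L)
    shared <- length(intersect(cl$members[[best]], truth$members[[1]]))
    expect_gte(shared / truth$n_members, 0.95)
  }
})

test_that("merging identical-span clusters unites members and is idempotent", {
  blocks <- tibble::tibble(
    chrom = "1",
    start = c(0L, 0L, 0L),
    end = c(4L, 4L, 4L),
    members = list(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
    consensus = c("0101", "0101", "0011")
  )
  het <- list(c(0, 0), c(0, 0), c(0, 0))
  m1 <- rohdice:::merge_clusters(blocks, het)
  expect_equal(nrow(m1$blocks), 2L)
  merged <- m1$blocks[m1$blocks$consensus == "0101", ]
  expect_identical(merged$members[[1]], 1:4)
  m2 <- rohdice:::merge_clusters(m1$blocks, m1$member_het)
  expect_identical(m2$blocks$members, m1$blocks$members)
  expect_identical(m2$blocks$consensus, m1$blocks$consensus)
})

test_that("chromosomes are scanned independently", {
  set.seed(5)
  v <- matrix(rbinom(40 * 60, 2, 0.1), 40, 60)
  # identical diplotype across the chromosome boundary: must not be joined
  v[1:10, 26:35] <- rep(rep(c(0L, 2L), 5), each = 10)
  meta <- site_meta(c(1:30, 1:30), chrom = rep(c("1", "2"), each = 30))
  cl <- call_roh_clusters(genotype_panel(v, meta = meta), L = 5, W = 5, seed = 1)
  expect_true(all(cl$end_site <= 30 | cl$start_site >= 30))
  for (i in seq_len(nrow(cl))) {
    ch <- meta$chrom[(cl$start_site[i] + 1):cl$end_site[i]]
    expect_equal(length(unique(ch)), 1L)
    expect_identical(unique(ch), cl$chrom[i])
  }
})

test_that("genetic lengths come from the map by interpolation and are NA without one", {
  pf <- plant_clusters(30, 60, list(list(start = 10, end = 40, n_members = 20)), seed = 3)
  cl <- call_roh_clusters(pf$panel, L = 20, W = 10, seed = 1)
  expect_true(all(is.na(cl$genetic_length_cm)))
  gm <- data.frame(chrom = "1", pos = c(1, 60), cm = c(0, 5.9))
  clm <- call_roh_clusters(pf$panel, L = 20, W = 10, seed = 1, genetic_map = gm)
  expect_true(all(!is.na(clm$genetic_length_cm)))
  i <- which.max(clm$n_members)
  expected <- (clm$bp_end[i] - clm$bp_start[i]) * 5.9 / 59
  expect_equal(clm$genetic_length_cm[i], expected, tolerance = 1e-8)
})
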