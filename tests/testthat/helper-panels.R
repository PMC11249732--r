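# Shared fixture builders for the test suite.  Everything is generated in
# code; no stored data.

random_binary_panel <- function(M, N, p1 = 0.4) {
  matrix(sample(0:1, M * N, replace = TRUE, prob = c(1 - p1, p1)), M, N)
}

# Canonical identity of a block set: (start, end, member set) triples.
block_keys <- function(blocks) {
  if (nrow(blocks) == 0L) return(character())
  vapply(seq_len(nrow(blocks)), function(b) {
    paste(blocks$start[b], blocks$end[b],
          paste(sort(blocks$members[[b]]), collapse = ","))
  }, character(1))
}

# Union of member x site cells covered by a block set, as "row:site" strings.
covered_cells <- function(blocks) {
  if (nrow(blocks) == 0L) return(character())
  unique(unlist(lapply(seq_len(nrow(blocks)), function(b) {
    sites <- blocks$start[b]:(blocks$end[b] - 1L)
    as.vector(outer(blocks$members[[b]], sites, paste, sep = ":"))
  })))
}

# A small panel shaped like the worked illustration of the two objectives:
# rows 1-3 identical over sites [1,4) with row 4 matching only [2,4)
# (width-maximal block at end 4), and rows 2,3,5 identical over [4,8) with
# a mismatch on either flank (length-maximal block).
figure_panel <- function() {
  rbind(
    c(0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 1L),
    c(1L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L),
    c(1L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 0L, 1L),
    c(0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L)
  )
}

# Planted fixture matching the recovery study: 120 of 200 individuals share
# a 150-site homozygous diplotype on an ~18%-heterozygous background.
planted_fixture <- function(seed = 42, noise = 0) {
  plant_clusters(200, 1200,
                 clusters = list(list(start = 400, end = 550,
                                      n_members = 120, noise = noise)),
                 seed = seed)
}

is_permutation <- function(a, M) identical(sort(a), seq_len(M))
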