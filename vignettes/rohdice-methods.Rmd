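---
title: "ROH diplotype cluster enumeration: model, algorithms and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROH diplotype cluster enumeration: model, algorithms and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A run of homozygosity (ROH) is a contiguous stretch of a diploid genome over
which an individual's two haplotypes are identical, typically because both
were inherited from a recent common ancestor.  Classical ROH analyses
aggregate each individual's ROH content into a single number, which discards
the information needed to map loci.  This package enumerates *ROH diplotype
clusters*: sets of at least $W$ individuals that share an identical
homozygous diplotype (the same consensus allele sequence) over at least $L$
consecutive biallelic sites.  Such clusters localise a shared recessive
haplotype and can be tested directly against phenotypes.

## From genotypes to a binary panel

The input is an $M \times N$ genotype matrix over $\{0,1,2\}$ (counts of the
alternative allele).  `compress_genotypes()` maps $0 \mapsto 0$,
$2 \mapsto 1$, and assigns each heterozygous cell a Bernoulli(1/2) allele
from a single seeded generator.  Two properties motivate this compression:

* a true ROH diplotype is homozygous at almost all of its sites, so members
  of a real cluster keep an identical compressed sequence with high
  probability;
* a non-ROH pair agrees at an independent heterozygous site with probability
  1/2, so the chance that spurious identical stretches survive $L$ on the
  order of 100 sites is negligible (of order $2^{-\#\text{het sites}}$).

The seed is recorded in every output header; re-running with the same
configuration reproduces outputs byte for byte.  The `het_mask` of the
compressed panel remembers which cells were heterozygous, which the caller's
post-processing uses.

## PBWT and block-maximal matches

The positional Burrows-Wheeler transform maintains, site by site, the
ordering $a_k$ of sequences by reversed prefix (ending just before site $k$)
and the divergence array $d_k$, where $d_k[i]$ is the first site of the
match between the sequences at sorted positions $i$ and $i-1$.  Sequences
identical over a window are adjacent in this ordering, so clusters appear as
runs of consecutive entries with small divergence.  The update is the
standard stable bucket step; our implementation accepts arbitrary
non-negative integer alphabets (used by the ground-truth construction below)
and costs $O(M \log M)$ per site, i.e. near-linear $O(NM\log M)$ per panel,
in compiled code.

A *block* is a pair of a site span $[s, e)$ and the maximal set $S$ of
sequences identical over it with $|S| \ge W$ and $e - s \ge L$.  Because a
block is two-dimensional, maximality can favour either dimension, and the
package implements both objectives:

* **width-maximal** (`objective = "width"`, the default): at every end
  position $e$, sorted entries are partitioned into runs separated by
  divergences exceeding $e - L$; a run of at least $W$ entries is a
  candidate whose start is the largest divergence inside the run, and it is
  reported as soon as a member leaves the run (or the panel ends).  This
  includes every individual that shares the window, which is what
  association work needs.
* **length-maximal** (`objective = "length"`): every triple $(s, e, S)$ such
  that no subset of at least $W$ members survives extending the span one
  site left or right.  These are found by decomposing each divergence array
  into its nested maximal intervals (the interval tree induced by internal
  maxima).

The semantics of both objectives is *defined* by the quadratic brute-force
reference `oracle_blocks()` (enumerate spans, group identical rows, apply
the definitions literally), and the compiled scans are required by the test
suite to reproduce it exactly on hundreds of randomized panels.  This
removes any ambiguity about trigger conditions in the scan.  `quickselect()`
(random-pivot selection, $O(n)$ expected) is provided as the rank-selection
primitive associated with the length-maximal formulation.

Conventions: sites are 0-based with half-open spans internally; bp
coordinates in files are 1-based inclusive (VCF convention); ties in the
reverse-prefix order are broken by original row index, so all outputs are
deterministic.  Reporting a block at the end of the panel counts as "cannot
be extended"; boundary blocks are genuine maximal matches.

## The caller and its post-processing

`call_roh_clusters()` chains compression, per-chromosome block enumeration,
and three post-processing steps:

1. every member whose heterozygous fraction inside the block span exceeds
   `max_member_het` (default 1%) is removed;
2. clusters whose width falls below $W$ after the filter are dropped — the
   output contract "shared by at least W individuals" is kept true;
3. clusters with identical span and consensus are merged by uniting their
   member sets (idempotent).  Clusters with the same span but different
   consensus remain distinct.

Genetic lengths are linearly interpolated from a user-supplied genetic map;
without a map they are `NA` rather than approximated from bp, because any
bp-to-cM shorthand is population specific.  The biobank-scale operating
point $L = 100$ sites, $W = 100$ individuals — large enough that shared
ancestry rather than noise drives the clusters, and wide enough to power
downstream association — is the default of the command-line `find`
subcommand.

## Synthetic data

Two generators are provided.

**Planted clusters** (`plant_clusters()`): background genotypes are drawn
independently per site in Hardy-Weinberg proportions with allele frequency
0.1, giving $2p(1-p) = 18\%$ heterozygous cells — the rate typical of
SNP-array panels; planted members are overwritten with a shared homozygous
diplotype and optionally re-heterozygosed at a per-cell noise rate.  The
truth is exact by construction, which makes this the fixture for unit tests,
false-positive suites (at allele frequency 0.5) and the null calibration of
the association tests.

**Coalescent panels** (`simulate_coalescent_panel()`): diploid samples from
the CEU deme of the Gutenkunst et al. (2009) three-population out-of-Africa
model (mutation rate $2.36\times10^{-8}$, recombination rate $10^{-8}$ per
bp per generation, generation time 25 y), simulated with msprime through the
system python; sites with minor allele frequency below 1% are removed;
genotyping errors re-draw a cell uniformly among the other two states.  The
model choice is recorded in the result's metadata because headline
accuracy/power numbers are sensitive to it.

**Ground truth.**  Within-individual IBD segments — spans where an
individual's two genomes descend from one ancestral node — are extracted
from the simulated genealogies.  For cluster-level truth, segments must be
grouped so that individuals inheriting a region along the same genealogical
path share alleles.  We group segments by their ancestral node and
additionally merge two overlapping segments when one segment's node is an
ancestor of the other's in the local tree (nearest-active-ancestor links,
applied with a union-find over a sweep of the tree sequence): descent
through a nested ancestor is the same genealogical path.  Without this
merge, truth clusters fragment arbitrarily at node changes.  The interim
panel is then built by painting each (group, site) with one random
homozygous allele, all remaining cells heterozygous, and the block finder
runs with heterozygous cells given per-row sentinel symbols so they can
never participate in a match; the resulting blocks are the ground-truth
clusters for the same $(L, W)$.

Two discretionary parameters are fixed once: segments shorter than 5 kb are
dropped (`min_ibd_bp`; at the simulated marker density of roughly 2.8
retained sites per kb, any cluster of at least 50 sites spans well over
15 kb, so shorter segments carry no cluster-level signal), and no ceiling is
placed on segment age by default (`max_tmrca = Inf`; the genealogy, not a
time threshold, defines descent — a finite ceiling is available to restrict
truth to recent descent).

What this generator does *not* emulate: genotyping platforms' site
ascertainment, LD-based array design, population structure beyond the
published demographic model, and mutation/gene-conversion processes beyond
msprime's defaults.  Because the genealogy-only truth ignores mutations
below a segment's ancestor, individuals whose descent is old enough to have
accumulated visible mutations are counted as truth members that no
genotype-based caller can recover; detection power under this truth is
accordingly conservative, and passing planted-cluster tests says nothing
about these model-level discrepancies on real data.

## Evaluation metrics

Overlap between a reported and a truth cluster is measured in
member-by-site *cell* space: $\mathrm{cells}(C)$ is the set of (individual,
site) pairs covered by $C$, and the overlap ratio of reported $R$ against
truth $T$ is $|\mathrm{cells}(R) \cap \mathrm{cells}(T)| /
|\mathrm{cells}(R)|$.  Cell space penalises wrong members and wrong spans
simultaneously and makes the following well defined (`space = "site"` is
available for sensitivity analysis):

* **accuracy** — mean over reported clusters of the best overlap ratio
  against any truth cluster;
* **power** — mean over truth clusters of the cumulative overlap from all
  reported clusters, capped at 1, so a large truth cluster recovered
  piecewise by several calls receives full credit.

Both are undefined (an error, not a silent 0) when the corresponding side
is empty.

## Association and linkage statistics

Cluster-phenotype association uses the Pearson chi-squared test on the 2x2
table $(D_1, N_1, D_2, N_2)$ of diseased/healthy carriers/non-carriers,
without continuity correction (a flag restores Yates' correction), with
$N_2 = M - D_1 - N_1 - D_2$ so the table sums to the cohort.  Degenerate
tables (a zero expected cell) are flagged rather than tested.

Linkage between a cluster and a SNP adapts two-locus LD: with $p_R$ the
membership frequency, $p_S$ the alternative-allele frequency and $p_{RS}$
their joint frequency, $D = p_{RS} - p_R p_S$ and $D'$ normalises by the
admissible extreme.  We count the joint frequency at the *allele* level
(each member contributes its dosage out of $2M$ alleles): mixing an
individual-level joint count with an allele-level margin can push $|D'|$
beyond 1 (consider heterozygous carriers), whereas the allele-level table
is internally consistent and keeps $|D'| \le 1$.  The default normalisation
is the textbook min-form; the printed max-form expression is available as
`mode = "max-form"` for comparability, without any claim about which
produced published tables.

The hotspot/coldspot scan scores each site with the member count of the
largest covering cluster and calls sites strictly above the 99.5th (below
the 0.5th) percentile of the score distribution, using the default
empirical quantile.

`power_comparison()` implements the phenotype simulation $Y = X\beta +
N(0, \sigma^2)$ with $\sigma^2 = 0.1$ and effect sizes 0 to 0.3 (step
0.05 by default): per replicate a causal cluster is drawn uniformly, the
cluster test is the equal-variance two-group $t$ on membership (identical
to the regression slope test), and the single-SNP baselines regress $Y$ on
additive (0/1/2), dominant ($\ge 1$) and recessive ($= 2$) codings at every
site, all under plain Bonferroni correction.  Success for the cluster
method requires the *causal* cluster to pass $\alpha/\#\text{clusters}$;
success for a GWAS baseline requires any site inside the causal span to
pass $\alpha/\#\text{sites}$.  The uniform causal draw makes the absolute
power level depend strongly on the cluster-size distribution: with 200
individuals, $\sigma^2 = 0.1$ and Bonferroni thresholds around $10^{-5}$,
a causal cluster needs roughly 25 or more carriers before any method can
reach significance, so panels dominated by minimum-width clusters yield low
absolute power for every method while preserving the ordering between the
cluster test and the single-SNP models.  A `compute_fwe` switch evaluates
every test genome-wide to verify family-wise error control at $\beta = 0$.

## Numerical and degenerate-input choices

* `W > M` or `L > N` yield empty results, not errors; invalid thresholds
  (`L < 1`, `W < 2`) are errors.
* Constant predictors (monomorphic codings) are skipped per site; a test on
  them is never silently significant.
* Divergence-array invariants (`d[1] = k`, agreement on `[d[i], k)`,
  disagreement at `d[i] - 1`) are asserted property-style in the suite.
* The random-heterozygote compression is the only stochastic step of the
  caller; one global seed governs it.
* IBD segments reaching outside the simulated site grid are clipped with a
  warning.

## Problem sizes

The shipped tests and the acceptance script run, by design, at desk scale:
oracle-equivalence suites on panels up to 16x32; planted fixtures of 200
individuals by 1200 sites; coalescent studies of 200 diploids (about 28,000
retained sites over 10 Mbp) and 1000 diploids for the widest operating
point; 100-200 phenotype replicates per effect size.  These sizes keep every
study reproducible in minutes on one core while leaving all algorithmic
paths identical to large-panel use; the scan itself is linear in panel size
and handles biobank-scale widths only insofar as memory allows, which is
outside this package's scope.

## Known limitations

* The coalescent truth is genealogical, not sequence-level: its exact
  fragmentation scale depends on the demographic model and on the IBD
  extraction parameters, and published headline numbers from other models
  are only approximately comparable.
* Phasing, imputation, covariate-adjusted or mixed-model association, and
  streaming storage for biobank-scale panels are out of scope.
* The VCF writer emits placeholder REF/ALT alleles; the panel container
  tracks dosages, not nucleotides.
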