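---
title: "Models and methods behind mitodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodrift)
```

# The problem

Somatic mitochondrial DNA (mtDNA) variants are attractive endogenous lineage
markers: the genome is short (16,569 bp), present in hundreds of copies per
cell, and mutates one to two orders of magnitude faster than the nuclear
genome, so variants arise and accumulate over ordinary cell divisions without
any genetic engineering.  But mtDNA heteroplasmy — the fraction of a cell's
mtDNA copies carrying a variant — is itself a drifting quantity.  Random
allocation of molecules at cell division (vegetative segregation), relaxed
replication, copy-number bottlenecks, and horizontal transfer of mitochondria
between cells all reshape per-cell variant allele frequencies (VAFs)
independently of the cell genealogy, and sequencing adds depth-limited noise
on top.  `mitodrift` is a forward-time simulator plus benchmark toolkit for
asking, quantitatively: *how well can a single-cell phylogeny be
reconstructed from mtDNA VAF profiles, and how much accuracy do VAF filters
and realistic sequencing depth cost?*

# The intracellular model

A cell carries a multiset of mtDNA haplotypes (variant sets with copy
counts); the founder starts with `N` molecules (default 500), optionally
seeded with pre-existing heteroplasmies.  One division is:

1. **Replication to `2n`.**  Under `strict_doubling` every molecule is
   copied once.  Under the default `relaxed` mode there are `n` replication
   events, each choosing its template uniformly *with replacement from the
   current, growing pool* — the simplest process with the defining property
   of relaxed replication, namely that some molecules replicate several
   times per cell cycle and others not at all, which adds replication drift
   on top of segregation drift.
2. **Mutation.**  Every replication event adds `K ~ Poisson(mu * L)` de novo
   variants to the new copy (`mu` per site per replication, default `1e-7`;
   `L = 16569`).  Sites are finite: positions are uniform, a position
   already mutated on the molecule is redrawn, and recurrent mutation at the
   same site in independent lineages is deliberately possible (homoplasy).
   Variant identity includes the alternate allele (3 per site, uniformly
   chosen), so recurrent hits at one site are usually distinguishable.
   Because no explicit reference sequence exists, alleles are labelled C/G/T
   under an A-reference convention.
3. **Segregation.**  The `2n` molecules are partitioned uniformly at random
   into two daughters of exactly `n` — multivariate hypergeometric per
   haplotype class.  With strict doubling and `mu = 0` the daughter VAF
   variance has the closed form `p(1-p)/(2N-1)`, which the test suite
   verifies by simulation; a neutral variant's fixation probability equals
   its frequency (verified against an exact absorbing-Markov-chain solve).
4. **Optional bottleneck.**  Each daughter is reduced to `b` molecules
   (without replacement) and re-expanded to `N` by relaxed replication,
   applied immediately after segregation since the reduction happens during
   division.  With `b = 1` the daughter becomes homoplasmic for one input
   haplotype, chosen proportionally to its copy count.

Horizontal **transfer** moves `k` molecules from donor to recipient without
replacement, with move semantics — both cells' frequencies change, which is
exactly why transfer confounds lineage inference.  Because transfer displaces
copy numbers from `N`, replication doubles *the current pool* rather than
insisting on `N`; bottlenecks restore `N` when enabled.

## A note on the relaxed-replication implementation

The sequential urn (each event duplicating a uniform draw from the growing
pool) is exchangeable, so by de Finetti the class-count increments after any
stretch of `t` mutation-free events are exactly Dirichlet-multinomial
`DM(t, counts)`.  The implementation samples those blocks in one step and
interleaves the (rare) mutation events at their sequential positions,
choosing each template in proportion to the current counts.  This is
*distributionally identical* to the molecule-by-molecule loop — a unit test
compares both against each other — and orders of magnitude faster in R.

# The tissue model

Tissue dynamics are two-phased, mirroring development followed by
homeostasis: `g` rounds of synchronous expansion from one founder (`2^g`
cells, every cell at exactly `g` divisions — the "neonatal" state), then `r`
Moran renewal steps: one uniformly chosen cell divides, and one cell chosen
uniformly among the *other* alive cells (same-step daughters exempt) dies.
Population size is constant through renewal while the number of surviving
founder lineages decays.  The full genealogy is recorded; the ground-truth
tree of a sample is the genealogy restricted to the sampled tips, with
unifurcations collapsed (branch lengths summed) and the root at the sample
MRCA.  Branch lengths count divisions, not wall-clock time, because
mutations accrue per replication.  Renewal trees are therefore *not*
ultrametric: lineages that happened to divide more often sit deeper.

A single global RNG stream seeded once drives everything; since the
simulator's own event order is deterministic, an identical configuration and
seed reproduce every output bit-exactly (tested).  Benchmark replicates use
`seed + replicate - 1` and are logged, so any replicate can be re-run alone.

# The sequencing model

For each cell-variant entry with true heteroplasmy `p`, coverage is
`Poisson(depth)` (default 50x; a `fixed` mode exists for closed-form tests)
and the alternate read count is `Binomial(cov, q)` with
`q = p(1-e) + (1-p)e/3` for per-read error rate `e` (default 0; the
benchmark conditions specify only depth and read support).  The observed VAF
is `alt/cov` if `alt` reaches the support threshold (default 2 reads) and 0
otherwise.  At `p = 0.01` and fixed 50x, the per-cell detection probability
is the binomial tail `1 - 0.99^50 - 50(0.01)0.99^49 ≈ 0.089` — low-frequency
heteroplasmies are essentially invisible at standard depth, which is the
crux of the benchmark.  The `VAF > 0.01` filter is applied per matrix entry
(strictly-greater survives), matching a per-cell reading of the condition;
a per-variant-maximum mode is exposed as an option.  The classic empirical
variant selector (heteroplasmy ≥ 5% in ≥ 80% of some predefined clone) is
provided as `empirical_clone_filter()`.

Coverage planning arithmetic: a 1x-nuclear WGS run of 1e7 PE150 read pairs
with ~0.5% mtDNA-derived reads implies `1e7 × 0.005 = 50,000` mtDNA read
pairs and `50,000 × 300 / 16569 ≈ 905x` mitochondrial coverage —
`expected_mt_coverage()` reproduces this worked example.

# Reconstruction and metrics

**Distances.**  `vaf_dist()` offers euclidean (its default), manhattan, and
binarized-Jaccard metrics on VAF row vectors.  **The benchmark defaults to
Jaccard.**  This was a genuinely open design choice, and the decisive
argument is structural: a frequency-quadratic metric weights a variant's
contribution by `p²`, so zeroing entries below 0.01 changes squared
distances by at most `1e-4` per entry — the VAF-cutoff condition would be a
near-no-op by construction, erasing precisely the fine-scale signal whose
loss the benchmark is designed to measure.  Shared *presence* of recent,
low-frequency variants is what marks close relatives; the binarized Jaccard
metric keeps that signal first-class.  The metric remains a flag everywhere
and is echoed in every run manifest.

**Neighbor joining** is implemented in the package (classical `Q`-criterion,
standard branch-length and distance-update formulas, per-join clamping of
negative branch lengths to zero, deterministic tie-breaking by smallest
label pair; dense `O(n³)`, ample at `n = 200`).  NJ is consistent on
additive matrices; the suite checks exact recovery (topology and branch
lengths) of random integer-branch trees, cross-checked against an
independent implementation.

**Clone assignment.**  Sampled cells are partitioned into `k = 20` clones of
similar size by greedy clade splitting of the truth tree: start from the
root's children, repeatedly split the largest group at its root bifurcation.
Every clone is a clade and the procedure is deterministic.

**Clone aggregation score (CAS).**  No public formula exists for this score,
so the package adopts and documents a nearest-neighbour purity
operationalisation, isolated in one function so an alternative can be
swapped in: for clone `c` with `n_c ≥ 2` tips, each tip's `n_c - 1` nearest
other tips (reconstructed path distance, ties by label) are inspected and
the in-clone fraction averaged over the clone; singletons score 1 by
convention.  Two provable properties anchor it: perfect, compact
reconstruction gives `CAS = 1`, and under random labels
`E[CAS(c)] = (n_c - 1)/(n - 1)`.  One caveat is worth stating plainly: on a
*non-ultrametric* truth tree a clone whose internal diameter exceeds its
distance to neighbouring clades can score below 1 even when the
reconstruction *is* the truth tree.  Sanity checks of the `CAS = 1` property
therefore use expansion-phase (exactly ultrametric) truth trees, where it is
a theorem; renewal-phase trees are used everywhere the metric compares
*conditions against each other*.

**Closest-pair ground-truth distance.**  For each tip, its nearest tip in
the reconstruction is found and the pair's path distance is measured in the
truth tree (in divisions).  Perfect reconstruction attains each tip's true
nearest-relative distance; misassignment inflates the value up to the
truth-tree diameter.  The phrase "terminal branch length" admits a second
reading — the sum of the pair's two terminal edges only — available via
`terminal_edges_only = TRUE`.  Both metrics depend only on distance *ranks*
in the reconstruction plus truth distances, hence are invariant to
rerooting and uniform rescaling of the reconstructed tree (tested).

# The benchmark and its study conditions

Each replicate simulates a tissue, samples `n` cells, and scores three
matrices: `all_vaf` (true heteroplasmies), `vaf_gt_cutoff` (entries ≤ 0.01
zeroed), and `sequenced` (50x Poisson coverage, 2-read support).  Replicate
means are paired across conditions in one-sided sign tests.

Problem sizes are the package's own choices, made once and documented here:

* `scaled` (the preset this package's analyses and tests use):
  `g = 8` (256 cells), `r = 500` Moran steps (preserving the `r/M ≈ 2`
  turnover of the full-size preset), `n = 100` sampled cells, `N = 500`
  copies, `mu = 1e-7`, depth 50, support 2, cutoff 0.01, `k = 20` clones,
  20 replicates.  One full run takes well under a minute on one core.
* `paper-like`: `g = 10` (1024 cells), `r = 2000`, `n = 200`, otherwise
  identical.
* The founder carries five pre-existing heteroplasmies (frequencies
  0.02–0.4, at familiar human mtDNA positions), reflecting the mutation
  load real founder cells start with; they supply clone-scale signal while
  de novo variants supply the fine-scale signal.

```{r benchmark, eval = FALSE}
preset <- benchmark_preset("scaled")
bench <- run_benchmark(preset$sim_config, preset$tissue_config,
                       preset$seq_config, replicates = 20, k = 20, seed = 1)
print(bench)
```

Across seeds the two directional effects are decisive (all 20 replicates
agreeing, sign-test `p ≈ 1e-6`): simulated sequencing sharply lowers CAS and
inflates the closest-pair distance, and excluding VAF ≤ 0.01 prominently
inflates the closest-pair distance while costing much less at clone scale —
low-VAF variants carry disproportionately *fine-scale* lineage information.
`scripts/acceptance.R` recomputes all of these numbers from scratch.

# What the generator does and does not emulate

The simulator captures neutral heteroplasmy drift, relaxed replication,
bottlenecks, transfer, finite-site homoplasy, Moran-type tissue turnover,
and depth-limited detection.  It deliberately omits: selection on variants
or cells, mtDNA copy-number phenotypes, strand asymmetry and mutational
signatures, modality-specific coverage profiles (cDNA restriction, ATAC
insertion bias), UMI consensus calling, and RNA-editing artifacts.  Passing
benchmarks therefore speak to the *population-genetic* limits of mtDNA
lineage tracing, not to platform-specific artifacts of any particular assay.

# Numerical and degenerate-input choices

* Distance matrices must be symmetric to `1e-12`, non-negative, zero
  diagonal; NJ ties break on the smallest label pair, and label order never
  affects the result beyond labelling (tested by permutation).
* An all-zero VAF matrix (e.g. nothing survives sequencing) yields a
  flagged all-zero distance matrix with a warning; NJ then resolves ties
  deterministically rather than failing, so pipelines keep running.
* `round(frequency × N)` fixes founder copy counts; variants landing on
  zero copies are simply absent.
* Newick output is canonical (children ordered by smallest descendant tip
  label, `%.12g` branch lengths), so equal trees serialise identically and
  byte-level reproducibility is testable.
* One-tip trees are supported throughout the truth-tree path (degenerate
  sampling), though NJ itself requires two taxa.
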