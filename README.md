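# mitodrift

Forward-time simulation of mitochondrial DNA heteroplasmy dynamics in
dividing cell populations, and a benchmark of how well single-cell lineages
can be reconstructed from mtDNA variant allele frequency (VAF) profiles.

Somatic mtDNA variants are natural lineage barcodes — the genome is short
(16,569 bp), highly multicopy, and fast-mutating — but heteroplasmy drifts:
molecules are allocated randomly at cell division (vegetative segregation),
replication is relaxed (molecules may copy zero or several times per cycle),
bottlenecks and horizontal mitochondrial transfer reshuffle frequencies, and
sequencing only detects variants its depth can support.  `mitodrift` is for
researchers in single-cell lineage tracing who want to quantify what those
processes cost: it simulates cells whose mtDNA pools evolve by replication
with de novo mutation (`K ~ Poisson(mu L)` per replication event),
hypergeometric segregation (daughter-VAF variance `p(1-p)/(2N-1)`), optional
bottlenecks and transfer; grows tissues by synchronous expansion followed by
constant-size Moran renewal with the full genealogy recorded; converts true
heteroplasmies into observed VAF matrices under Poisson coverage, binomial
read sampling (`q = p(1-e) + (1-p)e/3`) and a read-support threshold;
reconstructs lineages by neighbor joining (classical `Q`-criterion, written
in-package, consistent on additive matrices); and scores reconstructions
against the recorded truth with a clone aggregation score (CAS,
nearest-neighbour purity over `k = 20` truth-tree clades) and the
closest-pair ground-truth distance (divisions separating each tip from its
reconstructed nearest neighbour, measured in the truth tree).

## Worked example

```r
library(mitodrift)

# one tissue: 256 cells grown in 8 synchronous divisions, 500 Moran renewal
# steps, 100 cells sampled; 500 mtDNA copies/cell, mu = 1e-7 /site/replication
sim <- simulate_tissue(sim_config(), tissue_config(8, 500, 100),
                       default_founder_variants(), seed = 1)
sim
#> lineage_sim: 100 sampled cells, 169 variants in the true VAF matrix

# the three benchmark conditions, reconstructed and scored
mats <- condition_matrices(sim, seq_config(depth = 50, support_threshold = 2))
reports <- compare_conditions(sim$truth, mats, k = 20, metric = "jaccard")
reports$all_vaf
#> metrics_report [all_vaf]: 20 clones, 100 cells
#>   CAS          mean 0.265  median 0.200
#>   closest-pair mean 13.35  median 16.00 divisions
reports$sequenced
#> metrics_report [sequenced]: 20 clones, 100 cells
#>   CAS          mean 0.107  median 0.000
#>   closest-pair mean 19.53  median 19.00 divisions
```

Reading the numbers: with every true heteroplasmy available (`all_vaf`), a
sampled cell's reconstructed nearest neighbours are relatives ~13
divisions away and clones cohere far above the ~0.05 random-label baseline;
after simulated 50x sequencing with 2-read support (`sequenced`), most
low-frequency variants fall below the detection limit (a 1% heteroplasmy is
detected in only ~9% of cells at 50x), CAS drops toward baseline and the
closest-pair distance inflates by ~6 divisions.  The full replicated
benchmark with paired sign tests:

```r
p <- benchmark_preset("scaled")
bench <- run_benchmark(p$sim_config, p$tissue_config, p$seq_config,
                       replicates = 20, k = 20, seed = 1)
print(bench)
#> mito_benchmark: 20 replicates, 20 clones, metric 'jaccard'
#>      condition  cas_mean closest_pair_mean n_variants_mean
#>        all_vaf 0.2705456           13.4460          157.25
#>      sequenced 0.1239643           20.2535           13.30
#>  vaf_gt_cutoff 0.1764653           17.9900           22.05
#>   sign test: sequencing lowers CAS          p = 9.54e-07 (20/20)
#>   sign test: VAF cutoff raises closest-pair p = 9.54e-07 (20/20)
```

Filtering out VAF ≤ 0.01 costs little at clone scale but prominently
inflates the closest-pair distance: low-frequency variants carry the
fine-scale lineage signal.

A thin command-line front end is installed with the package
(`exec/mitosim`): `mitosim simulate|sequence|reconstruct|evaluate|benchmark`
with flat `key = value` config files; every run writes a JSON manifest (full
config echo + seed) from which it can be reproduced bit-exactly.

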