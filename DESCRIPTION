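Package: mitodrift
Title: Forward Simulation of Mitochondrial Heteroplasmy Dynamics and
    Lineage-Tracing Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Forward-time simulation of mitochondrial DNA heteroplasmy in
    dividing cell populations: relaxed or strict mtDNA replication with de
    novo mutation, random vegetative segregation at cell division,
    germline-style copy-number bottlenecks, and horizontal mitochondrial
    transfer.  Tissue-level dynamics combine exponential expansion with
    constant-size Moran renewal under full genealogy recording.  A
    sequencing-noise model converts true per-cell heteroplasmies into
    observed single-cell variant allele frequency (VAF) matrices at a given
    depth and read-support threshold.  Lineages are reconstructed by
    neighbor joining and scored against the recorded ground truth with a
    clone aggregation score and a closest-pair ground-truth distance,
    quantifying how VAF filtering and sequencing depth degrade single-cell
    mitochondrial lineage tracing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
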