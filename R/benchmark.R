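## End-to-end simulation and the three-condition benchmark: expansion +
## renewal -> sample -> truth tree + true VAF matrix -> (all VAF | VAF-cutoff
## filtered | simulated sequencing) -> NJ reconstruction -> CAS and
## closest-pair metrics, paired across replicates.

#' Default pre-existing founder heteroplasmies
#'
#' Five heteroplasmic variants spanning rare to mid-frequency (0.02-0.4), at
#' well-known human mtDNA positions, standing in for the mutation load a
#' real founder cell carries before any simulated division.
#'
#' @return A data frame accepted by [make_founder()].
#' @export
default_founder_variants <- function() {
  founder_variants(position = c(1555, 3243, 7028, 8344, 11778),
                   frequency = c(0.10, 0.02, 0.20, 0.05, 0.40),
                   allele = c("G", "G", "T", "G", "G"))
}

#' Simulate a tissue and extract the sampled ground truth
#'
#' One full forward simulation: synchronous expansion, Moran renewal, uniform
#' cell sampling, ground-truth tree extraction and the true VAF matrix of the
#' sample.
#'
#' @param sim_config A [sim_config()].
#' @param tissue_config A [tissue_config()].
#' @param founder_variants Optional pre-existing heteroplasmies (see
#'   [make_founder()]).
#' @param seed Optional integer seed (`set.seed`) for bit-identical runs.
#' @return An object of class `"lineage_sim"`: list with the `tissue`, the
#'   `sampled` cells, the `truth` tree, and the true `vaf` matrix.
#' @export
#' @examples
#' sim <- simulate_tissue(sim_config(N = 50, mu = 1e-6),
#'                        tissue_config(4, 20, 8), seed = 1)
#' dim(sim$vaf)
simulate_tissue <- function(sim_config = sim_config(),
                            tissue_config = tissue_config(),
                            founder_variants = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ts <- grow(sim_config, tissue_config, founder_variants)
  if (tissue_config$renewal_steps > 0L) ts <- renew(ts)
  sampled <- sample_cells(ts)
  structure(list(tissue = ts,
                 sampled = sampled,
                 truth = ground_truth_tree(ts, sampled),
                 vaf = build_true_vaf_matrix(sampled),
                 seed = seed),
            class = "lineage_sim")
}

#' @export
print.lineage_sim <- function(x, ...) {
  cat(sprintf("lineage_sim: %d sampled cells, %d variants in the true VAF matrix\n",
              nrow(x$vaf), ncol(x$vaf)))
  invisible(x)
}

#' Build the three benchmark condition matrices from one simulation
#'
#' `all_vaf`: the true VAF matrix unchanged; `vaf_gt_cutoff`: entries at or
#' below `cutoff` zeroed ([filter_low_vaf()]); `sequenced`: the observed
#' matrix after [simulate_sequencing()].
#'
#' @param sim A `"lineage_sim"`.
#' @param seq_config A [seq_config()].
#' @param cutoff VAF cutoff for the filtered condition (default 0.01).
#' @return Named list of three VAF matrices.
#' @export
condition_matrices <- function(sim, seq_config = seq_config(), cutoff = 0.01) {
  list(all_vaf = sim$vaf,
       vaf_gt_cutoff = filter_low_vaf(sim$vaf, cutoff),
       sequenced = simulate_sequencing(sim$vaf, seq_config)$vaf)
}

## one-sided sign test on paired differences (ties dropped)
sign_test <- function(x, y, alternative = "greater") {
  d <- x - y
  nz <- d != 0
  if (!any(nz)) return(list(wins = 0L, n = 0L, p = 1))
  ht <- stats::binom.test(sum(d[nz] > 0), sum(nz), p = 0.5,
                          alternative = alternative)
  list(wins = sum(d[nz] > 0), n = sum(nz), p = ht$p.value)
}

#' Replicate benchmark of lineage-tracing accuracy across data conditions
#'
#' Repeats the full pipeline `replicates` times with per-replicate seeds
#' derived from `seed`, scoring each condition with the clone aggregation
#' score (CAS) and the closest-pair ground-truth distance, and pairing the
#' replicate means in one-sided sign tests for the two directional effects
#' of interest: sequencing noise lowering CAS relative to the noise-free
#' matrix, and the VAF cutoff inflating the closest-pair distance.
#'
#' @param sim_config,tissue_config,seq_config Configurations.
#' @param founder_variants Pre-existing founder heteroplasmies (default
#'   [default_founder_variants()]).
#' @param replicates Number of independent replicates (default 20).
#' @param k Number of ground-truth clones (default 20).
#' @param metric Distance metric for [vaf_dist()].  The benchmark defaults to
#'   `"jaccard"` (variant presence/absence): a frequency-quadratic metric such
#'   as euclidean down-weights low-VAF variants by `p^2` and thereby erases
#'   the very signal whose loss the VAF-cutoff condition is meant to measure
#'   (see the methods vignette).
#' @param cutoff VAF cutoff of the filtered condition (default 0.01).
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @return An object of class `"mito_benchmark"`: per-replicate long-format
#'   results (`$results`), the per-condition summary (`$summary`), paired
#'   sign tests (`$tests`), and the configurations.
#' @export
run_benchmark <- function(sim_config = sim_config(),
                          tissue_config = tissue_config(),
                          seq_config = seq_config(),
                          founder_variants = default_founder_variants(),
                          replicates = 20, k = 20, metric = "jaccard",
                          cutoff = 0.01, seed = 1) {
  stopifnot(replicates >= 1)
  rows <- vector("list", replicates)
  for (rep in seq_len(replicates)) {
    rep_seed <- seed + rep - 1L
    sim <- simulate_tissue(sim_config, tissue_config, founder_variants,
                           seed = rep_seed)
    mats <- condition_matrices(sim, seq_config, cutoff)
    reports <- compare_conditions(sim$truth, mats, k = k, metric = metric)
    rows[[rep]] <- do.call(rbind, lapply(reports, function(r) {
      data.frame(replicate = rep, seed = rep_seed, condition = r$condition,
                 n_cells = length(r$closest_pair),
                 n_variants = ncol(mats[[r$condition]]),
                 cas_mean = r$summary$cas$mean,
                 cas_cell_mean = r$summary$cas_per_cell$mean,
                 closest_pair_mean = r$summary$closest_pair$mean,
                 closest_pair_median = r$summary$closest_pair$median,
                 stringsAsFactors = FALSE)
    }))
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  wide <- function(col) {
    s <- split(results, results$condition)
    m <- vapply(s, function(df) df[[col]][order(df$replicate)],
                numeric(replicates))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(s)))
    m
  }
  cas <- wide("cas_mean")
  cpd <- wide("closest_pair_mean")
  tests <- list(
    cas_sequencing_decreases = sign_test(cas[, "all_vaf"], cas[, "sequenced"]),
    cas_cutoff_decreases = sign_test(cas[, "all_vaf"], cas[, "vaf_gt_cutoff"]),
    cpd_cutoff_increases = sign_test(cpd[, "vaf_gt_cutoff"], cpd[, "all_vaf"]),
    cpd_sequencing_increases = sign_test(cpd[, "sequenced"], cpd[, "all_vaf"]))
  summary <- do.call(rbind, lapply(split(results, results$condition), function(df) {
    data.frame(condition = df$condition[1L],
               cas_mean = mean(df$cas_mean),
               closest_pair_mean = mean(df$closest_pair_mean),
               n_variants_mean = mean(df$n_variants),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, tests = tests,
                 sim_config = sim_config, tissue_config = tissue_config,
                 seq_config = seq_config, k = k, metric = metric,
                 cutoff = cutoff, seed = seed, replicates = replicates),
            class = "mito_benchmark")
}

#' @export
print.mito_benchmark <- function(x, ...) {
  cat(sprintf("mito_benchmark: %d replicates, %d clones, metric '%s'\n",
              x$replicates, x$k, x$metric))
  print(x$summary, row.names = FALSE)
  cat(sprintf("  sign test: sequencing lowers CAS          p = %.3g (%d/%d)\n",
              x$tests$cas_sequencing_decreases$p,
              x$tests$cas_sequencing_decreases$wins,
              x$tests$cas_sequencing_decreases$n))
  cat(sprintf("  sign test: VAF cutoff raises closest-pair p = %.3g (%d/%d)\n",
              x$tests$cpd_cutoff_increases$p,
              x$tests$cpd_cutoff_increases$wins,
              x$tests$cpd_cutoff_increases$n))
  invisible(x)
}

#' Benchmark presets
#'
#' Bundled configurations: `"tiny"` finishes in seconds and exists for smoke
#' tests; `"scaled"` (256 cells, 500 renewal steps, 100 sampled cells, 20
#' replicates) is the desk-scale benchmark this package's own analyses use;
#' `"paper-like"` (1024 cells, 2000 renewal steps, 200 sampled cells) is the
#' full-size default.  Population sizes and rates are this package's own
#' parameter choices, documented in the methods vignette.
#'
#' @param name One of `"tiny"`, `"scaled"`, `"paper-like"`.
#' @return Named list of arguments for [run_benchmark()].
#' @export
benchmark_preset <- function(name = c("scaled", "tiny", "paper-like")) {
  name <- match.arg(name)
  switch(name,
    tiny = list(sim_config = sim_config(N = 50L, mu = 1e-6),
                tissue_config = tissue_config(4L, 20L, 10L),
                seq_config = seq_config(),
                replicates = 2, k = 3),
    scaled = list(sim_config = sim_config(),
                  tissue_config = tissue_config(8L, 500L, 100L),
                  seq_config = seq_config(),
                  replicates = 20, k = 20),
    `paper-like` = list(sim_config = sim_config(),
                        tissue_config = tissue_config(10L, 2000L, 200L),
                        seq_config = seq_config(),
                        replicates = 20, k = 20))
}
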