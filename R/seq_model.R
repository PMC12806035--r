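## Sequencing-noise model: convert true per-cell heteroplasmies into
## observed VAF matrices under Poisson/fixed coverage, binomial read
## sampling, an optional per-read error rate, and a minimum read-support
## threshold; plus the empirical VAF filters used for variant selection.

#' True VAF matrix of a cell sample
#'
#' Takes the union of variants present in any sampled cell and tabulates each
#' cell's true heteroplasmy (0 when a cell lacks the variant).  Columns are
#' ordered deterministically by position then allele; by construction no
#' column is all-zero.
#'
#' @param cells List of [cell_record()]s (e.g. from [sample_cells()]).
#' @return Numeric matrix, cells in rows (labelled `"cell<ID>"`), variant
#'   tokens `"pos:allele"` in columns.
#' @export
build_true_vaf_matrix <- function(cells) {
  if (!length(cells)) stop("'cells' is empty", call. = FALSE)
  vafs <- lapply(cells, function(cl) true_vaf_codes(cl$mito))
  allcodes <- sort(unique(unlist(lapply(vafs, `[[`, "codes"))))
  m <- matrix(0, nrow = length(cells), ncol = length(allcodes),
              dimnames = list(
                vapply(cells, function(cl) paste0("cell", cl$cell_id), ""),
                if (length(allcodes)) variant_token(allcodes) else NULL))
  for (i in seq_along(vafs)) {
    m[i, match(vafs[[i]]$codes, allcodes)] <- vafs[[i]]$freq
  }
  m
}

drop_zero_columns <- function(m) {
  if (ncol(m) == 0L) return(m)
  m[, colSums(m > 0) > 0, drop = FALSE]
}

#' Simulate sequencing of a true VAF matrix
#'
#' For each cell-variant entry with true heteroplasmy `p`, coverage is drawn
#' as `Poisson(depth)` (or fixed at `depth`), and the alternate read count as
#' `Binomial(cov, q)` with `q = p (1 - e) + (1 - p) e / 3` for per-read error
#' rate `e`.  The observed VAF is `alt / cov` when the alternate count
#' reaches the support threshold and 0 otherwise (also 0 at zero coverage).
#' Variants called in no cell are dropped from the observed matrix; the read
#' count matrices keep all columns.
#'
#' @param true_matrix Numeric matrix from [build_true_vaf_matrix()] (cells in
#'   rows, values in `[0, 1]`).
#' @param config A [seq_config()].
#' @return An object of class `"seq_result"`: list with integer matrices
#'   `alt` and `cov` (same shape as the input) and the thresholded observed
#'   VAF matrix `vaf`.
#' @export
#' @examples
#' set.seed(1)
#' truth <- matrix(c(0.3, 0), 2, 1, dimnames = list(c("cell1", "cell2"), "99:C"))
#' simulate_sequencing(truth, seq_config(depth = 100))$vaf
simulate_sequencing <- function(true_matrix, config = seq_config()) {
  stopifnot(is.matrix(true_matrix), inherits(config, "seq_config"))
  if (any(true_matrix < 0 | true_matrix > 1)) {
    stop("true VAF values must lie in [0, 1]", call. = FALSE)
  }
  nn <- length(true_matrix)
  cov <- if (config$coverage_model == "poisson") {
    stats::rpois(nn, config$depth)
  } else {
    rep.int(as.integer(round(config$depth)), nn)
  }
  e <- config$error_rate
  q <- true_matrix * (1 - e) + (1 - true_matrix) * (e / 3)
  alt <- stats::rbinom(nn, cov, as.vector(q))
  dim(cov) <- dim(alt) <- dim(true_matrix)
  dimnames(cov) <- dimnames(alt) <- dimnames(true_matrix)
  vaf <- matrix(0, nrow(true_matrix), ncol(true_matrix),
                dimnames = dimnames(true_matrix))
  called <- alt >= config$support_threshold & cov > 0L
  vaf[called] <- alt[called] / cov[called]
  structure(list(alt = alt, cov = cov, vaf = drop_zero_columns(vaf),
                 config = config),
            class = "seq_result")
}

#' @export
print.seq_result <- function(x, ...) {
  cat(sprintf("seq_result: %d cells x %d simulated variants, %d called after %d-read support\n",
              nrow(x$alt), ncol(x$alt), ncol(x$vaf), x$config$support_threshold))
  invisible(x)
}

#' Filter low-VAF entries from a VAF matrix
#'
#' Entries at or below `cutoff` are set to 0 (strictly greater values are
#' retained), and variants left with no nonzero entry are dropped.  With
#' `per_variant_max = TRUE` the filter instead drops whole variants whose
#' maximum VAF across cells does not exceed the cutoff, leaving surviving
#' columns untouched.  The entrywise filter is idempotent.
#'
#' @param matrix Numeric VAF matrix (cells in rows).
#' @param cutoff Frequency cutoff in `[0, 1)` (default 0.01).
#' @param per_variant_max Apply the cutoff to the per-variant maximum rather
#'   than per entry (default `FALSE`).
#' @return Filtered VAF matrix.
#' @export
filter_low_vaf <- function(matrix, cutoff = 0.01, per_variant_max = FALSE) {
  stopifnot(is.matrix(matrix))
  if (cutoff < 0 || cutoff >= 1) stop("'cutoff' must be in [0, 1)", call. = FALSE)
  if (per_variant_max) {
    if (ncol(matrix) == 0L) return(matrix)
    return(matrix[, apply(matrix, 2L, max) > cutoff, drop = FALSE])
  }
  matrix[matrix <= cutoff] <- 0
  drop_zero_columns(matrix)
}

#' Empirical clone-informed variant filter
#'
#' Classic empirical selection of clone-informative mtDNA variants: a variant
#' is retained when some predefined clone has at least `min_cell_frac` of its
#' cells carrying it at heteroplasmy `>= min_het` (defaults: 5% heteroplasmy
#' in at least 80% of a clone's cells).
#'
#' @param matrix Numeric VAF matrix (cells in rows).
#' @param clone_labels Vector of clone labels, one per row of `matrix`.
#' @param min_het Minimum heteroplasmy (default 0.05).
#' @param min_cell_frac Minimum fraction of a clone's cells (default 0.8).
#' @return Character vector of selected variant tokens.
#' @export
empirical_clone_filter <- function(matrix, clone_labels,
                                   min_het = 0.05, min_cell_frac = 0.80) {
  stopifnot(is.matrix(matrix))
  if (length(clone_labels) != nrow(matrix)) {
    stop("'clone_labels' must label every cell (row)", call. = FALSE)
  }
  clone_labels <- as.factor(clone_labels)
  if (any(table(clone_labels) == 0L)) stop("empty clone", call. = FALSE)
  if (ncol(matrix) == 0L) return(character(0))
  selected <- rep(FALSE, ncol(matrix))
  for (cl in levels(clone_labels)) {
    rows <- matrix[clone_labels == cl, , drop = FALSE]
    frac <- colMeans(rows >= min_het)
    selected <- selected | (frac >= min_cell_frac)
  }
  colnames(matrix)[selected]
}

#' Expected mitochondrial fold coverage of a sequencing run
#'
#' Coverage arithmetic for planning: given the total read-pair count of a
#' whole-genome run, the fraction of reads that are mtDNA-derived, and the
#' bases per read pair, returns the implied mtDNA read count and the fold
#' coverage of the mitochondrial genome.  A typical 1x nuclear-coverage WGS
#' run of 1e7 PE150 pairs with ~0.5% mtDNA content yields ~50,000 mtDNA
#' reads, i.e. ~900x mitochondrial coverage.
#'
#' @param total_read_pairs Total read pairs in the run.
#' @param mt_fraction Fraction of reads that are mtDNA-derived.
#' @param bases_per_pair Sequenced bases per read pair (default 300 = PE150).
#' @param genome_length Mitochondrial genome length (default 16569).
#' @return List with `mt_reads` and `coverage`.
#' @export
#' @examples
#' expected_mt_coverage(1e7, 0.005)
expected_mt_coverage <- function(total_read_pairs, mt_fraction,
                                 bases_per_pair = 300, genome_length = 16569) {
  vals <- c(total_read_pairs, mt_fraction, bases_per_pair, genome_length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  mt_reads <- total_read_pairs * mt_fraction
  structure(list(mt_reads = mt_reads,
                 coverage = mt_reads * bases_per_pair / genome_length),
            class = "mt_coverage")
}

#' @export
print.mt_coverage <- function(x, ...) {
  cat(sprintf("%.4g mtDNA read pairs -> %.1fx mitochondrial coverage\n",
              x$mt_reads, x$coverage))
  invisible(x)
}
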