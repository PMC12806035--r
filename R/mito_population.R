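## A cell's mitochondrial genome pool is a multiset of haplotypes: distinct
## variant sets with positive copy counts.  Haplotypes are sorted integer
## vectors of variant codes; the reference molecule is integer(0).

#' Construct a mitochondrial genome pool
#'
#' A `mito_population` is the heteroplasmy state of one cell: a map from
#' haplotypes (sets of variants carried by one mtDNA molecule) to positive
#' copy counts.  Duplicated haplotypes are merged and zero counts dropped.
#'
#' @param haplotypes List of integer vectors of variant codes (see
#'   [variant_code()]); `integer(0)` is the reference molecule.
#' @param counts Integer copy counts, one per haplotype.
#' @return An object of class `"mito_population"`.
#' @export
#' @examples
#' m <- mito_population(list(integer(0), variant_code(100, "G")), c(7, 3))
#' copy_number(m)
#' true_vaf(m)
mito_population <- function(haplotypes = list(integer(0)), counts = 1L) {
  if (!is.list(haplotypes)) haplotypes <- list(haplotypes)
  if (length(counts) != length(haplotypes)) {
    stop("'counts' must match 'haplotypes' in length", call. = FALSE)
  }
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0L)) {
    stop("copy counts must be non-negative integers", call. = FALSE)
  }
  haplotypes <- lapply(haplotypes, function(v) sort(unique(as.integer(v))))
  for (v in haplotypes) {
    if (anyDuplicated(v %/% 3L)) {
      stop("a haplotype may carry at most one variant per position", call. = FALSE)
    }
  }
  out <- new_mito(haplotypes, counts)
  if (copy_number(out) < 1L) stop("population must hold at least one molecule",
                                  call. = FALSE)
  out
}

## Fast internal constructor: merges duplicate haplotype classes, drops empty
## ones, no per-variant validation.
new_mito <- function(haplotypes, counts) {
  keep <- counts > 0L
  if (!all(keep)) {
    haplotypes <- haplotypes[keep]
    counts <- counts[keep]
  }
  key <- vapply(haplotypes, paste, "", collapse = ",")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    counts <- as.integer(rowsum(counts, key, reorder = FALSE)[, 1L])
    haplotypes <- haplotypes[first]
  }
  structure(list(haplotypes = haplotypes, counts = as.integer(counts)),
            class = "mito_population")
}

#' @rdname mito_population
#' @param mito A `mito_population`.
#' @export
copy_number <- function(mito) sum(mito$counts)

#' @export
print.mito_population <- function(x, ...) {
  cat(sprintf("mito_population: %d molecules, %d haplotype class(es)\n",
              copy_number(x), length(x$counts)))
  vaf <- true_vaf(x)
  if (length(vaf)) {
    cat("  heteroplasmies:\n")
    for (i in seq_along(vaf)) {
      cat(sprintf("    %-12s %.4f\n", names(vaf)[i], vaf[i]))
    }
  } else {
    cat("  all molecules are reference\n")
  }
  invisible(x)
}

#' True heteroplasmy of every variant in a cell
#'
#' The true variant allele frequency (VAF) of a variant is the fraction of
#' mtDNA molecules carrying it.  Variants carried by no molecule are absent
#' from the result, so all returned frequencies are in (0, 1].
#'
#' @param mito A [mito_population()].
#' @return Named numeric vector of frequencies; names are `"pos:allele"`
#'   tokens ordered by position then allele.
#' @export
true_vaf <- function(mito) {
  v <- true_vaf_codes(mito)
  stats::setNames(v$freq, variant_token(v$codes))
}

## Internal variant-code version (cheaper to merge across cells).
true_vaf_codes <- function(mito) {
  n <- copy_number(mito)
  if (n < 1L) stop("empty mitochondrial population", call. = FALSE)
  codes <- unlist(mito$haplotypes, use.names = FALSE)
  if (!length(codes)) return(list(codes = integer(0), freq = numeric(0)))
  w <- rep.int(mito$counts, lengths(mito$haplotypes))
  uc <- sort(unique(codes))
  tot <- rowsum(w, factor(codes, levels = uc))[, 1L]
  list(codes = uc, freq = unname(tot) / n)
}

#' Write a mitochondrial population as tab-separated text
#'
#' Debug serialization: one row per haplotype class with columns
#' `haplotype_id`, `copy_count`, and the comma-joined `"pos:allele"` tokens
#' (0-based positions; empty string for the reference molecule).
#'
#' @param mito A [mito_population()].
#' @param file Path or connection; `""` prints to stdout.
#' @export
write_mito_population <- function(mito, file = "") {
  tokens <- vapply(mito$haplotypes,
                   function(v) paste(variant_token(v), collapse = ","), "")
  df <- data.frame(haplotype_id = seq_along(tokens),
                   copy_count = mito$counts,
                   variants = tokens,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
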