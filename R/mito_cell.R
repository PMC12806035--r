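## Intracellular mtDNA dynamics: replication with de novo mutation, random
## vegetative segregation at division, copy-number bottlenecks, and
## horizontal transfer.  All randomness comes from R's global RNG; seed runs
## with set.seed() for bit-identical reproduction.

#' Cell records
#'
#' A `cell_record` ties a mitochondrial genome pool to its place in the
#' recorded genealogy: a unique integer id, the parent id (`NA` for the
#' founder), and the number of cell divisions since the founder, which is the
#' ground-truth branch-length unit.
#'
#' @param cell_id Unique integer id.
#' @param parent_id Integer parent id or `NA` for the founder.
#' @param n_divisions Divisions since the founder (0 for the founder).
#' @param mito A [mito_population()].
#' @return An object of class `"cell_record"`.
#' @export
cell_record <- function(cell_id, parent_id, n_divisions, mito) {
  stopifnot(inherits(mito, "mito_population"))
  structure(list(cell_id = as.integer(cell_id),
                 parent_id = as.integer(parent_id),
                 n_divisions = as.integer(n_divisions),
                 mito = mito),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("cell %d (parent %s, %d divisions): %d mtDNA copies, %d variant(s)\n",
              x$cell_id,
              if (is.na(x$parent_id)) "none" else x$parent_id,
              x$n_divisions, copy_number(x$mito),
              length(true_vaf_codes(x$mito)$codes)))
  invisible(x)
}

#' Create a founder cell, optionally with pre-existing heteroplasmies
#'
#' Pre-existing mtDNA mutations are common in real cells and drift over
#' subsequent divisions alongside de novo ones.  Each pre-existing variant is
#' placed on `round(frequency * N)` molecules; molecules are chosen
#' independently per variant, so co-occurrence on the same molecule is
#' random.
#'
#' @param config A [sim_config()].
#' @param preexisting `NULL`, or a data frame with columns `position`
#'   (0-based), `frequency` in `[0, 1]`, and optionally `allele` (default
#'   `"C"`); see [founder_variants()].  Positions must be distinct.
#' @return A [cell_record()] with id 1 and `N` molecules.
#' @export
#' @examples
#' set.seed(1)
#' cell <- make_founder(sim_config(N = 100), founder_variants(3242, 0.3))
#' true_vaf(cell$mito)
make_founder <- function(config, preexisting = NULL) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$N
  if (is.null(preexisting) || NROW(preexisting) == 0L) {
    return(cell_record(1L, NA_integer_, 0L,
                       new_mito(list(integer(0)), N)))
  }
  preexisting <- as.data.frame(preexisting)
  if (!all(c("position", "frequency") %in% names(preexisting))) {
    stop("'preexisting' needs columns 'position' and 'frequency'", call. = FALSE)
  }
  if (is.null(preexisting$allele)) preexisting$allele <- "C"
  f <- preexisting$frequency
  if (any(f < 0 | f > 1)) stop("founder variant frequencies must be in [0, 1]",
                               call. = FALSE)
  if (any(preexisting$position < 0 | preexisting$position >= config$L)) {
    stop("founder variant positions must be in [0, L)", call. = FALSE)
  }
  if (anyDuplicated(preexisting$position)) {
    stop("founder variant positions must be distinct", call. = FALSE)
  }
  codes <- variant_code(preexisting$position, preexisting$allele)
  molecules <- vector("list", N)
  for (i in seq_along(codes)) {
    nv <- round(f[i] * N)
    if (nv > 0L) {
      idx <- sample.int(N, nv)
      for (j in idx) molecules[[j]] <- c(molecules[[j]], codes[i])
    }
  }
  key <- vapply(molecules, paste, "", collapse = ",")
  first <- !duplicated(key)
  counts <- as.integer(table(factor(key, levels = key[first])))
  haps <- lapply(molecules[first], function(v) sort(as.integer(v)))
  cell_record(1L, NA_integer_, 0L, new_mito(haps, counts))
}

#' @rdname make_founder
#' @param position,frequency,allele Vectors defining pre-existing variants.
#' @export
founder_variants <- function(position, frequency, allele = "C") {
  data.frame(position = as.integer(position),
             frequency = as.numeric(frequency),
             allele = rep_len(as.character(allele), length(position)),
             stringsAsFactors = FALSE)
}

#' Replicate a single mtDNA molecule
#'
#' Returns a copy of the haplotype carrying `K ~ Poisson(mu * L)` additional
#' de novo variants.  Positions are uniform on `[0, L)` with a uniformly
#' chosen alternate allele; a drawn position already mutated on this molecule
#' is redrawn.  Recurrent mutation at the same site on *different* molecules
#' or lineages is deliberately allowed (finite-sites homoplasy).
#'
#' @param haplotype Sorted integer vector of variant codes.
#' @param config A [sim_config()].
#' @return The replicated haplotype (integer vector of variant codes).
#' @export
replicate_molecule <- function(haplotype, config) {
  muL <- config$mu * config$L
  k <- if (muL > 0) stats::rpois(1L, muL) else 0L
  if (k == 0L) return(haplotype)
  mutate_haplotype(haplotype, k, config$L)
}

## Add k de novo variants to a haplotype, redrawing positions that collide
## with ones already mutated on the molecule (including the new ones).
mutate_haplotype <- function(haplotype, k, L) {
  pos <- haplotype %/% 3L
  newv <- integer(k)
  for (i in seq_len(k)) {
    repeat {
      p <- sample.int(L, 1L) - 1L
      if (!(p %in% pos)) break
    }
    newv[i] <- p * 3L + (sample.int(3L, 1L) - 1L)
    pos <- c(pos, p)
  }
  sort(c(haplotype, newv))
}

## t sequential uniform-with-replacement draws from a growing pool, counted
## per haplotype class.  By Polya-urn exchangeability this is exactly
## Dirichlet-multinomial(t, counts): draw class weights ~ Gamma(counts), then
## a multinomial.
urn_draws <- function(counts, t) {
  g <- stats::rgamma(length(counts), shape = counts)
  if (!any(g > 0)) g <- counts   # numerical underflow guard
  as.vector(stats::rmultinom(1L, t, g))
}

## Relaxed expansion of a class table by t replication events.  Mutation
## events (K ~ Poisson(mu*L) per event) are interleaved at their sequential
## positions: the stretch of mutation-free events between them is a
## Dirichlet-multinomial block, and each mutation event picks its template
## in proportion to the current class counts, adding the mutated copy as a
## new class of size 1.
urn_expand <- function(haplotypes, counts, t, config) {
  if (t < 1L) return(list(haplotypes = haplotypes, counts = as.integer(counts)))
  muL <- config$mu * config$L
  k <- if (muL > 0) stats::rpois(t, muL) else integer(t)
  mut <- which(k > 0L)
  counts <- as.numeric(counts)
  at <- 1L
  for (b in seq_along(mut)) {
    gap <- mut[b] - at
    if (gap > 0L) counts <- counts + urn_draws(counts, gap)
    cl <- sample.int(length(counts), 1L, prob = counts)
    haplotypes <- c(haplotypes, list(mutate_haplotype(haplotypes[[cl]],
                                                      k[mut[b]], config$L)))
    counts <- c(counts, 1)
    at <- mut[b] + 1L
  }
  gap <- t + 1L - at
  if (gap > 0L) counts <- counts + urn_draws(counts, gap)
  list(haplotypes = haplotypes, counts = as.integer(counts))
}

#' Double a cell's mtDNA pool before division
#'
#' Expands the pool from its current size `n` to `2n`.  Under
#' `"strict_doubling"` every molecule is replicated exactly once; under
#' `"relaxed"` there are `n` replication events, each choosing its template
#' uniformly with replacement from the current growing pool, so replication
#' itself adds drift on top of segregation.  Every replication event can
#' introduce de novo variants (see [replicate_molecule()]).
#'
#' @param mito A [mito_population()].
#' @param config A [sim_config()].
#' @return A `mito_population` with twice the input copy number.
#' @export
double_population <- function(mito, config) {
  n <- copy_number(mito)
  if (n < 1L) stop("cannot double an empty population", call. = FALSE)
  muL <- config$mu * config$L
  if (config$replication_mode == "strict_doubling") {
    counts <- 2L * mito$counts
    haps <- mito$haplotypes
    k <- if (muL > 0) stats::rpois(n, muL) else integer(n)
    mut <- which(k > 0L)
    if (length(mut)) {
      # replication event j copies original molecule j (class order)
      cls <- findInterval(mut, cumsum(mito$counts), left.open = TRUE) + 1L
      for (i in seq_along(mut)) {
        counts[cls[i]] <- counts[cls[i]] - 1L
        haps <- c(haps, list(mutate_haplotype(mito$haplotypes[[cls[i]]],
                                              k[mut[i]], config$L)))
        counts <- c(counts, 1L)
      }
    }
    new_mito(haps, counts)
  } else {
    out <- urn_expand(mito$haplotypes, mito$counts, n, config)
    new_mito(out$haplotypes, out$counts)
  }
}

## Multivariate hypergeometric draw: sample k molecules without replacement
## from a class table.
rmvhyper <- function(counts, k) {
  K <- length(counts)
  out <- integer(K)
  rem_total <- sum(counts)
  rem_k <- as.integer(k)
  for (i in seq_len(K)) {
    if (rem_k == 0L) break
    x <- stats::rhyper(1L, counts[i], rem_total - counts[i], rem_k)
    out[i] <- x
    rem_k <- rem_k - x
    rem_total <- rem_total - counts[i]
  }
  out
}

#' Randomly segregate a doubled pool into two daughters
#'
#' Vegetative segregation: a uniformly random partition of the `2n` molecules
#' into two groups of exactly `n` (equivalently, daughter 1 receives a
#' without-replacement sample of size `n`).  Molecule identities are
#' preserved and the union of the daughters equals the parent multiset, so
#' per-variant copies are conserved: `VAF_d1 + VAF_d2 = 2 * VAF_parent`.
#'
#' @param mito A `mito_population` with even copy number.
#' @return List of two `mito_population`s of equal size.
#' @export
segregate <- function(mito) {
  n2 <- copy_number(mito)
  if (n2 %% 2L != 0L) stop("segregation needs an even copy number", call. = FALSE)
  x <- rmvhyper(mito$counts, n2 %/% 2L)
  list(new_mito(mito$haplotypes, x),
       new_mito(mito$haplotypes, mito$counts - x))
}

#' Apply a copy-number bottleneck
#'
#' Samples `bottleneck_size` molecules without replacement and re-expands the
#' pool to `N` by relaxed replication.  Bottlenecks accelerate heteroplasmy
#' shifts: low-frequency variants are frequently lost outright while the
#' survivors jump in frequency (with `b = 1` the output is homoplasmic for
#' one input haplotype, chosen with probability proportional to its copy
#' count).
#'
#' @param mito A [mito_population()].
#' @param config A [sim_config()] with `bottleneck_size` set.
#' @return A `mito_population` with copy number `N`.
#' @export
bottleneck <- function(mito, config) {
  b <- config$bottleneck_size
  if (is.null(b)) stop("'bottleneck_size' is not set in the config", call. = FALSE)
  n <- copy_number(mito)
  if (b >= n) stop("bottleneck size must be smaller than the copy number",
                   call. = FALSE)
  x <- rmvhyper(mito$counts, b)
  keep <- new_mito(mito$haplotypes, x)
  out <- urn_expand(keep$haplotypes, keep$counts, config$N - b, config)
  new_mito(out$haplotypes, out$counts)
}

#' Horizontal mitochondrial transfer between two cells
#'
#' Moves `k` molecules, sampled without replacement, from the donor to the
#' recipient (move semantics: the donor loses them), so the heteroplasmies of
#' *both* cells change.  Per-variant copy totals across the pair are
#' conserved.
#'
#' @param donor,recipient [cell_record()]s.
#' @param k Number of molecules to move, `1 <= k <` donor copy number.
#' @return List with updated `donor` and `recipient` cell records.
#' @export
transfer_molecules <- function(donor, recipient, k) {
  k <- as.integer(k)
  n <- copy_number(donor$mito)
  if (is.na(k) || k < 1L || k >= n) {
    stop("'k' must satisfy 1 <= k < donor copy number", call. = FALSE)
  }
  x <- rmvhyper(donor$mito$counts, k)
  recipient$mito <- new_mito(c(recipient$mito$haplotypes, donor$mito$haplotypes),
                             c(recipient$mito$counts, x))
  donor$mito <- new_mito(donor$mito$haplotypes, donor$mito$counts - x)
  list(donor = donor, recipient = recipient)
}

#' Divide a cell into two daughters
#'
#' Doubles the mtDNA pool (with de novo mutation), randomly segregates it
#' into two daughters, and, if the config sets a bottleneck, passes each
#' daughter through it.  Daughters get fresh ids, `parent_id` set to the
#' dividing cell, and `n_divisions` incremented by one.
#'
#' @param cell A [cell_record()].
#' @param config A [sim_config()].
#' @param ids Integer vector of two fresh daughter ids; the default heap
#'   numbering `2 * cell_id + c(0, 1)` suits pure synchronous growth.
#' @return List of two daughter [cell_record()]s.
#' @export
divide_cell <- function(cell, config, ids = cell$cell_id * 2L + c(0L, 1L)) {
  doubled <- double_population(cell$mito, config)
  pair <- segregate(doubled)
  if (!is.null(config$bottleneck_size)) {
    pair <- lapply(pair, bottleneck, config = config)
  }
  list(cell_record(ids[1L], cell$cell_id, cell$n_divisions + 1L, pair[[1L]]),
       cell_record(ids[2L], cell$cell_id, cell$n_divisions + 1L, pair[[2L]]))
}
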