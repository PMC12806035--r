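# shared fixtures and independent oracles, all built in code

MUT <- variant_code(1, "T")          # a single test variant
MUT_TOK <- variant_token(MUT)

# two-class population: n_ref reference molecules + n_mut carrying MUT
two_class_mito <- function(n_ref, n_mut) {
  mito_population(list(integer(0), MUT), c(n_ref, n_mut))
}

vaf_of <- function(mito, token = MUT_TOK) {
  f <- true_vaf(mito)[token]
  if (is.na(f)) 0 else unname(f)
}

# random additive tree with integer branch lengths
random_additive_tree <- function(ntip, max_len = 10L) {
  ape::rtree(ntip, br = function(n) sample.int(max_len, n, replace = TRUE))
}

# exact absorbing-Markov-chain fixation probability for a neutral variant:
# strict doubling (i mutants of N -> 2i of 2N), then hypergeometric
# segregation of one daughter; states 0..N, absorbing at 0 and N
markov_fixation_prob <- function(N, i0) {
  states <- 0:N
  P <- outer(states, states, function(i, j) {
    stats::dhyper(j, 2 * i, 2 * N - 2 * i, N)
  })
  trans <- 2:N                                 # transient states 1..N-1 (+1)
  Q <- P[trans, trans, drop = FALSE]
  R <- P[trans, N + 1L, drop = FALSE]          # absorption into state N
  absorb <- solve(diag(length(trans)) - Q, R)
  absorb[i0, 1L]
}

# brute-force sequential Polya urn: n draws, each duplicating a uniformly
# chosen molecule from the growing pool; returns final class counts
sequential_urn <- function(counts) {
  pool <- rep.int(seq_along(counts), counts)
  n <- length(pool)
  for (i in seq_len(n)) {
    pool <- c(pool, pool[sample.int(length(pool), 1L)])
  }
  tabulate(pool, nbins = length(counts))
}

# Monte-Carlo standard error of a sample variance
se_of_variance <- function(x) {
  n <- length(x)
  m4 <- mean((x - mean(x))^4)
  sqrt((m4 - stats::var(x)^2 * (n - 3) / (n - 1)) / n)
}

# build a cell_record holding a given variant->frequency map exactly
cell_with_vafs <- function(id, codes, freqs, N = 10L) {
  stopifnot(all(round(freqs * N) == freqs * N))
  mols <- vector("list", N)
  at <- 1L
  for (i in seq_along(codes)) {
    k <- as.integer(freqs[i] * N)
    if (k > 0L) for (j in seq_len(k)) {
      mols[[j]] <- c(mols[[j]], codes[i])
    }
  }
  key <- vapply(mols, paste, "", collapse = ",")
  first <- !duplicated(key)
  counts <- as.integer(table(factor(key, levels = key[first])))
  cell_record(id, NA_integer_, 0L,
              mito_population(mols[first], counts))
}
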