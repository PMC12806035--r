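#' Configuration of intracellular mtDNA dynamics
#'
#' Collects the parameters governing a single cell's mitochondrial genome
#' pool: genome length, per-cell copy number, per-site per-replication
#' mutation probability, the replication mode, and the optional bottleneck
#' and horizontal-transfer settings.
#'
#' Human mtDNA is 16,569 bp long and present in hundreds to thousands of
#' copies per cell; its mutation rate is one to two orders of magnitude above
#' the nuclear rate.  The defaults (`N = 500`, `mu = 1e-7` per site per
#' replication) are realistic placeholders in that range and are meant to be
#' overridden per study.
#'
#' @param L Mitochondrial genome length in bp (default 16569).
#' @param N mtDNA copies per cell at birth (default 500, must be >= 2).
#' @param mu Per-site per-replication mutation probability, in (0, 1).
#'   `mu = 0` is allowed and disables de novo mutation.
#' @param replication_mode `"relaxed"` (default): replication is not
#'   synchronised with the cell cycle; each of the N replication events picks
#'   its template uniformly with replacement from the current, growing pool,
#'   so some molecules replicate several times and others not at all.
#'   `"strict_doubling"`: every molecule is replicated exactly once.
#' @param bottleneck_size Optional integer `b`, `1 <= b < N`.  When set, each
#'   daughter cell passes through a copy-number bottleneck immediately after
#'   segregation: `b` molecules are sampled without replacement and the pool
#'   is re-expanded to `N` by relaxed replication.
#' @param transfer_rate Expected number of horizontal mitochondrial transfer
#'   events per renewal step (default 0 = disabled).
#' @param transfer_size Molecules moved per transfer event (default 0).
#' @return An object of class `"sim_config"`.
#' @export
#' @examples
#' sim_config(N = 100, mu = 1e-7)
sim_config <- function(L = 16569L, N = 500L, mu = 1e-7,
                       replication_mode = c("relaxed", "strict_doubling"),
                       bottleneck_size = NULL,
                       transfer_rate = 0, transfer_size = 0L) {
  replication_mode <- match.arg(replication_mode)
  L <- as.integer(L); N <- as.integer(N)
  if (is.na(L) || L < 1L) stop("'L' must be a positive integer", call. = FALSE)
  if (is.na(N) || N < 2L) stop("'N' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu >= 1) {
    stop("'mu' must be a single probability in [0, 1)", call. = FALSE)
  }
  if (!is.null(bottleneck_size)) {
    bottleneck_size <- as.integer(bottleneck_size)
    if (is.na(bottleneck_size) || bottleneck_size < 1L || bottleneck_size >= N) {
      stop("'bottleneck_size' must satisfy 1 <= b < N", call. = FALSE)
    }
  }
  if (transfer_rate < 0) stop("'transfer_rate' must be >= 0", call. = FALSE)
  transfer_size <- as.integer(transfer_size)
  if (is.na(transfer_size) || transfer_size < 0L) {
    stop("'transfer_size' must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(L = L, N = N, mu = mu, replication_mode = replication_mode,
         bottleneck_size = bottleneck_size,
         transfer_rate = transfer_rate, transfer_size = transfer_size),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("mtDNA simulation config\n")
  cat(sprintf("  genome length L:   %d bp\n", x$L))
  cat(sprintf("  copies per cell N: %d\n", x$N))
  cat(sprintf("  mutation rate mu:  %g per site per replication\n", x$mu))
  cat(sprintf("  replication mode:  %s\n", x$replication_mode))
  cat(sprintf("  bottleneck size:   %s\n",
              if (is.null(x$bottleneck_size)) "none" else x$bottleneck_size))
  if (x$transfer_rate > 0) {
    cat(sprintf("  transfer:          rate %g, %d molecules/event\n",
                x$transfer_rate, x$transfer_size))
  }
  invisible(x)
}

#' Configuration of tissue-level dynamics
#'
#' @param growth_divisions Number `g` of synchronous expansion rounds starting
#'   from a single founder; the population then holds `2^g` cells.
#' @param renewal_steps Number `r` of Moran renewal steps (one cell divides,
#'   one dies) applied after expansion; population size stays constant.
#' @param sample_size Number of alive cells drawn (without replacement) at the
#'   sampling time point.
#' @param max_cells Guard against runaway expansion (default 1e5).
#' @return An object of class `"tissue_config"`.
#' @export
tissue_config <- function(growth_divisions = 10L, renewal_steps = 2000L,
                          sample_size = 200L, max_cells = 1e5) {
  g <- as.integer(growth_divisions)
  r <- as.integer(renewal_steps)
  n <- as.integer(sample_size)
  if (is.na(g) || g < 0L) stop("'growth_divisions' must be >= 0", call. = FALSE)
  if (is.na(r) || r < 0L) stop("'renewal_steps' must be >= 0", call. = FALSE)
  if (is.na(n) || n < 1L) stop("'sample_size' must be >= 1", call. = FALSE)
  if (2^g > max_cells) {
    stop(sprintf("2^growth_divisions = %g exceeds max_cells = %g", 2^g, max_cells),
         call. = FALSE)
  }
  if (n > 2^g) stop("'sample_size' cannot exceed 2^growth_divisions", call. = FALSE)
  structure(list(growth_divisions = g, renewal_steps = r, sample_size = n,
                 max_cells = max_cells),
            class = "tissue_config")
}

#' @export
print.tissue_config <- function(x, ...) {
  cat(sprintf("tissue config: %d growth divisions (%d cells), %d renewal steps, sample %d\n",
              x$growth_divisions, 2^x$growth_divisions, x$renewal_steps,
              x$sample_size))
  invisible(x)
}

#' Configuration of the sequencing-noise model
#'
#' @param depth Mean per-site coverage (default 50).
#' @param support_threshold Minimum number of alternate reads required to call
#'   a variant in a cell (default 2); entries below the threshold are reported
#'   as VAF 0.
#' @param error_rate Per-read miscall probability (default 0).  A read drawn
#'   from a true-variant molecule is called reference with probability
#'   `error_rate`, and a reference read is miscalled to the specific alternate
#'   allele with probability `error_rate / 3`.
#' @param coverage_model `"poisson"` (default): per cell-variant coverage is
#'   Poisson(`depth`); `"fixed"`: exactly `depth` reads everywhere.
#' @return An object of class `"seq_config"`.
#' @export
seq_config <- function(depth = 50, support_threshold = 2L, error_rate = 0,
                       coverage_model = c("poisson", "fixed")) {
  coverage_model <- match.arg(coverage_model)
  if (!is.numeric(depth) || depth <= 0) stop("'depth' must be > 0", call. = FALSE)
  support_threshold <- as.integer(support_threshold)
  if (is.na(support_threshold) || support_threshold < 1L) {
    stop("'support_threshold' must be >= 1", call. = FALSE)
  }
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("'error_rate' must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(depth = depth, support_threshold = support_threshold,
                 error_rate = error_rate, coverage_model = coverage_model),
            class = "seq_config")
}

#' @export
print.seq_config <- function(x, ...) {
  cat(sprintf("sequencing config: %gx %s coverage, >= %d-read support, error rate %g\n",
              x$depth, x$coverage_model, x$support_threshold, x$error_rate))
  invisible(x)
}
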