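# sequencing-noise model, VAF matrix construction, and the empirical filters

test_that("the true VAF matrix unions variants with deterministic column order", {
  # one cell, no variants: 1 x 0 matrix
  ref <- cell_record(1L, NA_integer_, 0L, mito_population(list(integer(0)), 10L))
  m0 <- build_true_vaf_matrix(list(ref))
  expect_equal(dim(m0), c(1L, 0L))
  # a variant fixed in both cells: a column of ones
  v <- variant_code(5, "G")
  fixed <- lapply(1:2, function(i) {
    cell_record(i, NA_integer_, 0L, mito_population(list(v), 10L))
  })
  m1 <- build_true_vaf_matrix(fixed)
  expect_equal(unname(m1[, 1L]), c(1, 1))
  # union with zeros for absent variants
  v1 <- variant_code(1, "C"); v2 <- variant_code(2, "G")
  cells <- list(cell_with_vafs(1L, c(v1, v2), c(0.4, 0.2)),
                cell_with_vafs(2L, v1, 0.1))
  m2 <- build_true_vaf_matrix(cells)
  expect_equal(dim(m2), c(2L, 2L))
  expect_equal(colnames(m2), variant_token(c(v1, v2)))
  expect_equal(unname(m2), matrix(c(0.4, 0.1, 0.2, 0), 2L, 2L))
})

test_that("sequencing never calls an absent variant at zero error rate", {
  truth <- matrix(0, 50, 1, dimnames = list(paste0("cell", 1:50), "0:C"))
  set.seed(1)
  res <- simulate_sequencing(truth, seq_config(depth = 100))
  expect_true(all(res$alt == 0L))
  expect_equal(ncol(res$vaf), 0L)
  expect_true(all(res$alt <= res$cov))
})

test_that("observed VAF converges to the truth at high depth", {
  truth <- matrix(0.3, 2000, 1, dimnames = list(paste0("cell", 1:2000), "0:C"))
  set.seed(2)
  res <- simulate_sequencing(truth, seq_config(depth = 1e4))
  expect_lt(mean(abs(res$vaf[, 1L] - 0.3)), 0.01)
  # unbiased at support threshold 1 and zero error, conditional on coverage
  set.seed(3)
  res1 <- simulate_sequencing(truth, seq_config(depth = 50, support_threshold = 1))
  obs <- res1$alt[res1$cov > 0] / res1$cov[res1$cov > 0]
  expect_lt(abs(mean(obs) - 0.3), 3 * sd(obs) / sqrt(length(obs)))
})

test_that("raising the read-support threshold never adds a called variant", {
  truth <- matrix(runif(400, 0, 0.2), 100, 4,
                  dimnames = list(paste0("cell", 1:100), paste0(1:4, ":C")))
  for (thr in c(2L, 4L)) {
    set.seed(9)
    lo <- simulate_sequencing(truth, seq_config(depth = 30, support_threshold = thr))
    set.seed(9)
    hi <- simulate_sequencing(truth, seq_config(depth = 30, support_threshold = thr + 1L))
    called_lo <- lo$alt >= thr & lo$cov > 0
    called_hi <- hi$alt >= thr + 1L & hi$cov > 0
    expect_true(all(called_lo | !called_hi))
  }
})

test_that("the per-read error model perturbs the alternate-read probability", {
  truth <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "0:C"))
  set.seed(4)
  res <- simulate_sequencing(truth,
                             seq_config(depth = 5e4, error_rate = 0.03,
                                        support_threshold = 1,
                                        coverage_model = "fixed"))
  expect_equal(res$alt[1, 1] / res$cov[1, 1], 0.01, tolerance = 0.15)  # e/3
  expect_equal(res$alt[2, 1] / res$cov[2, 1], 0.97, tolerance = 0.01)  # 1-e
})

test_that("the entrywise VAF cutoff keeps strictly-greater values and is idempotent", {
  m <- matrix(c(0.005, 0.30, 0.005, 0.009), 2, 2,
              dimnames = list(c("a", "b"), c("1:C", "2:C")))
  f <- filter_low_vaf(m, 0.01)
  expect_equal(colnames(f), "1:C")            # all-zero column dropped
  expect_equal(unname(f[, 1L]), c(0, 0.30))
  expect_identical(filter_low_vaf(f, 0.01), f)
  # cutoff 0: exact zeros removed, everything else untouched
  m0 <- cbind(m, "3:C" = c(0, 0))
  expect_equal(colnames(filter_low_vaf(m0, 0)), c("1:C", "2:C"))
  # per-variant-max mode drops whole columns without zeroing entries
  pv <- filter_low_vaf(m, 0.01, per_variant_max = TRUE)
  expect_equal(unname(pv[, 1L]), c(0.005, 0.30))
})

test_that("the empirical clone filter applies the 5% / 80% rule per clone", {
  mk <- function(vals) matrix(vals, ncol = 1,
                              dimnames = list(paste0("c", seq_along(vals)), "7:C"))
  labels <- rep("clone1", 5)
  expect_equal(empirical_clone_filter(mk(rep(0.5, 5)), labels), "7:C")
  expect_equal(empirical_clone_filter(mk(rep(0.04, 5)), labels), character(0))
  expect_equal(empirical_clone_filter(mk(c(0.06, 0.06, 0.06, 0.06, 0)), labels),
               "7:C")                          # 4/5 = 0.8 just reaches
  expect_equal(empirical_clone_filter(mk(c(0.06, 0.06, 0.06, 0, 0)), labels),
               character(0))                   # 3/5 falls short
  # a qualifying clone suffices even if others fail
  two <- rbind(mk(rep(0.5, 5)), mk(rep(0, 5)))
  rownames(two) <- paste0("c", 1:10)
  expect_equal(empirical_clone_filter(two, rep(c("A", "B"), each = 5)), "7:C")
  expect_error(empirical_clone_filter(mk(rep(0.5, 5)),
                                      factor(labels, levels = c("clone1", "ghost"))),
               "empty clone")
})

test_that("coverage arithmetic reproduces the WGS worked example", {
  cov <- expected_mt_coverage(1e7, 0.005, 300, 16569)
  expect_equal(cov$mt_reads, 5e4)
  expect_equal(cov$coverage, 5e4 * 300 / 16569, tolerance = 1e-12)
  expect_equal(round(cov$coverage), 905)
  expect_error(expected_mt_coverage(1e7, 0), "positive")
  expect_error(expected_mt_coverage(-1, 0.005), "positive")
})
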