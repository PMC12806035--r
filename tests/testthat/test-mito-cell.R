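# intracellular dynamics: founder construction, replication with mutation,
# doubling, segregation, bottleneck, transfer, and the drift laws they obey

test_that("variant tokens round-trip and reject nonsense", {
  codes <- variant_code(c(0, 7, 16568), c("C", "G", "T"))
  expect_identical(parse_variant_token(variant_token(codes)), codes)
  expect_error(variant_code(3, "A"), "allele")
  expect_error(parse_variant_token("12"), "token")
})

test_that("founder construction places pre-existing variants at the rounded frequency", {
  cfg <- sim_config(N = 100L, mu = 0)
  set.seed(1)
  # no variants: all reference
  f0 <- make_founder(cfg)
  expect_equal(copy_number(f0$mito), 100L)
  expect_length(true_vaf(f0$mito), 0L)
  expect_identical(f0$n_divisions, 0L)
  expect_true(is.na(f0$parent_id))
  # one variant at 0.30 -> exactly 30 molecules
  f1 <- make_founder(cfg, founder_variants(10, 0.30, "G"))
  expect_equal(unname(true_vaf(f1$mito)[variant_token(variant_code(10, "G"))]),
               0.30)
  # fixed + half-frequency variant on N = 10
  cfg10 <- sim_config(N = 10L, mu = 0)
  f2 <- make_founder(cfg10, founder_variants(c(1, 2), c(1.0, 0.5), c("C", "T")))
  v <- true_vaf(f2$mito)
  expect_equal(unname(v[variant_token(variant_code(1, "C"))]), 1.0)
  expect_equal(unname(v[variant_token(variant_code(2, "T"))]), 0.5)
  # every molecule carries the fixed variant
  expect_true(all(vapply(f2$mito$haplotypes,
                         function(h) variant_code(1, "C") %in% h, logical(1))))
  expect_error(make_founder(cfg, founder_variants(1, 1.2)), "\\[0, 1\\]")
  expect_error(make_founder(cfg, founder_variants(c(3, 3), c(0.1, 0.2))),
               "distinct")
})

test_that("molecule replication is the identity at mu = 0 and redraws collided positions", {
  cfg <- sim_config(N = 10L, mu = 0)
  hap <- variant_code(c(5, 9), c("C", "G"))
  expect_identical(replicate_molecule(hap, cfg), hap)
  # L = 2 with position 0 occupied: a single new mutation must land on 1
  set.seed(42)
  for (i in 1:20) {
    out <- mitodrift:::mutate_haplotype(variant_code(0, "C"), 1L, 2L)
    expect_length(unique(out %/% 3L), 2L)
    expect_true(1L %in% (out %/% 3L))
  }
})

test_that("de novo mutation count per replication is Poisson(mu * L)", {
  cfg <- sim_config(N = 10L, mu = 1e-7)   # mu * L = 1.6569e-3
  muL <- cfg$mu * cfg$L
  set.seed(7)
  n <- 1e6L
  k <- vapply(seq_len(n), function(i) length(replicate_molecule(integer(0), cfg)),
              integer(1))
  se_mean <- sqrt(muL / n)
  expect_lt(abs(mean(k) - muL), 3 * se_mean)
  # Poisson: variance equals the mean
  expect_lt(abs(var(k) - muL), 3 * sqrt((muL + 2 * muL^2) / n))
})

test_that("strict doubling duplicates every molecule and preserves frequencies", {
  cfg <- sim_config(N = 10L, mu = 0, replication_mode = "strict_doubling")
  m <- two_class_mito(7L, 3L)
  d <- double_population(m, cfg)
  expect_equal(copy_number(d), 20L)
  expect_equal(vaf_of(d), 0.3)
  ref <- mito_population(list(integer(0)), 10L)
  dref <- double_population(ref, cfg)
  expect_equal(copy_number(dref), 20L)
  expect_length(true_vaf(dref), 0L)
})

test_that("relaxed doubling matches the sequential Polya-urn law", {
  cfg <- sim_config(N = 10L, mu = 0, replication_mode = "relaxed")
  m <- two_class_mito(5L, 5L)
  nrep <- 2e4L
  set.seed(11)
  impl <- replicate(nrep, vaf_of(double_population(m, cfg)))
  set.seed(12)
  oracle <- replicate(nrep, {
    x <- sequential_urn(c(5L, 5L))
    x[2L] / 20
  })
  expect_equal(copy_number(double_population(m, cfg)), 20L)
  # means agree with each other and with the martingale value 0.5
  se <- sqrt(var(impl) / nrep + var(oracle) / nrep)
  expect_lt(abs(mean(impl) - mean(oracle)), 3 * se)
  expect_lt(abs(mean(impl) - 0.5), 3 * sd(impl) / sqrt(nrep))
  # replication itself adds variance, and the same amount as the urn oracle
  expect_gt(var(impl), 0)
  se_v <- sqrt(se_of_variance(impl)^2 + se_of_variance(oracle)^2)
  expect_lt(abs(var(impl) - var(oracle)), 3 * se_v)
})

test_that("segregation splits molecules evenly and conserves every variant", {
  cfg <- sim_config(N = 10L, mu = 1e-6)
  ref20 <- mito_population(list(integer(0)), 20L)
  pair <- segregate(ref20)
  expect_equal(copy_number(pair[[1]]), 10L)
  expect_equal(copy_number(pair[[2]]), 10L)
  expect_error(segregate(mito_population(list(integer(0)), 9L)), "even")
  set.seed(3)
  for (i in 1:20) {
    d <- double_population(make_founder(cfg, founder_variants(c(2, 4), c(0.3, 0.6)))$mito, cfg)
    pair <- segregate(d)
    va <- true_vaf(pair[[1]]); vb <- true_vaf(pair[[2]]); vp <- true_vaf(d)
    toks <- names(vp)
    get <- function(v) ifelse(is.na(v[toks]), 0, v[toks])
    expect_equal(unname(get(va) + get(vb)), unname(2 * vp), tolerance = 1e-12)
  }
})

test_that("neutral division is a martingale and fixation is absorbing", {
  cfg <- sim_config(N = 10L, mu = 0, replication_mode = "strict_doubling")
  fixed <- cell_record(1L, NA_integer_, 0L, two_class_mito(0L, 10L))
  kids <- divide_cell(fixed, cfg)
  expect_equal(vaf_of(kids[[1]]$mito), 1)
  expect_equal(vaf_of(kids[[2]]$mito), 1)
  expect_equal(kids[[1]]$n_divisions, 1L)
  expect_equal(kids[[1]]$parent_id, 1L)
  parent <- cell_record(1L, NA_integer_, 0L, two_class_mito(7L, 3L))
  set.seed(21)
  nrep <- 2e4L
  v <- replicate(nrep, vaf_of(divide_cell(parent, cfg)[[1]]$mito))
  expect_lt(abs(mean(v) - 0.3), 3 * sd(v) / sqrt(nrep))
})

test_that("bottleneck resamples and re-expands, losing low-frequency variants", {
  # b = copy_number - 1, homoplasmic mutant, mu = 0: composition unchanged
  cfg <- sim_config(N = 10L, mu = 0, bottleneck_size = 9L)
  hom <- two_class_mito(0L, 10L)
  out <- bottleneck(hom, cfg)
  expect_equal(copy_number(out), 10L)
  expect_equal(vaf_of(out), 1)
  expect_error(bottleneck(two_class_mito(5L, 4L), cfg), "smaller")
  expect_error(bottleneck(hom, sim_config(N = 10L, mu = 0)), "not set")
  # b = 1: output homoplasmic; fixation probability = copy fraction
  cfg1 <- sim_config(N = 10L, mu = 0, bottleneck_size = 1L)
  m <- two_class_mito(8L, 2L)
  set.seed(31)
  nrep <- 4e3L
  fixed <- replicate(nrep, vaf_of(bottleneck(m, cfg1)))
  expect_true(all(fixed %in% c(0, 1)))
  ht <- stats::binom.test(sum(fixed == 1), nrep, p = 0.2)
  expect_gt(ht$p.value, 1e-4)
})

test_that("mitochondrial transfer moves molecules and changes both cells", {
  donor <- cell_record(1L, NA_integer_, 0L, two_class_mito(0L, 100L))
  recip <- cell_record(2L, NA_integer_, 0L, two_class_mito(100L, 0L))
  set.seed(5)
  res <- transfer_molecules(donor, recip, 10L)
  expect_equal(copy_number(res$donor$mito), 90L)
  expect_equal(copy_number(res$recipient$mito), 110L)
  expect_equal(vaf_of(res$recipient$mito), 10 / 110, tolerance = 1e-12)
  # total mutant copies conserved across the pair
  tot <- vaf_of(res$donor$mito) * 90 + vaf_of(res$recipient$mito) * 110
  expect_equal(tot, 100, tolerance = 1e-9)
  # reference-only transfer leaves the recipient's VAFs untouched
  ref_a <- cell_record(3L, NA_integer_, 0L, two_class_mito(50L, 0L))
  ref_b <- cell_record(4L, NA_integer_, 0L, two_class_mito(50L, 0L))
  res2 <- transfer_molecules(ref_a, ref_b, 5L)
  expect_equal(copy_number(res2$recipient$mito), 55L)
  expect_length(true_vaf(res2$recipient$mito), 0L)
  expect_error(transfer_molecules(res$donor, recip, 90L), "k <")
})

test_that("true VAF counts molecules across haplotype classes", {
  expect_length(true_vaf(mito_population(list(integer(0)), 10L)), 0L)
  expect_equal(unname(true_vaf(two_class_mito(7L, 3L))), 0.3)
  v1 <- variant_code(1, "C"); v2 <- variant_code(2, "G")
  m <- mito_population(list(v1, c(v1, v2), integer(0)), c(2L, 2L, 6L))
  v <- true_vaf(m)
  expect_equal(unname(v[variant_token(v1)]), 0.4)
  expect_equal(unname(v[variant_token(v2)]), 0.2)
  expect_error(mito_population(list(c(v1, variant_code(1, "G"))), 1L),
               "one variant per position")
})
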