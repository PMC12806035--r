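# clone assignment, clone aggregation score, closest-pair ground-truth
# distance, and the cross-condition comparison wrapper

balanced_tree <- function(h) {
  tr <- ape::stree(2^h, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

caterpillar <- ape::read.tree(
  text = "(((((((t1:1,t2:1):1,t3:1):1,t4:1):1,t5:1):1,t6:1):1,t7:1):1,t8:1);")

test_that("greedy clade splitting balances clone sizes where the topology allows", {
  bal <- balanced_tree(3L)
  for (k in c(2L, 4L, 8L)) {
    asg <- assign_clones(bal, k)
    expect_true(all(table(asg) == 8L / k))
    # every clone is a clade: tips of a clone share their MRCA exclusively
    for (cl in unique(asg)) {
      tips <- names(asg)[asg == cl]
      if (length(tips) > 1L) {
        node <- ape::getMRCA(bal, tips)
        expect_setequal(ape::extract.clade(bal, node)$tip.label, tips)
      }
    }
  }
  expect_true(all(table(assign_clones(bal, 8L)) == 1L))   # singletons
  # caterpillar, k = 3: the greedy trace gives clades of sizes 6, 1, 1
  expect_equal(sort(as.vector(table(assign_clones(caterpillar, 3L)))),
               c(1L, 1L, 6L))
  expect_error(assign_clones(caterpillar, 1L), "at least 2")
  expect_error(assign_clones(caterpillar, 9L), "exceeds")
})

test_that("CAS is 1 for clade clones on the tree itself and for compact pairs", {
  bal <- balanced_tree(3L)
  asg <- assign_clones(bal, 4L)
  cas <- clone_aggregation_score(bal, asg)
  expect_true(all(cas == 1))
  expect_true(all(attr(cas, "per_tip") == 1))
  # hand 4-tip case: {1,2} mutually nearest and labelled A, {3,4} labelled B
  quad <- ape::read.tree(text = "((t1:1,t2:1):2,(t3:1,t4:1):2);")
  asg2 <- stats::setNames(c(1L, 1L, 2L, 2L), paste0("t", 1:4))
  expect_true(all(clone_aggregation_score(quad, asg2) == 1))
  # singleton clones score 1 by convention
  asg3 <- stats::setNames(c(1L, 1L, 2L, 3L), paste0("t", 1:4))
  cas3 <- clone_aggregation_score(quad, asg3)
  expect_equal(unname(cas3[c("2", "3")]), c(1, 1))
  expect_error(clone_aggregation_score(quad, asg2[1:3]), "tip sets differ")
})

test_that("CAS under random labels matches the sampling-without-replacement baseline", {
  set.seed(23)
  sim <- simulate_tissue(sim_config(N = 20L, mu = 0), tissue_config(6L, 0L, 48L))
  asg <- assign_clones(sim$truth, 8L)
  n <- length(asg); sizes <- table(asg)
  nperm <- 400L
  pm <- replicate(nperm, {
    clone_aggregation_score(sim$truth, stats::setNames(sample(asg), names(asg)))
  })
  ns <- names(sizes)[sizes >= 2L]          # singletons score 1 by convention
  pooled <- colMeans(pm[ns, , drop = FALSE])
  expected <- mean((sizes[ns] - 1) / (n - 1))
  se <- sd(pooled) / sqrt(nperm)
  expect_lt(abs(mean(pooled) - expected), 3 * se)
})

test_that("closest-pair distances are read off the truth tree for reconstructed pairs", {
  truth <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # perfect reconstruction attains each tip's true nearest-relative distance
  cpd0 <- closest_pair_truth_distance(truth, truth)
  expect_equal(unname(cpd0[c("A", "B", "C", "D")]), rep(2, 4))
  # a reconstruction pairing A with C is charged the truth distance 4
  recon <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  cpd <- closest_pair_truth_distance(recon, truth)
  expect_equal(unname(cpd["A"]), 4)
  expect_equal(unname(cpd["C"]), 4)
  # terminal-edges-only mode sums the pair's two terminal branches instead
  cpd_t <- closest_pair_truth_distance(recon, truth, terminal_edges_only = TRUE)
  expect_equal(unname(cpd_t["A"]), 2)
  expect_error(closest_pair_truth_distance(ape::read.tree(text = "(A:1,X:1);"),
                                           truth), "tip sets differ")
})

test_that("both metrics ignore recon rerooting and uniform branch rescaling", {
  set.seed(24)
  sim <- simulate_tissue(sim_config(N = 20L, mu = 1e-6), tissue_config(5L, 0L, 20L))
  mats <- list(x = sim$vaf)
  recon <- neighbor_joining(vaf_dist(sim$vaf, "jaccard"))
  asg <- assign_clones(sim$truth, 5L)
  cas <- clone_aggregation_score(recon, asg)
  cpd <- closest_pair_truth_distance(recon, sim$truth)
  rerooted <- ape::root(recon, outgroup = recon$tip.label[3L], resolve.root = TRUE)
  scaled <- recon; scaled$edge.length <- scaled$edge.length * 37.5
  for (variant in list(rerooted, scaled)) {
    expect_equal(clone_aggregation_score(variant, asg), cas)
    expect_equal(closest_pair_truth_distance(variant, sim$truth), cpd)
  }
})

test_that("condition comparison scores each matrix and demands matching cells", {
  set.seed(25)
  sim <- simulate_tissue(sim_config(N = 20L, mu = 1e-6), tissue_config(5L, 0L, 16L))
  reports <- compare_conditions(sim$truth, list(a = sim$vaf, b = sim$vaf), k = 4L)
  expect_named(reports, c("a", "b"))
  expect_equal(reports$a$cas_per_clone, reports$b$cas_per_clone)
  expect_equal(reports$a$closest_pair, reports$b$closest_pair)
  truncated <- sim$vaf[-1L, , drop = FALSE]
  expect_error(compare_conditions(sim$truth, list(bad = truncated), k = 4L),
               "does not cover")
  # report serialisation is valid JSON with the per-clone scores
  f <- tempfile(fileext = ".json")
  write_metrics_report(reports$a, f, extra = list(seed = 25))
  parsed <- jsonlite::read_json(f)
  expect_equal(length(parsed$cas_per_clone), 4L)
  expect_equal(parsed$seed, 25L)
})
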