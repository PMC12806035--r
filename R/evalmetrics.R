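## Benchmark metrics: ground-truth clone assignment by greedy clade
## splitting, the clone aggregation score (CAS), and the closest-pair
## ground-truth distance.  Both scores depend only on distance ranks in the
## reconstruction and on path distances in the truth tree, so they are
## invariant to rerooting and uniform rescaling of the reconstructed tree.

## children and per-node descendant-tip lists of a rooted phylo
tree_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Partition the truth tree into k similarly sized clades ("clones")
#'
#' Greedy clade splitting: start from the root's children as groups and
#' repeatedly replace the group with the most tips by the two clades at its
#' root bifurcation until `k` groups exist.  Every group is a clade of the
#' truth tree and the procedure is deterministic (ties broken by the
#' smallest descendant tip label).  Clones are numbered 1..k in order of
#' their smallest tip label.
#'
#' @param tree Rooted binary `"phylo"` truth tree.
#' @param k Number of clones, `2 <= k <=` number of tips (default 20).
#' @return Named integer vector mapping each tip label to its clone.
#' @export
assign_clones <- function(tree, k = 20) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("'k' must be at least 2", call. = FALSE)
  if (k > ntip) stop(sprintf("'k' (%d) exceeds the tip count (%d)", k, ntip),
                     call. = FALSE)
  desc <- tree_descendants(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- ntip + 1L
  groups <- kids[[as.character(root)]]
  min_lab <- vapply(desc, function(tp) min(tree$tip.label[tp]), "")
  while (length(groups) < k) {
    sizes <- lengths(desc[groups])
    internal <- groups > ntip
    sizes[!internal] <- -1L               # tips cannot be split
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) best <- best[order(min_lab[groups[best]])][1L]
    node <- groups[best]
    groups <- c(groups[-best], kids[[as.character(node)]])
  }
  groups <- groups[order(min_lab[groups])]
  out <- integer(ntip)
  for (g in seq_along(groups)) out[desc[[groups[g]]]] <- g
  stats::setNames(out, tree$tip.label)
}

check_tip_match <- function(recon, assignment_or_truth) {
  labs <- if (inherits(assignment_or_truth, "phylo")) {
    assignment_or_truth$tip.label
  } else {
    names(assignment_or_truth)
  }
  if (!setequal(recon$tip.label, labs) ||
      length(recon$tip.label) != length(labs)) {
    extra <- setdiff(recon$tip.label, labs)
    missing <- setdiff(labs, recon$tip.label)
    stop("tip sets differ",
         if (length(extra)) paste0("; only in reconstruction: ",
                                   paste(utils::head(extra, 5), collapse = ", ")),
         if (length(missing)) paste0("; missing from reconstruction: ",
                                     paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
}

## neighbor ordering per tip: indices of the other tips sorted by
## reconstructed distance, ties by label
neighbor_order <- function(D) {
  labs <- rownames(D)
  lapply(seq_len(nrow(D)), function(i) {
    o <- order(D[i, ], labs)
    o[o != i]
  })
}

#' Clone aggregation score (CAS)
#'
#' Scores how tightly the cells of each ground-truth clone cluster in a
#' reconstructed tree.  For a clone `c` with `n_c >= 2` tips, every tip's
#' `m = n_c - 1` nearest other tips (by reconstructed path distance, ties
#' broken by label order) are inspected and the fraction belonging to `c` is
#' averaged over the clone's tips.  A perfectly monophyletic, compact clone
#' scores 1; under random labels the expectation is `(n_c - 1) / (n - 1)`.
#' Singleton clones score 1 by convention (vacuous aggregation).
#'
#' This nearest-neighbour purity operationalisation is isolated here so an
#' alternative formula can be swapped in; note that a clone can score below
#' 1 even on the true tree when its internal diameter exceeds the distance
#' to its neighbours (impossible for ultrametric trees).
#'
#' @param recon Reconstructed `"phylo"` tree.
#' @param assignment Named clone vector from [assign_clones()].
#' @return Named numeric vector of per-clone scores in `[0, 1]`, with the
#'   per-tip scores in attribute `"per_tip"`.
#' @export
clone_aggregation_score <- function(recon, assignment) {
  check_tip_match(recon, assignment)
  D <- cophenetic_distances(recon)
  labs <- rownames(D)
  cl <- assignment[labs]
  sizes <- table(cl)
  nb <- neighbor_order(D)
  per_tip <- vapply(seq_along(labs), function(i) {
    m <- sizes[[as.character(cl[i])]] - 1L
    if (m == 0L) return(1)
    mean(cl[nb[[i]][seq_len(m)]] == cl[i])
  }, numeric(1))
  names(per_tip) <- labs
  per_clone <- vapply(split(per_tip, cl), mean, numeric(1))
  names(per_clone) <- names(split(per_tip, cl))
  attr(per_clone, "per_tip") <- per_tip
  per_clone
}

#' Ground-truth distance of each tip's closest reconstructed partner
#'
#' For every tip the closest other tip in the *reconstructed* tree is found
#' (path distance, ties broken by smallest label) and the pair's distance is
#' then measured in the *truth* tree, in divisions.  Accurate fine-scale
#' reconstruction keeps these values at each tip's true nearest-relative
#' distance; misplacing tips inflates them, up to the truth-tree diameter.
#'
#' @param recon Reconstructed `"phylo"` tree.
#' @param truth Ground-truth `"phylo"` tree over the same tips.
#' @param terminal_edges_only Use the sum of the pair's two terminal branch
#'   lengths in the truth tree instead of the full path distance (default
#'   `FALSE`).
#' @return Named numeric vector, one value per tip.
#' @export
closest_pair_truth_distance <- function(recon, truth,
                                        terminal_edges_only = FALSE) {
  check_tip_match(recon, truth)
  Dr <- cophenetic_distances(recon)
  labs <- rownames(Dr)
  nb <- neighbor_order(Dr)
  partner <- labs[vapply(nb, `[`, integer(1), 1L)]
  if (terminal_edges_only) {
    ntip <- length(truth$tip.label)
    tip_edge <- stats::setNames(
      truth$edge.length[match(seq_len(ntip), truth$edge[, 2L])],
      truth$tip.label)
    out <- tip_edge[labs] + tip_edge[partner]
  } else {
    Dt <- cophenetic_distances(truth)
    out <- Dt[cbind(labs, partner)]
  }
  stats::setNames(as.numeric(out), labs)
}

summary_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  list(mean = mean(x), median = stats::median(x), q25 = q[1L], q75 = q[2L])
}

#' Evaluate one reconstruction against the truth
#'
#' Computes the clone aggregation score and the closest-pair ground-truth
#' distances for a reconstructed tree, bundling per-clone, per-tip, and
#' summary values into a `"metrics_report"`.
#'
#' @param recon Reconstructed `"phylo"` tree.
#' @param truth Ground-truth `"phylo"` tree.
#' @param assignment Clone assignment (default: [assign_clones()] on the
#'   truth with `k`).
#' @param k Number of clones when `assignment` is not given.
#' @param condition Condition tag stored in the report (e.g. `"all_vaf"`).
#' @return A `"metrics_report"` object.
#' @export
evaluate_reconstruction <- function(recon, truth,
                                    assignment = assign_clones(truth, k),
                                    k = 20, condition = "unnamed") {
  cas <- clone_aggregation_score(recon, assignment)
  cpd <- closest_pair_truth_distance(recon, truth)
  structure(list(condition = condition,
                 cas_per_clone = as.numeric(cas),
                 clone = names(cas),
                 cas_per_cell = attr(cas, "per_tip"),
                 closest_pair = cpd,
                 summary = list(cas = summary_stats(as.numeric(cas)),
                                cas_per_cell = summary_stats(attr(cas, "per_tip")),
                                closest_pair = summary_stats(cpd))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report [%s]: %d clones, %d cells\n",
              x$condition, length(x$cas_per_clone), length(x$closest_pair)))
  cat(sprintf("  CAS          mean %.3f  median %.3f\n",
              x$summary$cas$mean, x$summary$cas$median))
  cat(sprintf("  closest-pair mean %.2f  median %.2f divisions\n",
              x$summary$closest_pair$mean, x$summary$closest_pair$median))
  invisible(x)
}

#' Compare lineage reconstructions across data conditions
#'
#' Runs the reconstruction-and-scoring pipeline (VAF distances, neighbor
#' joining, CAS, closest-pair distance) once per named condition matrix and
#' returns one [evaluate_reconstruction()] report per condition.  All
#' matrices must cover the same cell set as the truth tree.
#'
#' @param truth Ground-truth `"phylo"` tree.
#' @param matrices Named list of VAF matrices (cells in rows), one per
#'   condition; names are the condition tags.
#' @param k Number of ground-truth clones (default 20).
#' @param metric Distance metric for [vaf_dist()].
#' @return Named list of `"metrics_report"`s.
#' @export
compare_conditions <- function(truth, matrices, k = 20, metric = "euclidean") {
  stopifnot(is.list(matrices), length(matrices) >= 1L,
            !is.null(names(matrices)))
  assignment <- assign_clones(truth, k)
  out <- lapply(names(matrices), function(tag) {
    m <- matrices[[tag]]
    if (!setequal(rownames(m), truth$tip.label)) {
      stop(sprintf("condition '%s' does not cover the sampled cell set", tag),
           call. = FALSE)
    }
    d <- suppressWarnings(vaf_dist(m, metric))
    recon <- neighbor_joining(d)
    evaluate_reconstruction(recon, truth, assignment, condition = tag)
  })
  stats::setNames(out, names(matrices))
}

#' Serialise a metrics report (or a list of them) as JSON
#'
#' @param report A `"metrics_report"` or a named list of them.
#' @param path Output file path.
#' @param extra Optional named list (config echo, seed, ...) merged into the
#'   JSON object.
#' @export
write_metrics_report <- function(report, path, extra = NULL) {
  as_plain <- function(r) {
    list(condition = r$condition,
         cas_per_clone = stats::setNames(as.list(r$cas_per_clone), r$clone),
         cas_per_cell = as.list(r$cas_per_cell),
         closest_pair_truth_distances = as.list(r$closest_pair),
         summary = r$summary)
  }
  obj <- if (inherits(report, "metrics_report")) {
    as_plain(report)
  } else {
    lapply(report, as_plain)
  }
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
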