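## Tissue-level simulation: synchronous exponential expansion from one
## founder, then constant-size Moran renewal (one cell divides, one dies per
## step), with the full division genealogy recorded so the ground-truth
## lineage tree of any cell sample can be extracted exactly.

new_tissue <- function(cells, ped_id, ped_parent, ped_ndiv, deaths,
                       next_id, sim_config, tissue_config) {
  structure(list(cells = cells,
                 ped_id = ped_id, ped_parent = ped_parent, ped_ndiv = ped_ndiv,
                 deaths = deaths, next_id = next_id,
                 sim_config = sim_config, tissue_config = tissue_config),
            class = "mito_tissue")
}

#' @export
print.mito_tissue <- function(x, ...) {
  cat(sprintf("mito_tissue: %d alive cells, %d cells ever recorded, %d deaths\n",
              length(x$cells), length(x$ped_id), length(x$deaths)))
  invisible(x)
}

#' Expand a founder into a tissue by synchronous divisions
#'
#' Starting from a single founder, every alive cell divides in each of `g`
#' rounds, giving `2^g` cells that have all undergone exactly `g` divisions.
#' The full genealogy (every parent-child relation) is recorded.
#'
#' @param sim_config A [sim_config()].
#' @param tissue_config A [tissue_config()]; `growth_divisions` is `g`.
#' @param founder_variants Optional pre-existing heteroplasmies for the
#'   founder, see [make_founder()].
#' @return A `"mito_tissue"` object.
#' @export
#' @examples
#' set.seed(1)
#' ts <- grow(sim_config(N = 20), tissue_config(3, 0, 4))
#' length(ts$cells)  # 8
grow <- function(sim_config, tissue_config, founder_variants = NULL) {
  stopifnot(inherits(sim_config, "sim_config"),
            inherits(tissue_config, "tissue_config"))
  g <- tissue_config$growth_divisions
  founder <- make_founder(sim_config, founder_variants)
  cells <- stats::setNames(list(founder), "1")
  ped_id <- 1L; ped_parent <- NA_integer_; ped_ndiv <- 0L
  next_id <- 2L
  for (d in seq_len(g)) {
    new_cells <- vector("list", 2L * length(cells))
    for (i in seq_along(cells)) {
      kids <- divide_cell(cells[[i]], sim_config,
                          ids = c(next_id, next_id + 1L))
      new_cells[[2L * i - 1L]] <- kids[[1L]]
      new_cells[[2L * i]] <- kids[[2L]]
      ped_id <- c(ped_id, next_id, next_id + 1L)
      ped_parent <- c(ped_parent, cells[[i]]$cell_id, cells[[i]]$cell_id)
      ped_ndiv <- c(ped_ndiv, d, d)
      next_id <- next_id + 2L
    }
    cells <- new_cells
    names(cells) <- vapply(cells, function(cl) as.character(cl$cell_id), "")
  }
  new_tissue(cells, ped_id, ped_parent, ped_ndiv, integer(0),
             next_id, sim_config, tissue_config)
}

#' Renew a tissue at constant size by Moran steps
#'
#' Each step one alive cell, chosen uniformly, divides (both daughters enter
#' the population) and one cell, chosen uniformly among the remaining alive
#' cells (daughters of the same step excluded), dies.  The population size is
#' therefore constant while the number of surviving founder lineages decays,
#' mimicking homeostatic tissue turnover.  When `transfer_rate > 0`, each
#' step additionally performs `Poisson(transfer_rate)` horizontal transfer
#' events of `transfer_size` molecules between uniformly chosen distinct
#' alive cells.
#'
#' @param tissue A `"mito_tissue"` from [grow()].
#' @param steps Number of Moran steps (default: the config's
#'   `renewal_steps`).
#' @return The updated `"mito_tissue"`.
#' @export
renew <- function(tissue, steps = tissue$tissue_config$renewal_steps) {
  stopifnot(inherits(tissue, "mito_tissue"))
  if (steps < 1L) return(tissue)
  if (length(tissue$cells) < 2L) stop("renewal needs at least 2 alive cells",
                                      call. = FALSE)
  cfg <- tissue$sim_config
  cells <- tissue$cells
  next_id <- tissue$next_id
  # preallocate pedigree extension
  add <- 2L * steps
  ped_id <- c(tissue$ped_id, integer(add))
  ped_parent <- c(tissue$ped_parent, integer(add))
  ped_ndiv <- c(tissue$ped_ndiv, integer(add))
  at <- length(tissue$ped_id)
  deaths <- tissue$deaths
  do_transfer <- cfg$transfer_rate > 0 && cfg$transfer_size > 0L
  for (step in seq_len(steps)) {
    di <- sample.int(length(cells), 1L)
    parent <- cells[[di]]
    kids <- divide_cell(parent, cfg, ids = c(next_id, next_id + 1L))
    cells[[di]] <- NULL
    # death among the other alive cells; the new daughters are exempt
    ki <- sample.int(length(cells), 1L)
    deaths <- c(deaths, cells[[ki]]$cell_id)
    cells[[ki]] <- NULL
    cells[[as.character(next_id)]] <- kids[[1L]]
    cells[[as.character(next_id + 1L)]] <- kids[[2L]]
    ped_id[at + 1:2] <- c(next_id, next_id + 1L)
    ped_parent[at + 1:2] <- parent$cell_id
    ped_ndiv[at + 1:2] <- parent$n_divisions + 1L
    at <- at + 2L
    next_id <- next_id + 2L
    if (do_transfer) {
      nt <- stats::rpois(1L, cfg$transfer_rate)
      for (tr in seq_len(nt)) {
        pair <- sample.int(length(cells), 2L)
        k <- min(cfg$transfer_size, copy_number(cells[[pair[1L]]]$mito) - 1L)
        if (k >= 1L) {
          res <- transfer_molecules(cells[[pair[1L]]], cells[[pair[2L]]], k)
          cells[[pair[1L]]] <- res$donor
          cells[[pair[2L]]] <- res$recipient
        }
      }
    }
  }
  new_tissue(cells, ped_id[seq_len(at)], ped_parent[seq_len(at)],
             ped_ndiv[seq_len(at)], deaths, next_id,
             cfg, tissue$tissue_config)
}

#' Sample alive cells uniformly without replacement
#'
#' @param tissue A `"mito_tissue"`.
#' @param n Sample size; must not exceed the number of alive cells.
#' @return List of [cell_record()]s, named by cell id.
#' @export
sample_cells <- function(tissue, n = tissue$tissue_config$sample_size) {
  stopifnot(inherits(tissue, "mito_tissue"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > length(tissue$cells)) {
    stop(sprintf("'n' must be between 1 and the number of alive cells (%d)",
                 length(tissue$cells)), call. = FALSE)
  }
  tissue$cells[sort(sample.int(length(tissue$cells), n))]
}

## Full recorded genealogy as an ape "phylo": one node per cell ever created,
## each division edge of length 1; tips are cells that never divided.
genealogy_phylo <- function(tissue) {
  id <- tissue$ped_id
  parent <- tissue$ped_parent
  is_tip <- !(id %in% parent)
  tips <- id[is_tip]
  internals <- id[!is_tip]
  ntip <- length(tips)
  if (ntip == 1L && length(internals) == 0L) {
    return(single_tip_tree(paste0("cell", tips), 0))
  }
  # ape convention: tips 1..ntip, root ntip+1
  root <- id[is.na(parent)]
  internals <- c(root, setdiff(internals, root))
  node_of <- integer(max(id))
  node_of[tips] <- seq_len(ntip)
  node_of[internals] <- ntip + seq_along(internals)
  child <- id[!is.na(parent)]
  edge <- cbind(node_of[parent[!is.na(parent)]], node_of[child])
  tr <- structure(list(edge = edge,
                       edge.length = rep(1, nrow(edge)),
                       tip.label = paste0("cell", tips),
                       Nnode = length(internals)),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

single_tip_tree <- function(label, len) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 edge.length = len,
                 tip.label = label,
                 Nnode = 1L),
            class = "phylo")
}

#' Ground-truth lineage tree of a cell sample
#'
#' Restricts the recorded genealogy to the sampled cells: ancestors without
#' sampled descendants are removed, unifurcating internal nodes are collapsed
#' with their branch lengths summed, and the root is the most recent common
#' ancestor of the sample.  Branch lengths count cell divisions, so the
#' cophenetic (path) distance between two tips is the number of divisions
#' separating them through their common ancestor.
#'
#' @param tissue A `"mito_tissue"`.
#' @param sampled List of sampled [cell_record()]s (from [sample_cells()]) or
#'   an integer vector of cell ids.
#' @return A rooted binary `"phylo"` tree with tip labels `"cell<ID>"`.
#' @export
ground_truth_tree <- function(tissue, sampled) {
  ids <- if (is.list(sampled)) {
    vapply(sampled, function(cl) cl$cell_id, integer(1))
  } else {
    as.integer(sampled)
  }
  if (!length(ids)) stop("'sampled' is empty", call. = FALSE)
  unknown <- setdiff(ids, tissue$ped_id)
  if (length(unknown)) {
    stop("unknown cell id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  labs <- paste0("cell", ids)
  if (length(ids) == 1L) {
    ndiv <- tissue$ped_ndiv[match(ids, tissue$ped_id)]
    return(single_tip_tree(labs, ndiv))
  }
  full <- genealogy_phylo(tissue)
  tr <- ape::keep.tip(full, labs)
  tr$root.edge <- NULL
  tr
}

#' Pairwise division distances straight from the pedigree
#'
#' Independent of any tree object: for each pair of cells walks the recorded
#' parent pointers to their most recent common ancestor and sums the division
#' counts on both sides.  Used as an oracle for the pruned ground-truth tree.
#'
#' @param tissue A `"mito_tissue"`.
#' @param ids Integer vector of cell ids.
#' @return Symmetric matrix of division distances, labelled `"cell<ID>"`.
#' @export
pedigree_distances <- function(tissue, ids) {
  ids <- as.integer(ids)
  parent <- tissue$ped_parent[match(tissue$ped_id, tissue$ped_id)]
  names(parent) <- tissue$ped_id
  ndiv <- stats::setNames(tissue$ped_ndiv, tissue$ped_id)
  ancestors <- lapply(ids, function(i) {
    path <- i
    while (!is.na(parent[[as.character(path[length(path)])]])) {
      path <- c(path, parent[[as.character(path[length(path)])]])
    }
    path
  })
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(paste0("cell", ids), paste0("cell", ids)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      common <- intersect(ancestors[[i]], ancestors[[j]])
      mrca <- common[which.max(ndiv[as.character(common)])]
      d[i, j] <- d[j, i] <-
        ndiv[[as.character(ids[i])]] + ndiv[[as.character(ids[j])]] -
        2 * ndiv[[as.character(mrca)]]
    }
  }
  d
}

#' Number of surviving founder lineages
#'
#' Counts the distinct ancestors at a given division depth (default: the
#' first division, i.e. the founder's two daughters and deeper splits are
#' collapsed to their depth-`depth` ancestor) that still have alive
#' descendants.  Under Moran renewal this count decreases as drift fixes the
#' population on fewer and fewer original lineages.
#'
#' @param tissue A `"mito_tissue"`.
#' @param depth Ancestor generation to count at (default 1).
#' @return Integer number of distinct surviving lineages.
#' @export
surviving_lineages <- function(tissue, depth = 1L) {
  parent <- stats::setNames(tissue$ped_parent, tissue$ped_id)
  ndiv <- stats::setNames(tissue$ped_ndiv, tissue$ped_id)
  anc <- vapply(tissue$cells, function(cl) {
    i <- cl$cell_id
    while (ndiv[[as.character(i)]] > depth) i <- parent[[as.character(i)]]
    i
  }, integer(1))
  length(unique(anc))
}
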