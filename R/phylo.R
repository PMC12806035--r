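## Distance computation from VAF profiles, classical neighbor joining,
## cophenetic distances, and canonical Newick I/O.  Trees are ape "phylo"
## objects throughout; reconstructed trees are unrooted (basal
## trifurcation), truth trees rooted at the sample MRCA.  All truth/recon
## comparisons use path distances, which are rooting-invariant.

#' Pairwise distances between cells from their VAF profiles
#'
#' Treats each cell's row of the VAF matrix as a feature vector.
#' `"euclidean"` (the default) and `"manhattan"` act on the frequencies
#' directly; `"jaccard"` first binarises at VAF > 0 and uses the Jaccard
#' distance on variant presence.
#'
#' @param matrix Numeric VAF matrix, cells in rows.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"jaccard"`.
#' @return Symmetric distance matrix with the cell labels.  When the matrix
#'   has no variants the result is all zeros with attribute
#'   `degenerate = TRUE` and a warning.
#' @export
vaf_dist <- function(matrix, metric = c("euclidean", "manhattan", "jaccard")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 2L) stop("need at least 2 cells", call. = FALSE)
  if (ncol(matrix) == 0L) {
    warning("VAF matrix has no variants; distances are all zero", call. = FALSE)
    d <- array(0, dim = c(nrow(matrix), nrow(matrix)),
               dimnames = list(rownames(matrix), rownames(matrix)))
    attr(d, "degenerate") <- TRUE
    return(d)
  }
  d <- switch(metric,
    euclidean = stats::dist(matrix, method = "euclidean"),
    manhattan = stats::dist(matrix, method = "manhattan"),
    jaccard   = stats::dist(matrix > 0, method = "binary"))
  d <- as.matrix(d)
  d[!is.finite(d)] <- 0   # binary distance of two all-zero profiles
  d
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree reconstruction
#'
#' Classical agglomerative neighbor joining: at each step the pair `(i, j)`
#' minimising `Q(i, j) = (m - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)` is
#' joined, with the standard branch-length and distance-update formulas.
#' Negative branch lengths are clamped to 0 as each join is made.  Ties are
#' broken deterministically by the smallest label pair (labels are sorted
#' internally, so the input row order is irrelevant).  NJ is consistent:
#' additive distance matrices are recovered exactly.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal and
#'   unique row labels (or an object coercible via `as.matrix`, e.g. `dist`).
#' @return An unrooted binary `"phylo"` tree (2 tips: the trivial one-edge
#'   tree, split evenly).
#' @export
#' @examples
#' d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(d)
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric",
                                       call. = FALSE)
  if (any(d < 0)) stop("distance matrix must be non-negative", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero",
                                      call. = FALSE)
  ord <- order(rownames(d))
  D <- d[ord, ord, drop = FALSE]
  sub <- rownames(D)           # newick fragment per active node
  if (n == 2L) {
    txt <- paste0("(", sub[1L], ":", fmt_len(D[1, 2] / 2),
                  ",", sub[2L], ":", fmt_len(D[1, 2] / 2), ");")
    return(ape::read.tree(text = txt))
  }
  while (nrow(D) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    newd <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    news <- paste0("(", sub[i], ":", fmt_len(li), ",", sub[j], ":", fmt_len(lj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    sub <- c(sub[keep], news)
  }
  l1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  l2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  l3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  txt <- paste0("(", sub[1L], ":", fmt_len(l1),
                ",", sub[2L], ":", fmt_len(l2),
                ",", sub[3L], ":", fmt_len(l3), ");")
  ape::read.tree(text = txt)
}

#' Cophenetic (path) distances between the tips of a tree
#'
#' Sum of branch lengths along the tip-to-tip path; invariant to rooting.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @return Symmetric matrix of path distances labelled by tip.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 1L) {
    return(matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  ape::cophenetic.phylo(tree)
}

#' Read and write Newick trees in a canonical form
#'
#' `read_newick()` parses a Newick string (or a file containing one) after a
#' structural pre-check that reports the character position of unbalanced
#' parentheses or a missing terminal semicolon.  `write_newick()` emits a
#' canonical form in which every node's children are ordered by their
#' smallest descendant tip label, so equal trees serialise identically and
#' `write(read(x))` is the identity on canonical strings.
#'
#' @param x A Newick string or the path of a file holding one.
#' @return `read_newick()`: a `"phylo"` tree.  `write_newick()`: the Newick
#'   string, invisibly when written to a file.
#' @export
read_newick <- function(x) {
  if (length(x) == 1L && !grepl("(", x, fixed = TRUE)) {
    if (!file.exists(x)) stop("newick file not found: ", x, call. = FALSE)
    text <- paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    text <- paste(x, collapse = "")
  }
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("newick parse error: unbalanced ')' at position %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("newick parse error: %d unclosed '(' at position %d",
                 depth, length(chars)), call. = FALSE)
  }
  if (!endsWith(text, ";")) {
    stop(sprintf("newick parse error: missing ';' at position %d", nchar(text)),
         call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("newick parse error: invalid tree text", call. = FALSE)
  }
  tr
}

#' @rdname read_newick
#' @param tree A `"phylo"` tree.
#' @param file Optional path; when given the string is written there.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  if (ntip == 1L) {
    txt <- paste0("(", tree$tip.label,
                  if (has_len) paste0(":", fmt_len(tree$edge.length[1L])),
                  ");")
  } else {
    kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
    rec <- function(node) {
      if (node <= ntip) {
        return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
      }
      rows <- kids[[as.character(node)]]
      parts <- lapply(tree$edge[rows, 2L], rec)
      mins <- vapply(parts, `[[`, "", "min")
      o <- order(mins)
      strs <- vapply(seq_along(rows), function(ii) {
        paste0(parts[[o[ii]]]$str,
               if (has_len) paste0(":", fmt_len(tree$edge.length[rows[o[ii]]])))
      }, "")
      list(str = paste0("(", paste(strs, collapse = ","), ")"),
           min = min(mins))
    }
    txt <- paste0(rec(ntip + 1L)$str, ";")
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
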