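## Alignment-distance matrices and neighbour-joining trees.

#' All-vs-all alignment distance matrix
#'
#' Globally aligns every pair of sequences once and records
#' `d = 1 - pct_identity / 100`, giving a symmetric matrix with zero
#' diagonal suitable for distance-based tree building.
#'
#' @param seqs Named character vector of protein sequences (unique
#'   names, length >= 2).
#' @param ... Passed to [global_align()].
#' @return Symmetric numeric matrix with sequence names as dimnames.
#' @export
distance_matrix <- function(seqs, ...) {
  if (length(seqs) < 2) stop_fmt("need at least 2 sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop_fmt("sequences must have unique non-empty names")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- global_align(seqs[[i]], seqs[[j]], ...)
      d[i, j] <- d[j, i] <- 1 - aln$pct_identity / 100
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining agglomeration (exact on additive
#' matrices).  Negative branch-length estimates, which NJ can produce on
#' non-additive input, are clamped to zero with a warning so the tree
#' stays a valid Newick object.
#'
#' @param dm Symmetric distance matrix with >= 3 labelled taxa.
#' @return Unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) < 3) stop_fmt("need >= 3 taxa")
  if (is.null(rownames(dm))) stop_fmt("distance matrix must be labelled")
  if (max(abs(dm - t(dm))) > 1e-12) stop_fmt("distance matrix not symmetric")
  tree <- ape::nj(dm)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sprintf("%d negative NJ branch length(s) clamped to 0",
                    sum(neg)), call. = FALSE)
    tree$edge.length[neg] <- 0
  }
  tree
}
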