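#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining on a complete distance matrix, with negative
#' branch lengths clamped to zero. On an additive matrix the patristic
#' distances of the output reproduce the input exactly. This is the
#' pipeline's stand-in tree builder; any externally inferred tree (e.g.
#' maximum likelihood) can be supplied as Newick instead.
#'
#' @param d complete distance matrix with `n >= 3` ids.
#' @return Newick string (unrooted tree, branch lengths in the units of `d`).
#' @export
nj_tree <- function(d) {
  d <- dist_matrix(d)
  if (anyNA(d)) stop("distance matrix has missing entries; NJ needs a complete matrix",
                     call. = FALSE)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::write.tree(tr)
}

#' Patristic distances between the tips of a tree
#'
#' The distance between two tips is the sum of the branch lengths on the
#' unique path connecting them.
#'
#' @param tree Newick string, path to a Newick file, or an ape `phylo`.
#' @return distance matrix over the tip labels.
#' @export
patristic_distances <- function(tree) {
  tr <- as_phylo(tree)
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length)) {
    stop("tree must have a branch length on every edge", call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels", call. = FALSE)
  m <- ape::cophenetic.phylo(tr)
  m <- m[tr$tip.label, tr$tip.label]
  dist_matrix(m, ids = tr$tip.label)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1)
  tr <- if (file.exists(tree) && !grepl(";", tree, fixed = TRUE)) {
    ape::read.tree(tree)
  } else {
    ape::read.tree(text = tree)
  }
  if (is.null(tr)) stop("could not parse Newick tree", call. = FALSE)
  tr
}
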