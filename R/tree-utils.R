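#' Read a time-calibrated Newick tree
#'
#' Reads a single rooted Newick tree with branch lengths (interpreted in Myr
#' throughout the package). Trees without branch lengths are rejected since
#' every downstream method needs them; fossil trees are generally
#' non-ultrametric.
#'
#' @param path file path containing one Newick tree.
#' @return an [ape::phylo] object with normalized tip labels.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1]]
  }
  if (is.null(tr)) stop("could not parse a Newick tree from ", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; all comparative methods require them")
  if (anyNA(tr$edge.length))
    stop("tree has NA branch lengths")
  if (anyDuplicated(tr$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr$tip.label <- normalize_labels(tr$tip.label)
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  tr
}

#' Phylogenetic covariance matrix
#'
#' Shared path lengths from the root: `C[i,j]` is the depth of the most
#' recent common ancestor of tips i and j, `C[i,i]` the root-to-tip path
#' length. This is the Brownian-motion trait covariance structure used by
#' every GLS-based method here.
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric positive semi-definite matrix, tip labels as dimnames.
#' @export
vcv_matrix <- function(tree) ape::vcv.phylo(tree)

#' Pagel lambda scaling of a phylogenetic covariance
#'
#' Multiplies off-diagonal (shared-history) entries by `lambda` while
#' preserving the diagonal; `lambda = 0` yields a star phylogeny (no
#' phylogenetic signal), `lambda = 1` leaves the tree untouched.
#'
#' @param C covariance matrix from [vcv_matrix()].
#' @param lambda scalar in `[bounds[1], bounds[2]]`.
#' @param bounds allowed range, default `c(0, 1)`.
#' @return scaled covariance matrix.
#' @export
lambda_transform <- function(C, lambda, bounds = c(0, 1)) {
  if (lambda < bounds[1] || lambda > bounds[2])
    stop("lambda = ", lambda, " outside [", bounds[1], ", ", bounds[2], "]")
  d <- diag(C)
  C2 <- C * lambda
  diag(C2) <- d
  C2
}

#' Prune a tree to a taxon subset
#'
#' Induced subtree on `keep_taxa`; degree-2 internal nodes are collapsed
#' with branch lengths summed.
#'
#' @param tree a `phylo`.
#' @param keep_taxa character vector of >= 3 tip labels to retain.
#' @return pruned `phylo`.
#' @export
prune_tree <- function(tree, keep_taxa) {
  keep_taxa <- normalize_labels(keep_taxa)
  unknown <- setdiff(keep_taxa, tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(keep_taxa) < 3L)
    stop("pruning to fewer than 3 taxa is not supported")
  ape::keep.tip(tree, keep_taxa)
}

#' Replace zero-length branches
#'
#' Branches of length <= 0 (or below numerical floor) are replaced by
#' `epsilon` (default 0.1 Myr), the standard fix before fitting Markov and
#' Gaussian models on calibrated fossil trees.
#'
#' @param tree a `phylo`.
#' @param epsilon replacement length in Myr.
#' @return `phylo` with strictly positive branch lengths.
#' @export
fix_zero_branches <- function(tree, epsilon = 0.1) {
  zero <- tree$edge.length < .Machine$double.eps
  tree$edge.length[zero] <- epsilon
  tree
}

# Depth (distance from root) of every node, tips first then internals,
# in ape node numbering.
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

# For each pair of tips, the node number of their MRCA (ape numbering).
mrca_matrix <- function(tree) {
  m <- ape::mrca(tree)
  m[tree$tip.label, tree$tip.label]
}

# Children edges listed in preorder (root first); returns edge indices.
preorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  match(paste(tr$edge[, 1], tr$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}
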