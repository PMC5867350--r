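#' Read / write newick trees
#'
#' Thin wrappers around ape's newick parser that add the validation this
#' package relies on (unique leaf names, a single root). Internal node
#' labels (written after the closing parenthesis) and branch lengths are
#' preserved.
#'
#' @param path Path to a newick file, or use `text =` for a literal string.
#' @param text Optional newick string instead of a file.
#' @return An ape `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Prune a tree to a set of taxa
#'
#' Leaves outside `keep` are dropped; unary internal nodes are collapsed
#' with their edge lengths summed (ape's pruning semantics).
#'
#' @param tree `phylo` object.
#' @param keep Character vector of leaf names to retain (>= 2).
#' @return Pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, keep)
}

node_heights <- function(tree) {
  # depth of every node from the root, in edge-length units
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Grafen branch lengths with root height 1
#'
#' Assigns each node the height `((d - 1) / (n - 1))^rho` where `d` is its
#' number of descendant leaves and `n` the total leaf count; leaves sit at
#' height 0 and the root at exactly 1, so the output is ultrametric.
#'
#' @param tree `phylo` topology (existing branch lengths are ignored).
#' @param rho Positive exponent (default 1).
#' @return Ultrametric `phylo` with the same topology.
#' @export
grafen_lengths <- function(tree, rho = 1) {
  n <- ape::Ntip(tree)
  if (n < 2L) stop("need at least 2 leaves")
  stopifnot(rho > 0)
  ndesc <- ape::node.depth(tree)   # number of tips below each node
  h <- ifelse(ndesc == 1L, 0, ((ndesc - 1) / (n - 1))^rho)
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  tree
}

#' Test whether a tree is ultrametric
#'
#' @param tree `phylo` with branch lengths on every edge.
#' @param tolerance Maximum allowed spread of root-to-leaf path lengths.
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tolerance = 1e-8) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depth)) <= tolerance
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage hierarchical clustering returning a rooted ultrametric
#' dendrogram in which two clusters merging at distance `d` join at height
#' `d / 2` (leaves at height 0).
#'
#' The default mode clusters the supplied divergence matrix directly. Mode
#' `"euclidean"` first treats each taxon's row of the matrix as a point and
#' clusters the Euclidean distances between rows — the convention of
#' distance-matrix front-ends that re-embed their input.
#'
#' @param m Symmetric non-negative matrix with taxon dimnames.
#' @param mode `"direct"` (default) or `"euclidean"`.
#' @return Ultrametric `phylo` dendrogram.
#' @examples
#' m <- matrix(c(0, 2, 8, 2, 0, 6, 8, 6, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma_tree(m)  # A,B join at height 1; C at 3.5
#' @export
upgma_tree <- function(m, mode = c("direct", "euclidean")) {
  mode <- match.arg(mode)
  if (!isSymmetric(unname(m))) stop("matrix must be symmetric")
  if (any(m < 0)) stop("matrix entries must be non-negative")
  if (nrow(m) < 2L) stop("need at least 2 taxa")
  # alphabetical taxon order makes tie-breaking deterministic
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  d <- if (mode == "direct") stats::as.dist(m) else stats::dist(m)
  ape::as.phylo(stats::hclust(d, method = "average"))
}
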