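#' Read a dated tree from Newick
#'
#' Expects a single rooted, binary tree with branch lengths (Myr). Node
#' ages are derived assuming ultrametry; a tree that is non-ultrametric
#' beyond `tol` triggers a warning and ages are taken from the maximum
#' root-to-tip path.
#'
#' @param path Newick file path.
#' @param tol ultrametricity tolerance (relative, on root-to-tip depths).
#' @return an `ape::phylo` with internal `node.label`s (filled as
#'   `n<ape node number>` when absent).
#' @export
read_dated_tree <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) stop_invalid("'%s': expected a single tree", path)
  validate_dated_tree(tree, tol = tol)
}

#' @rdname read_dated_tree
#' @param tree an `ape::phylo`.
#' @export
validate_dated_tree <- function(tree, tol = 1e-6) {
  if (is.null(tree$edge.length)) stop_invalid("tree has no branch lengths")
  if (is.null(tree$tip.label) || anyNA(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop_invalid("tree has unlabeled tips")
  }
  if (anyDuplicated(tree$tip.label)) stop_invalid("tip labels are not unique")
  if (!ape::is.binary(tree)) stop_invalid("tree must be binary")
  if (!ape::is.rooted(tree)) stop_invalid("tree must be rooted")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > tol * max(depths)) {
    warning("tree is not ultrametric; node ages taken from the maximum root-to-tip path")
  }
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label))) {
    tree$node.label <- paste0("n", ape::Ntip(tree) + seq_len(tree$Nnode))
  }
  tree
}

#' @rdname read_dated_tree
#' @export
write_dated_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Node ages of an ultrametric tree
#'
#' @param tree an `ape::phylo` with branch lengths in Myr.
#' @return numeric vector over all nodes (ape numbering: tips first), ages
#'   in Myr before present; tips of an ultrametric tree are at 0.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Labels for every node of a tree
#'
#' Tips keep their tip labels; internal nodes use `node.label` (filled by
#' [validate_dated_tree()] as `n<number>`).
#'
#' @param tree an `ape::phylo`.
#' @return character vector indexed by ape node number.
#' @export
node_labels <- function(tree) {
  nl <- tree$node.label
  if (is.null(nl)) nl <- paste0("n", ape::Ntip(tree) + seq_len(tree$Nnode))
  c(tree$tip.label, nl)
}

## internal node numbers in stable postorder (children before parents)
internal_postorder <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1])
}

## edge table with labels, one row per branch
branch_table <- function(tree) {
  labs <- node_labels(tree)
  data.frame(
    parent = labs[tree$edge[, 1]],
    child = labs[tree$edge[, 2]],
    parent_id = tree$edge[, 1],
    child_id = tree$edge[, 2],
    length = tree$edge.length,
    is_terminal = tree$edge[, 2] <= ape::Ntip(tree),
    stringsAsFactors = FALSE
  )
}
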