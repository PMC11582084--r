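# Tree plumbing: Newick I/O, name normalisation, pruning, BM covariance.
# All heavy lifting delegated to ape; this layer adds the contracts the
# comparative machinery relies on (duplicate-name checks, deterministic
# polytomy resolution, ultrametricity tolerance).

#' Read a rooted phylogeny from Newick
#'
#' @param text A Newick string, or NULL to read from \code{file}.
#' @param file Path to a Newick file (used when \code{text} is NULL).
#' @return An \code{ape} \code{phylo} object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text)
        else if (!is.null(file)) ape::read.tree(file = file)
        else stop("supply either text or file")
  if (is.null(tr)) stop("failed to parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a phylogeny as Newick
#'
#' @param tree A \code{phylo} object.
#' @param file Optional path; if NULL the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(file) }
}

#' Normalise taxon names for matching
#'
#' Trims whitespace and maps underscores to spaces, the two Newick dialect
#' differences that break tip-to-table joins.
#'
#' @param x Character vector of names.
#' @export
normalize_taxon_names <- function(x) {
  trimws(gsub("_", " ", x, fixed = TRUE))
}

#' Test ultrametricity within a relative tolerance
#'
#' @param tree A \code{phylo} object.
#' @param tol Relative tolerance on root-to-tip path lengths (default 1e-6).
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  h <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(h)) <= tol * max(h)
}

# root-to-node path lengths for all nodes (tips first, then internals)
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Resolve polytomies deterministically
#'
#' Multifurcations are resolved to a binary tree with zero-length branches;
#' children are taken in alphabetical order of their smallest descendant tip
#' so the resolution is reproducible.
#'
#' @param tree A \code{phylo} object.
#' @export
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  ape::multi2di(tree, random = FALSE)
}

#' Prune a tree to a taxon set
#'
#' Returns the induced subtree on \code{keep}: suppressed degree-2 nodes have
#' their branch lengths summed, so ultrametricity is preserved. Names are
#' matched after [normalize_taxon_names()].
#'
#' @param tree A \code{phylo} object.
#' @param keep Character vector of tip names to retain (at least 2).
#' @export
prune_to_taxa <- function(tree, keep) {
  tips_norm <- normalize_taxon_names(tree$tip.label)
  keep_norm <- unique(normalize_taxon_names(keep))
  missing <- setdiff(keep_norm, tips_norm)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(keep_norm) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, tree$tip.label[tips_norm %in% keep_norm])
}

#' Brownian-motion covariance of a tree
#'
#' \code{C[i, j]} is the shared root-to-MRCA path length of tips i and j;
#' the diagonal holds root-to-tip depths.
#'
#' @param tree A rooted \code{phylo} object with branch lengths.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
tree_vcv <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Tree height (maximum root-to-tip depth)
#' @param tree A \code{phylo} object.
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Write a Newick tree annotated with per-node summaries
#'
#' Attaches one label per internal node (e.g. maximum-likelihood ancestral
#' states) as Newick node labels and writes or returns the tree.
#'
#' @param tree A \code{phylo} object.
#' @param node_labels Character vector, one entry per internal node in ape
#'   numbering order.
#' @param file Optional path; if NULL the Newick string is returned.
#' @export
write_annotated_newick <- function(tree, node_labels, file = NULL) {
  if (length(node_labels) != tree$Nnode)
    stop("need one label per internal node (", tree$Nnode, ")")
  tree$node.label <- as.character(node_labels)
  write_newick(tree, file)
}
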