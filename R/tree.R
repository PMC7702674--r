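#' Parse a Newick string into a rooted tree
#'
#' Thin wrapper over ape's Newick reader with the validation this package
#' relies on: single string, unique tip labels, branch lengths present and
#' non-negative. Quoted labels are supported.
#'
#' @param text Newick string (or a vector of lines that will be pasted).
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  text <- paste(text, collapse = "")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: unreadable string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Serialize a tree to Newick
#' @param tree an [ape::phylo] tree.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 12L) {
  ape::write.tree(tree, digits = digits)
}

#' Prune a tree to a set of tips
#'
#' Drops all other tips, suppresses the resulting unary nodes and sums the
#' fused branch lengths, so patristic distances among kept tips are
#' unchanged.
#'
#' @param tree an [ape::phylo] tree.
#' @param keep_taxa character vector of tip labels to keep.
#' @return the pruned tree.
#' @export
prune_tree <- function(tree, keep_taxa) {
  unknown <- setdiff(keep_taxa, tree$tip.label)
  if (length(unknown))
    stop("taxa not on the tree: ", paste(unknown, collapse = ", "))
  ape::keep.tip(tree, keep_taxa)
}

# ---- internal tree bookkeeping ----------------------------------------------

.n_tips <- function(tree) length(tree$tip.label)

# depths (distance from root) for every node, index = node id
.node_depths <- function(tree) {
  n <- .n_tips(tree)
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  ord <- .preorder_edges(tree)
  for (e in ord)
    depth[tree$edge[e, 2L]] <- depth[tree$edge[e, 1L]] + tree$edge.length[e]
  depth
}

# edge indices in preorder (parent before child)
.preorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
}

# edge indices in postorder (children before parent)
.postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder", index.only = TRUE)
}

# list: path of node ids from root to each node (inclusive)
.root_paths <- function(tree) {
  n <- .n_tips(tree)
  nn <- n + tree$Nnode
  parent <- integer(nn)
  for (e in seq_len(nrow(tree$edge)))
    parent[tree$edge[e, 2L]] <- tree$edge[e, 1L]
  root <- n + 1L
  lapply(seq_len(nn), function(v) {
    p <- v
    while (v != root) {
      v <- parent[v]
      p <- c(v, p)
    }
    p
  })
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the length of the shared root-to-MRCA path of tips i and
#' j; the diagonal holds root-to-tip depths. Works for non-ultrametric
#' (fossil-bearing) trees.
#'
#' @param tree an [ape::phylo] tree.
#' @return a symmetric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  n <- .n_tips(tree)
  depth <- .node_depths(tree)
  paths <- .root_paths(tree)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    V[i, i] <- depth[i]
    if (i < n) for (j in (i + 1L):n) {
      pi <- paths[[i]]; pj <- paths[[j]]
      k <- min(length(pi), length(pj))
      shared <- pi[seq_len(k)] == pj[seq_len(k)]
      mrca <- pi[max(which(shared))]
      V[i, j] <- V[j, i] <- depth[mrca]
    }
  }
  V
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal entries by lambda and leaves the diagonal
#' untouched — the general form, exact also for non-ultrametric trees.
#'
#' @param vcv covariance matrix from [phylo_vcv()].
#' @param lambda signal parameter in \[0, 1\].
#' @return the transformed matrix.
#' @export
lambda_transform <- function(vcv, lambda) {
  if (lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]; clamp before transforming")
  V <- vcv * lambda
  diag(V) <- diag(vcv)
  V
}
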