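# Fitch parsimony and the Retention Index.

#' Fitch parsimony step count
#'
#' Number of state changes required by the most parsimonious assignment of
#' a discrete character on a rooted tree (Fitch's set algorithm;
#' multifurcations are resolved arbitrarily with zero-length branches,
#' which leaves the Fitch count of a hard polytomy unchanged for the
#' intersection/union recursion applied pairwise).
#'
#' @param tree an [ape::phylo] tree.
#' @param states character/factor vector named by tip or in `tip.label`
#'   order.
#' @return integer number of steps.
#' @export
fitch_steps <- function(tree, states) {
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree)
  ts <- .tip_state_index(tree, states)
  n <- .n_tips(tree)
  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- ts$idx[i]
  steps <- 0L
  for (e in .postorder_edges(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (is.null(sets[[p]])) {
      sets[[p]] <- sets[[ch]]
    } else {
      inter <- intersect(sets[[p]], sets[[ch]])
      if (length(inter)) {
        sets[[p]] <- inter
      } else {
        sets[[p]] <- union(sets[[p]], sets[[ch]])
        steps <- steps + 1L
      }
    }
  }
  steps
}

#' Retention Index of a discrete character on a tree
#'
#' RI = (g - s) / (g - m), where s is the Fitch parsimony step count, m =
#' k - 1 the minimum possible steps for k states, and g = n_tips - (largest
#' state frequency) the maximum steps on any tree. RI = 1 means the
#' character clusters perfectly on the tree; 0 means maximal homoplasy.
#'
#' @inheritParams fitch_steps
#' @return RI in \[0, 1\].
#' @export
retention_index <- function(tree, states) {
  ts <- .tip_state_index(tree, states)
  k <- length(ts$states)
  if (k < 2L) stop("invariant character: RI undefined")
  s <- fitch_steps(tree, states)
  m <- k - 1L
  g <- length(ts$idx) - max(tabulate(ts$idx, k))
  if (g == m) stop("g equals the minimum step count: RI undefined")
  (g - s) / (g - m)
}
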