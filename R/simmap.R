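# Stochastic character mapping: joint node-state sampling by pruning +
# traceback, branch histories conditioned on endpoints by uniformization.

# sample a full history on one branch: start state a, end state b (1..k),
# duration t, under Q. Returns named numeric vector of segment durations,
# names = state indices (phytools $maps convention). Uses uniformization:
# jump chain R = I + Q/Omega, number of jumps drawn conditional on the
# endpoints, virtual (self) jumps collapsed.
.branch_history <- function(Q, a, b, t, Pab = NULL, max_jumps = 1000L) {
  k <- nrow(Q)
  if (t <= 0 || (a == b && all(abs(Q[a, ]) < 1e-14))) {
    out <- t; names(out) <- a
    return(out)
  }
  Omega <- max(-diag(Q))
  if (Omega <= 0) { out <- t; names(out) <- a; return(out) }
  R <- diag(k) + Q / Omega
  if (is.null(Pab)) Pab <- mk_transition_prob(Q, t)[a, b]
  if (Pab <= 0) stop("endpoint pair has zero transition probability")
  # jump-count distribution: P(N = n) ~ dpois(n, Omega t) * R^n[a, b]
  nmax <- max(20L, stats::qpois(1 - 1e-12, Omega * t) + 10L)
  nmax <- min(nmax, max_jumps)
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1L]] <- diag(k)
  for (i in seq_len(nmax)) Rpow[[i + 1L]] <- Rpow[[i]] %*% R
  w <- vapply(0:nmax, function(n) {
    stats::dpois(n, Omega * t) * Rpow[[n + 1L]][a, b]
  }, numeric(1))
  if (sum(w) <= 0) stop("uniformization failed: zero jump-count mass")
  N <- sample.int(nmax + 1L, 1L, prob = w) - 1L
  states <- a
  if (N > 0) {
    s <- a
    for (i in seq_len(N)) {
      # backward-sampled chain conditioned on hitting b at step N
      pr <- R[s, ] * Rpow[[N - i + 1L]][, b]
      s <- sample.int(k, 1L, prob = pr)
      states <- c(states, s)
    }
  }
  times <- c(0, sort(stats::runif(N, 0, t)), t)
  dur <- diff(times)
  # collapse virtual jumps (adjacent equal states)
  keep <- c(TRUE, states[-1L] != states[-length(states)])
  seg_id <- cumsum(keep)
  out <- as.numeric(tapply(dur, seg_id, sum))
  names(out) <- states[keep]
  out
}

#' Sample stochastic character maps
#'
#' Draws joint ancestral state histories conditional on the observed tip
#' states and a fitted Mk model: conditional likelihoods by pruning, joint
#' node states by stochastic traceback from the root, then full branch
#' histories conditioned on their endpoint states via uniformization.
#' Segment durations sum to branch lengths exactly.
#'
#' @param tree an [ape::phylo] tree.
#' @param tip_states observed states (named by tip or in `tip.label` order).
#' @param model an `mk_model` from [fit_mk()] (fitted on demand if `NULL`).
#' @param n_maps number of maps to draw.
#' @param seed optional RNG seed.
#' @param root_prior `"stationary"` (default) or `"uniform"`; overrides the
#'   prior stored in `model`.
#' @return object of class `simmap_set`: list with `tree`, `states`, and
#'   `maps`, a list of length `n_maps`; each map is a list over edges (rows
#'   of `tree$edge`) of named duration vectors (names = state labels).
#' @export
simmap_sample <- function(tree, tip_states, model = NULL, n_maps = 100L,
                          seed = NULL, root_prior = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- fit_mk(tree, tip_states)
  ts <- .tip_state_index(tree, tip_states, model$states)
  Q <- unname(model$Q)
  k <- nrow(Q)
  n <- .n_tips(tree)
  pr <- if (is.null(root_prior)) model$pi
        else if (root_prior == "uniform") rep(1 / k, k)
        else .mk_stationary(Q)
  part <- .mk_partials(tree, ts$idx, Q)
  L <- part$L; P <- part$P
  pre <- .preorder_edges(tree)
  root <- n + 1L
  edges <- tree$edge
  lens <- tree$edge.length
  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    state <- integer(n + tree$Nnode)
    state[root] <- sample.int(k, 1L, prob = pr * L[root, ])
    hist <- vector("list", nrow(edges))
    for (e in pre) {
      p <- edges[e, 1L]; ch <- edges[e, 2L]
      sp <- state[p]
      pvec <- P[[e]][sp, ] * L[ch, ]
      sc <- sample.int(k, 1L, prob = pvec)
      state[ch] <- sc
      seg <- .branch_history(Q, sp, sc, lens[e], Pab = P[[e]][sp, sc])
      names(seg) <- model$states[as.integer(names(seg))]
      hist[[e]] <- seg
    }
    maps[[m]] <- hist
  }
  structure(list(tree = tree, states = model$states, maps = maps,
                 tip_states = model$states[ts$idx]),
            class = "simmap_set")
}

#' Posterior state profile along every branch
#'
#' For a regular grid of points along each branch, the fraction of sampled
#' maps in which the lineage is in the focal state; also reports
#' "acquisition" branches, where the posterior crosses 50% from the
#' parent-side to the child-side end of the branch.
#'
#' @param maps a `simmap_set` from [simmap_sample()].
#' @param focal_state state label whose posterior is profiled.
#' @param n_grid grid points per branch.
#' @return list with `profile` (edges x n_grid matrix of fractions),
#'   `node_posterior` (named vector over all nodes), and `acquisitions`
#'   (child node ids of branches crossing 50% upward).
#' @export
branch_posterior <- function(maps, focal_state, n_grid = 20L) {
  tree <- maps$tree
  if (!focal_state %in% maps$states) stop("unknown focal state")
  ne <- nrow(tree$edge)
  lens <- tree$edge.length
  acc <- matrix(0, ne, n_grid)
  n <- .n_tips(tree)
  node_acc <- numeric(n + tree$Nnode)
  frac <- seq(0, 1, length.out = n_grid)
  for (h in maps$maps) {
    for (e in seq_len(ne)) {
      seg <- h[[e]]
      bounds <- cumsum(seg)
      tgrid <- frac * lens[e]
      idx <- findInterval(tgrid, bounds, left.open = TRUE) + 1L
      idx[idx > length(seg)] <- length(seg)
      st <- names(seg)[idx]
      acc[e, ] <- acc[e, ] + (st == focal_state)
      node_acc[tree$edge[e, 2L]] <- node_acc[tree$edge[e, 2L]] +
        (names(seg)[length(seg)] == focal_state)
      if (tree$edge[e, 1L] == n + 1L)
        node_acc[n + 1L] <- node_acc[n + 1L] +
          (names(seg)[1L] == focal_state) / 2  # root seen from both children
    }
  }
  nm <- length(maps$maps)
  profile <- acc / nm
  node_post <- node_acc / nm
  start <- profile[, 1L]
  end <- profile[, n_grid]
  acq <- tree$edge[start < 0.5 & end >= 0.5, 2L]
  list(profile = profile, node_posterior = node_post, acquisitions = acq)
}

#' Derive focal (convergently acquiring) clades from a mapped history
#'
#' Groups focal-state tips by their nearest ancestral acquisition branch
#' (posterior crossing 50%), mirroring the clustering of each converging
#' fully fossorial clade for the convergence indices. Tips whose history
#' contains no acquisition branch (focal since the root) form one group.
#'
#' @param maps a `simmap_set`.
#' @param focal_state the state defining the clades.
#' @param posterior optional precomputed [branch_posterior()] result.
#' @return named list of character vectors of tip labels (disjoint clades).
#' @export
derive_focal_clades <- function(maps, focal_state, posterior = NULL) {
  tree <- maps$tree
  if (is.null(posterior)) posterior <- branch_posterior(maps, focal_state)
  acq <- posterior$acquisitions
  n <- .n_tips(tree)
  paths <- .root_paths(tree)
  focal_tips <- which(maps$tip_states == focal_state)
  if (!length(focal_tips)) return(list())
  grp <- vapply(focal_tips, function(tip) {
    anc <- rev(paths[[tip]])          # tip back to root
    hit <- anc[anc %in% acq]
    if (length(hit)) as.character(hit[1L]) else "root"
  }, character(1))
  split(tree$tip.label[focal_tips], grp)
}

#' Serialize a simmap history to SIMMAP-annotated Newick
#'
#' @param maps a `simmap_set`.
#' @param index which map to serialize.
#' @return a Newick string with `{state,time:...}` branch annotations.
#' @export
write_simmap <- function(maps, index = 1L) {
  tree <- maps$tree
  h <- maps$maps[[index]]
  n <- .n_tips(tree)
  edge_of <- integer(n + tree$Nnode)
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  lab <- function(v) {
    if (v <= n) tree$tip.label[v] else ""
  }
  ann <- function(v) {
    seg <- h[[edge_of[v]]]
    paste0("{", paste(sprintf("%s,%.8g", names(seg), seg), collapse = ":"), "}")
  }
  rec <- function(v) {
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    body <- if (length(kids))
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    else ""
    node <- paste0(body, lab(v))
    if (v == n + 1L) node else paste0(node, ":", ann(v))
  }
  paste0(rec(n + 1L), ";")
}
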