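# Independent brute-force oracles and small fixture builders used across
# the test files. Oracles deliberately take different computational routes
# than the package implementations they check.

# rasterized disc mask
disc_mask <- function(radius_px, pad = 2L) {
  n <- 2L * (radius_px + pad) + 1L
  ctr <- radius_px + pad + 1L
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix(as.integer((g$row - ctr)^2 + (g$col - ctr)^2 <= radius_px^2), n, n)
}

bar_mask <- function(height_px, length_px, pad = 2L) {
  m <- matrix(0L, height_px + 2L * pad, length_px + 2L * pad)
  m[(pad + 1L):(pad + height_px), (pad + 1L):(pad + length_px)] <- 1L
  m
}

# per-pixel brute-force local thickness: for every foreground pixel p, the
# max over centres q of 2*r(q) with |p-q| < r(q), r = exact EDT by direct
# minimization over background pixels
oracle_local_thickness <- function(m) {
  fg <- which(m == 1L, arr.ind = TRUE)
  bg <- which(m == 0L, arr.ind = TRUE)
  # treat outside the raster as background at the border ring
  r <- apply(fg, 1L, function(q) {
    db <- sqrt(min((bg[, 1L] - q[1L])^2 + (bg[, 2L] - q[2L])^2))
    db
  })
  th <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    p <- fg[i, ]
    d2 <- (fg[, 1L] - p[1L])^2 + (fg[, 2L] - p[2L])^2
    cover <- d2 < r^2
    th[i] <- if (any(cover)) 2 * max(r[cover]) else 0
  }
  out <- matrix(0, nrow(m), ncol(m))
  out[fg] <- th
  out
}

# BM covariance via the patristic-distance identity
# V[i, j] = (depth_i + depth_j - d_ij) / 2
oracle_vcv <- function(tree) {
  dep <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  (outer(dep, dep, "+") - D) / 2
}

# brute-force Fitch: minimum changes over all internal-node labelings
oracle_fitch <- function(tree, states_idx, k) {
  n <- length(tree$tip.label)
  nint <- tree$Nnode
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- c(states_idx, combos[r, ])
    ch <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
    best <- min(best, ch)
  }
  best
}

# brute-force Mk likelihood: sum over all internal-node state assignments
oracle_mk_lik <- function(tree, states_idx, Q, prior) {
  n <- length(tree$tip.label)
  nint <- tree$Nnode
  k <- nrow(Q)
  P <- lapply(tree$edge.length, function(t) skullconv::mk_transition_prob(Q, t))
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    lab <- c(states_idx, combos[r, ])
    pr <- prior[lab[n + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][lab[tree$edge[e, 1L]], lab[tree$edge[e, 2L]]]
    tot <- tot + pr
  }
  tot
}

# closed-form GLS ancestral states through the full node covariance matrix
oracle_asr <- function(tree, y) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  dep <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  Vfull <- matrix(dep[M], nn, nn)
  Vt <- Vfull[seq_len(n), seq_len(n)]
  Vti <- solve(Vt)
  one <- rep(1, n)
  mu <- drop((t(one) %*% Vti %*% y) / (t(one) %*% Vti %*% one))
  nodes <- (n + 1L):nn
  drop(mu + Vfull[nodes, seq_len(n)] %*% Vti %*% (y - mu))
}

# exhaustive C1: loops over between-clade pairs, explicit ancestor walks
oracle_c1 <- function(tree, y, focal, anc_fun = oracle_asr) {
  anc <- anc_fun(tree, y)
  vals <- c(y, anc)
  n <- length(tree$tip.label)
  tip_id <- function(lbl) match(lbl, tree$tip.label)
  pairs <- list()
  for (a in seq_along(focal)) for (b in seq_along(focal)) if (a < b)
    for (ta in focal[[a]]) for (tb in focal[[b]])
      pairs[[length(pairs) + 1L]] <- c(tip_id(ta), tip_id(tb))
  per <- vapply(pairs, function(pr) {
    m <- ape::getMRCA(tree, pr)
    path_to <- function(tip) {
      p <- tip
      v <- tip
      while (v != m) {
        v <- tree$edge[tree$edge[, 2L] == v, 1L]
        p <- c(p, v)
      }
      p
    }
    A <- vals[path_to(pr[1L])]
    B <- vals[path_to(pr[2L])]
    dmax <- max(abs(outer(A, B, "-")))
    1 - abs(y[pr[1L]] - y[pr[2L]]) / dmax
  }, numeric(1))
  mean(per)
}

# exhaustive univariate C5: explicit per-edge interval walk
oracle_c5 <- function(tree, y, focal_tips, anc_fun = oracle_asr) {
  anc <- anc_fun(tree, y)
  vals <- c(y, anc)
  n <- length(tree$tip.label)
  idx <- match(focal_tips, tree$tip.label)
  lo <- min(y[idx]); hi <- max(y[idx])
  cnt <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    pv <- vals[tree$edge[e, 1L]]; cv <- vals[tree$edge[e, 2L]]
    inside <- function(x) x >= lo && x <= hi
    if (!inside(pv)) {
      crosses <- inside(cv) || (min(pv, cv) <= hi && max(pv, cv) >= lo)
      if (crosses) cnt <- cnt + 1L
    }
  }
  if (vals[n + 1L] >= lo && vals[n + 1L] <= hi) cnt <- cnt + 1L
  cnt
}

random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n)
}
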