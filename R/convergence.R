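# Univariate C1 and univariate/bivariate C5 convergence indices with a
# Brownian-motion simulation null.

# validate focal clades; return list(tips = integer indices per clade)
.focal_prep <- function(tree, focal, min_clades = 1L) {
  if (!is.list(focal)) focal <- list(focal)
  if (length(focal) < min_clades)
    stop("need at least ", min_clades, " focal clade(s)")
  idx <- lapply(focal, function(cl) {
    i <- match(cl, tree$tip.label)
    if (anyNA(i)) stop("focal tips not on tree: ",
                       paste(cl[is.na(i)], collapse = ", "))
    i
  })
  all_i <- unlist(idx)
  if (anyDuplicated(all_i)) stop("focal clades must be disjoint")
  idx
}

# Precompute, per between-clade tip pair, the tip indices and the number of
# path steps from each tip back to (and including) the pair's MRCA; plus
# per-tip root paths in tip-to-root order.
.c1_prep <- function(tree, focal) {
  idx <- .focal_prep(tree, focal, min_clades = 2L)
  paths <- .root_paths(tree)
  tips <- unlist(idx)
  clade <- rep(seq_along(idx), lengths(idx))
  pairs <- utils::combn(seq_along(tips), 2L)
  keep <- clade[pairs[1L, ]] != clade[pairs[2L, ]]
  pairs <- pairs[, keep, drop = FALSE]
  tip_paths <- lapply(tips, function(t) rev(paths[[t]]))  # tip -> root
  np <- ncol(pairs)
  ki <- integer(np); kj <- integer(np)
  for (m in seq_len(np)) {
    a <- tips[pairs[1L, m]]; b <- tips[pairs[2L, m]]
    pa <- paths[[a]]; pb <- paths[[b]]
    L <- min(length(pa), length(pb))
    shared <- which(pa[seq_len(L)] == pb[seq_len(L)])
    Ls <- max(shared)
    ki[m] <- length(pa) - Ls + 1L   # steps tip..MRCA inclusive
    kj[m] <- length(pb) - Ls + 1L
  }
  list(tips = tips, tip_paths = tip_paths, pairs = pairs, ki = ki, kj = kj)
}

# running max/min along each focal tip's path, for a node-value matrix
# (all nodes x n_sims); returns per focal tip matrices (path length x sims)
.path_cummax <- function(prep, vals) {
  lapply(prep$tip_paths, function(pp) {
    n <- length(pp); S <- ncol(vals)
    mx <- matrix(0, n, S); mn <- matrix(0, n, S)
    cur_mx <- vals[pp[1L], ]; cur_mn <- cur_mx
    mx[1L, ] <- cur_mx; mn[1L, ] <- cur_mn
    if (n > 1L) for (i in 2:n) {
      v <- vals[pp[i], ]
      cur_mx <- pmax(cur_mx, v); cur_mn <- pmin(cur_mn, v)
      mx[i, ] <- cur_mx; mn[i, ] <- cur_mn
    }
    list(mx = mx, mn = mn)
  })
}

# C1 per simulation column; vals = (n_tips + Nnode) x S matrix of tip values
# stacked over reconstructed node values. Returns list(overall = S-vector,
# per_pair = (n_pairs x S)).
.c1_stat <- function(prep, vals) {
  cm <- .path_cummax(prep, vals)
  np <- ncol(prep$pairs); S <- ncol(vals)
  per <- matrix(NA_real_, np, S)
  for (m in seq_len(np)) {
    i <- prep$pairs[1L, m]; j <- prep$pairs[2L, m]
    Amx <- cm[[i]]$mx[prep$ki[m], ]; Amn <- cm[[i]]$mn[prep$ki[m], ]
    Bmx <- cm[[j]]$mx[prep$kj[m], ]; Bmn <- cm[[j]]$mn[prep$kj[m], ]
    dmax <- pmax(Amx - Bmn, Bmx - Amn)
    dtip <- abs(vals[prep$tips[i], ] - vals[prep$tips[j], ])
    per[m, ] <- 1 - dtip / dmax
  }
  list(overall = colMeans(per), per_pair = per)
}

# node-value matrix for observed or simulated tip data
.node_values <- function(tree, tips_mat, operator) {
  rbind(tips_mat, operator %*% tips_mat)
}

#' Univariate C1 convergence index
#'
#' For every between-clade pair of focal tips, C1 = 1 - D_tip / D_max,
#' where D_tip is the trait distance between the two tips and D_max the
#' maximum distance between any two of their reconstructed ancestors (each
#' lineage traced from the tip back to and including the pair's MRCA, the
#' tip itself included). The overall index is the mean over between-clade
#' pairs; within-clade pairs are excluded, matching the clustering of each
#' converging clade.
#'
#' @param tree an [ape::phylo] tree.
#' @param trait named numeric tip vector (or `tip.label` order).
#' @param focal list of character vectors of tip labels (>= 2 disjoint
#'   clades).
#' @return list of class `c1_result`: `C1`, `per_pair` (data frame),
#'   `prep` (reusable internals).
#' @export
c1_univariate <- function(tree, trait, focal) {
  y <- .order_by_tips(tree, trait)
  if (diff(range(y)) <= 0)
    stop("constant trait: D_max = 0 for every pair, C1 undefined")
  prep <- .c1_prep(tree, focal)
  op <- asr_operator(tree)
  vals <- .node_values(tree, matrix(y, ncol = 1L), op)
  st <- .c1_stat(prep, vals)
  if (any(!is.finite(st$per_pair)))
    stop("D_max = 0 for at least one pair (constant trait?): C1 undefined")
  pp <- data.frame(tip1 = tree$tip.label[prep$tips[prep$pairs[1L, ]]],
                   tip2 = tree$tip.label[prep$tips[prep$pairs[2L, ]]],
                   C1 = st$per_pair[, 1L], stringsAsFactors = FALSE)
  structure(list(C1 = st$overall[1L], per_pair = pp, prep = prep,
                 operator = op), class = "c1_result")
}

# shared BM null: sigma2 by ML from the observed trait, root at the GLS
# mean; returns (n_tips x n_sim) tip matrix
.bm_null_sims <- function(tree, y, n_sim, seed, vcv = NULL) {
  fit <- fit_bm(tree, y, vcv = vcv)
  simulate_bm(tree, fit$sigma2, fit$root_state, n_reps = n_sim,
              seed = seed)$tips
}

#' Simulation p-value for C1
#'
#' Estimates the BM rate from the observed trait by ML, simulates `n_sim`
#' BM datasets on the tree, recomputes C1 (with ancestral states
#' re-reconstructed per dataset) and reports
#' p = (number of simulations with C1 >= observed + 1) / (n_sim + 1).
#'
#' @inheritParams c1_univariate
#' @param n_sim number of BM simulations.
#' @param seed RNG seed; use the same seed in [c5_pvalue()] to couple the
#'   two nulls to one simulation stream.
#' @param observed optional precomputed [c1_univariate()] result.
#' @return list with `C1`, `p`, `n_sim`, `seed`, `sim_C1`.
#' @export
c1_pvalue <- function(tree, trait, focal, n_sim = 1000L, seed = 1L,
                      observed = NULL) {
  if (n_sim < 1L) stop("n_sim must be positive")
  y <- .order_by_tips(tree, trait)
  if (is.null(observed)) observed <- c1_univariate(tree, trait, focal)
  op <- observed$operator
  tips <- .bm_null_sims(tree, y, n_sim, seed)
  vals <- .node_values(tree, tips, op)
  sim <- .c1_stat(observed$prep, vals)$overall
  list(C1 = observed$C1, p = (sum(sim >= observed$C1) + 1) / (n_sim + 1),
       n_sim = n_sim, seed = seed, sim_C1 = sim)
}

# entries for one column of node values; region = [lo, hi]
.c5_entries_1d <- function(tree, vals, lo, hi) {
  pv <- vals[tree$edge[, 1L]]
  cv <- vals[tree$edge[, 2L]]
  seg_lo <- pmin(pv, cv); seg_hi <- pmax(pv, cv)
  parent_out <- pv < lo | pv > hi
  reaches <- pmax(seg_lo, lo) <= pmin(seg_hi, hi)
  entering <- which(parent_out & reaches)
  root_val <- vals[.n_tips(tree) + 1L]
  root_in <- root_val >= lo && root_val <= hi
  list(entering = entering, root_entry = root_in,
       count = length(entering) + as.integer(root_in))
}

#' Univariate C5 convergence-event count
#'
#' The morphospace region is the closed interval spanned by the focal tip
#' values. Every branch is walked as a linear segment between its
#' reconstructed (or observed, at tips) endpoint values; a branch counts
#' as one entering lineage when its parent-side value lies outside the
#' region and the segment reaches it. A root lying inside the region
#' counts as one entry at the origin of the walk.
#'
#' @inheritParams c1_univariate
#' @param focal list of clades or a single character vector of focal tips.
#' @return list of class `c5_result`: `C5`, `region` (lo/hi), `entering`
#'   (data frame of entering branches with endpoint values), `root_entry`.
#' @export
c5_univariate <- function(tree, trait, focal) {
  y <- .order_by_tips(tree, trait)
  idx <- unlist(.focal_prep(tree, focal))
  op <- asr_operator(tree)
  vals <- drop(.node_values(tree, matrix(y, ncol = 1L), op))
  lo <- min(y[idx]); hi <- max(y[idx])
  ent <- .c5_entries_1d(tree, vals, lo, hi)
  entering <- data.frame(edge = ent$entering,
                         child = tree$edge[ent$entering, 2L],
                         parent_val = vals[tree$edge[ent$entering, 1L]],
                         child_val = vals[tree$edge[ent$entering, 2L]])
  structure(list(C5 = ent$count, region = c(lo = lo, hi = hi),
                 entering = entering, root_entry = ent$root_entry,
                 operator = op, focal_idx = idx),
            class = "c5_result")
}

#' Simulation p-value for C5
#'
#' Same BM null as [c1_pvalue()]; for each simulated dataset the region is
#' re-derived from the same focal tips and the entry count recomputed.
#'
#' @inheritParams c1_pvalue
#' @param observed optional precomputed [c5_univariate()] result.
#' @return list with `C5`, `p`, `n_sim`, `seed`, `sim_C5`.
#' @export
c5_pvalue <- function(tree, trait, focal, n_sim = 1000L, seed = 1L,
                      observed = NULL) {
  if (n_sim < 1L) stop("n_sim must be positive")
  y <- .order_by_tips(tree, trait)
  if (is.null(observed)) observed <- c5_univariate(tree, trait, focal)
  tips <- .bm_null_sims(tree, y, n_sim, seed)
  vals <- .node_values(tree, tips, observed$operator)
  idx <- observed$focal_idx
  sim <- vapply(seq_len(n_sim), function(s) {
    v <- vals[, s]
    .c5_entries_1d(tree, v, min(v[idx]), max(v[idx]))$count
  }, numeric(1))
  list(C5 = observed$C5, p = (sum(sim >= observed$C5) + 1) / (n_sim + 1),
       n_sim = n_sim, seed = seed, sim_C5 = sim)
}

#' Minimum-area enclosing ellipse (Khachiyan's algorithm)
#'
#' @param P numeric matrix of 2-D points (rows).
#' @param tol convergence tolerance.
#' @return list with `center` and shape matrix `A` such that the ellipse is
#'   \{x : (x - c)' A (x - c) <= 1\}; all input points satisfy the bound.
#' @export
min_enclosing_ellipse <- function(P, tol = 1e-7) {
  P <- as.matrix(P)
  d <- ncol(P); m <- nrow(P)
  stopifnot(d == 2L, m >= 3L)
  Q <- t(cbind(P, 1))
  u <- rep(1 / m, m)
  for (it in seq_len(5000L)) {
    X <- Q %*% (u * t(Q))
    M <- diag(t(Q) %*% solve(X, Q))
    j <- which.max(M)
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    nu <- u * (1 - step)
    nu[j] <- nu[j] + step
    if (sum(abs(nu - u)) < tol) { u <- nu; break }
    u <- nu
  }
  ctr <- drop(t(P) %*% u)
  A <- solve(t(P) %*% (u * P) - tcrossprod(ctr)) / d
  # guarantee containment despite finite iteration count
  q <- apply(P, 1L, function(x) drop(t(x - ctr) %*% A %*% (x - ctr)))
  A <- A / max(max(q), 1)
  list(center = ctr, A = A)
}

# covariance (95%) ellipse alternative
.cov_ellipse <- function(P, level = 0.95) {
  ctr <- colMeans(P)
  S <- stats::cov(P)
  list(center = ctr, A = solve(S * stats::qchisq(level, 2L)))
}

# padded bounding ellipse for degenerate (< 3 non-collinear) focal sets
.padded_ellipse <- function(P) {
  ctr <- colMeans(P)
  Pc <- sweep(P, 2L, ctr)
  sv <- svd(Pc)
  ax <- pmax(apply(abs(Pc %*% sv$v), 2L, max), 1e-8 + 0.01 * max(1, max(abs(P))))
  A <- sv$v %*% diag(1 / (1.05 * ax)^2) %*% t(sv$v)
  list(center = ctr, A = A)
}

.in_ellipse <- function(x, ell) {
  d <- x - ell$center
  drop(t(d) %*% ell$A %*% d) <= 1 + 1e-9
}

# does the segment p -> c intersect the ellipse?
.segment_hits_ellipse <- function(p, c2, ell) {
  d <- c2 - p
  f <- p - ell$center
  A <- ell$A
  a <- drop(t(d) %*% A %*% d)
  b <- 2 * drop(t(f) %*% A %*% d)
  cc <- drop(t(f) %*% A %*% f) - 1
  if (cc <= 1e-9) return(TRUE)          # starts inside
  if (a < 1e-18) return(FALSE)          # zero-length step, outside
  disc <- b * b - 4 * a * cc
  if (disc < 0) return(FALSE)
  t1 <- (-b - sqrt(disc)) / (2 * a)
  t2 <- (-b + sqrt(disc)) / (2 * a)
  t2 >= 0 && t1 <= 1
}

#' Bivariate C5 convergence-event count
#'
#' The morphospace region is the minimum-area ellipse enclosing the focal
#' tip points (95% covariance ellipse switchable). Branches are walked as
#' 2-D linear segments between reconstructed endpoint points; entries are
#' counted as in the univariate case, with a root inside the region
#' counting once. A degenerate focal set (< 3 non-collinear points) falls
#' back to a padded bounding ellipse and is flagged.
#'
#' @param tree an [ape::phylo] tree.
#' @param traits two-column matrix/data frame of tip values (rownames =
#'   tips) or list of two named vectors.
#' @param focal focal clades (list) or single tip vector; taxa excluded
#'   from the region definition (e.g. secondarily fossorial lineages) are
#'   simply omitted from `focal`.
#' @param region `"mvee"` (default) or `"covariance"`.
#' @return list of class `c5_result`: `C5`, `ellipse`, `entering` (data
#'   frame with edge ids and endpoint coordinates), `root_entry`,
#'   `degenerate` flag.
#' @export
c5_bivariate <- function(tree, traits, focal, region = c("mvee", "covariance")) {
  region <- match.arg(region)
  if (is.list(traits) && !is.data.frame(traits))
    traits <- cbind(traits[[1L]], traits[[2L]])
  X <- as.matrix(traits)
  stopifnot(ncol(X) == 2L)
  y1 <- .order_by_tips(tree, stats::setNames(X[, 1L], rownames(X)))
  y2 <- .order_by_tips(tree, stats::setNames(X[, 2L], rownames(X)))
  idx <- unlist(.focal_prep(tree, focal))
  op <- asr_operator(tree)
  v1 <- drop(.node_values(tree, matrix(y1, ncol = 1L), op))
  v2 <- drop(.node_values(tree, matrix(y2, ncol = 1L), op))
  Pf <- cbind(y1, y2)[idx, , drop = FALSE]
  degenerate <- nrow(Pf) < 3L ||
    qr(sweep(Pf, 2L, colMeans(Pf)), tol = 1e-10)$rank < 2L
  ell <- if (degenerate) .padded_ellipse(Pf)
         else if (region == "mvee") min_enclosing_ellipse(Pf)
         else .cov_ellipse(Pf)
  n <- .n_tips(tree)
  pts <- cbind(v1, v2)
  entering <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    p <- pts[tree$edge[e, 1L], ]; ch <- pts[tree$edge[e, 2L], ]
    if (!.in_ellipse(p, ell) && .segment_hits_ellipse(p, ch, ell))
      entering <- c(entering, e)
  }
  root_in <- .in_ellipse(pts[n + 1L, ], ell)
  ent <- data.frame(edge = entering, child = tree$edge[entering, 2L],
                    parent_x = pts[tree$edge[entering, 1L], 1L],
                    parent_y = pts[tree$edge[entering, 1L], 2L],
                    child_x = pts[tree$edge[entering, 2L], 1L],
                    child_y = pts[tree$edge[entering, 2L], 2L])
  structure(list(C5 = length(entering) + as.integer(root_in),
                 ellipse = ell, entering = ent, root_entry = root_in,
                 degenerate = degenerate), class = "c5_result")
}

#' Mean converging vector of the entering lineages
#'
#' Component-wise mean of the (child - parent) trait-space vectors over all
#' entering lineages of a C5 result — the sum of all converging lineages
#' divided by their number.
#'
#' @param c5 a `c5_result` from [c5_univariate()] or [c5_bivariate()].
#' @return numeric vector (length 1 or 2).
#' @export
mean_convergence_vectors <- function(c5) {
  ent <- c5$entering
  if (nrow(ent) == 0L) stop("no entering lineages")
  if ("parent_val" %in% names(ent))
    mean(ent$child_val - ent$parent_val)
  else c(x = mean(ent$child_x - ent$parent_x),
         y = mean(ent$child_y - ent$parent_y))
}
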