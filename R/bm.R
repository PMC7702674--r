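# Brownian-motion machinery: lambda ML, BM simulation, continuous ASR.

.gls_loglik <- function(V, y, X) {
  C <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(C)) return(list(logL = -Inf))
  n <- length(y)
  # whiten: z = U'^-1 y where V = U'U
  z <- backsolve(C, y, transpose = TRUE)
  W <- backsolve(C, X, transpose = TRUE)
  fit <- stats::lm.fit(W, z)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(C)))
  list(logL = -0.5 * (n * log(2 * pi * sigma2) + logdet + n),
       beta = fit$coefficients, sigma2 = sigma2, chol = C)
}

#' Maximum-likelihood Pagel's lambda
#'
#' Profiles the GLS log-likelihood of `trait ~ X` (intercept-only by
#' default) under the lambda-transformed BM covariance, over lambda in
#' \[0, 1\]. When the unconstrained optimum falls outside the interval the
#' estimate is clamped to the boundary and flagged, mirroring the protocol
#' of forcing negative estimates to 0 and estimates above 1 to 1.
#'
#' @param tree an [ape::phylo] tree.
#' @param trait named numeric vector (names = tip labels) or vector ordered
#'   as `tree$tip.label`.
#' @param X optional design matrix (default intercept only).
#' @param vcv optional precomputed [phylo_vcv()] matrix.
#' @return list with `lambda`, `logL`, `clamped`, `sigma2`, `beta`.
#' @export
fit_lambda_ml <- function(tree, trait, X = NULL, vcv = NULL) {
  y <- .order_by_tips(tree, trait)
  n <- length(y)
  if (n < 4L) stop("need at least 4 tips")
  if (stats::var(y) == 0) stop("trait has zero variance; lambda undefined")
  if (is.null(vcv)) vcv <- phylo_vcv(tree)
  if (is.null(X)) X <- matrix(1, n, 1L)
  f <- function(lam) .gls_loglik(lambda_transform(vcv, lam), y, X)$logL
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
  lam <- opt$maximum; logL <- opt$objective
  clamped <- FALSE
  h <- 1e-4
  # boundary beats the interior optimum => unconstrained optimum outside [0,1]
  for (b in c(0, 1)) {
    fb <- f(b)
    if (fb >= logL) {
      lam <- b; logL <- fb
      inside <- f(b + ifelse(b == 0, h, -h))
      clamped <- fb > inside
    }
  }
  g <- .gls_loglik(lambda_transform(vcv, lam), y, X)
  list(lambda = lam, logL = logL, clamped = clamped,
       sigma2 = g$sigma2, beta = g$beta)
}

#' ML Brownian-motion rate from tip data
#'
#' @inheritParams fit_lambda_ml
#' @return list with `sigma2` and `root_state` (GLS mean).
#' @export
fit_bm <- function(tree, trait, vcv = NULL) {
  y <- .order_by_tips(tree, trait)
  if (is.null(vcv)) vcv <- phylo_vcv(tree)
  g <- .gls_loglik(vcv, y, matrix(1, length(y), 1L))
  list(sigma2 = g$sigma2, root_state = unname(g$beta[1L]), logL = g$logL)
}

.order_by_tips <- function(tree, trait) {
  if (!is.null(names(trait))) {
    miss <- setdiff(tree$tip.label, names(trait))
    if (length(miss)) stop("trait missing for tips: ",
                           paste(miss, collapse = ", "))
    trait <- trait[tree$tip.label]
  } else if (length(trait) != .n_tips(tree)) {
    stop("trait length does not match number of tips")
  }
  as.numeric(trait)
}

#' Simulate Brownian motion on a tree
#'
#' Root-to-tip recursion: each branch adds a Normal(0, sigma2 * length)
#' increment. Returns tip values and, optionally, internal-node values.
#'
#' @param tree an [ape::phylo] tree.
#' @param sigma2 BM rate (> 0).
#' @param root_state trait value at the root.
#' @param n_reps number of replicate datasets.
#' @param seed optional RNG seed for reproducibility.
#' @return list with `tips` (n_tips x n_reps matrix, rownames = tip labels)
#'   and `nodes` ((n_tips + Nnode) x n_reps matrix of all node values).
#' @export
simulate_bm <- function(tree, sigma2, root_state = 0, n_reps = 1L,
                        seed = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- .n_tips(tree)
  nn <- n + tree$Nnode
  vals <- matrix(0, nn, n_reps)
  vals[n + 1L, ] <- root_state
  for (e in .preorder_edges(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    vals[ch, ] <- vals[p, ] +
      if (len > 0) stats::rnorm(n_reps, 0, sqrt(sigma2 * len)) else 0
  }
  tips <- vals[seq_len(n), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  list(tips = tips, nodes = vals)
}

#' Linear operator mapping tip values to ML ancestral states
#'
#' ML (joint GLS) ancestral states under BM minimize the sum over edges of
#' (x_child - x_parent)^2 / length; the minimizer is linear in the tip
#' values. This returns the (Nnode x n_tips) matrix of that linear map so
#' repeated reconstructions (e.g. simulation nulls) reduce to one matrix
#' product. Zero-length branches are given a tiny positive length.
#'
#' @param tree an [ape::phylo] tree.
#' @return matrix `M` with `node_states = M %*% tips_in_tip.label_order`.
#' @export
asr_operator <- function(tree) {
  n <- .n_tips(tree)
  nint <- tree$Nnode
  A <- matrix(0, nint, nint)
  B <- matrix(0, nint, n)
  lens <- pmax(tree$edge.length, 1e-9)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L] - n   # internal index of parent
    ch <- tree$edge[e, 2L]
    w <- 1 / lens[e]
    A[p, p] <- A[p, p] + w
    if (ch > n) {
      ci <- ch - n
      A[ci, ci] <- A[ci, ci] + w
      A[p, ci] <- A[p, ci] - w
      A[ci, p] <- A[ci, p] - w
    } else {
      B[p, ch] <- B[p, ch] + w
    }
  }
  M <- solve(A, B)
  rownames(M) <- as.character(n + seq_len(nint))
  colnames(M) <- tree$tip.label
  M
}

#' ML ancestral states of a continuous trait under Brownian motion
#'
#' @inheritParams fit_lambda_ml
#' @param operator optional precomputed [asr_operator()].
#' @return named numeric vector of states at internal nodes (names = node
#'   ids as in the `phylo` edge matrix; the root is node `n_tips + 1`).
#' @export
asr_continuous <- function(tree, trait, operator = NULL) {
  y <- .order_by_tips(tree, trait)
  if (is.null(operator)) operator <- asr_operator(tree)
  drop(operator %*% y)
}

#' Interpolated states along each branch (contMap-style export)
#'
#' @param tree an [ape::phylo] tree.
#' @param trait tip values (see [fit_lambda_ml()]).
#' @param n_grid points per branch.
#' @return list with `node_states` (tips then internals) and `branch_grid`,
#'   a matrix (edges x n_grid) of linearly interpolated states.
#' @export
asr_branch_profile <- function(tree, trait, n_grid = 20L) {
  y <- .order_by_tips(tree, trait)
  anc <- asr_continuous(tree, y)
  states <- c(y, anc)
  frac <- seq(0, 1, length.out = n_grid)
  grid <- t(vapply(seq_len(nrow(tree$edge)), function(e) {
    a <- states[tree$edge[e, 1L]]; b <- states[tree$edge[e, 2L]]
    a + (b - a) * frac
  }, numeric(n_grid)))
  list(node_states = states, branch_grid = grid)
}
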