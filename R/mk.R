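# Mk discrete-character model: transition probabilities, pruning likelihood,
# maximum-likelihood rate estimation.

#' Mk transition probability matrix
#'
#' @param Q rate matrix (rows sum to 0, off-diagonals >= 0).
#' @param t elapsed time (>= 0).
#' @return matrix exponential `expm(Q t)`.
#' @export
mk_transition_prob <- function(Q, t) {
  k <- nrow(Q)
  if (t == 0) return(diag(k))
  # equal-rates closed form: all off-diagonals equal
  off <- Q[row(Q) != col(Q)]
  if (max(off) - min(off) < 1e-14) {
    r <- off[1L]
    e <- exp(-k * r * t)
    P <- matrix((1 - e) / k, k, k)
    diag(P) <- (1 + (k - 1) * e) / k
    return(P)
  }
  eg <- eigen(Q)
  P <- Re(eg$vectors %*% diag(exp(eg$values * t), k) %*% solve(eg$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

# stationary distribution of Q (left null vector, normalized)
.mk_stationary <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  pi <- stats::lm.fit(A, c(rep(0, k), 1))$coefficients
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

# conditional (partial) likelihoods at every node; tip_states is an integer
# vector (1..k) ordered by tip.label. Returns list(L = (nn x k) matrix of
# partials, P = list of per-edge transition matrices).
.mk_partials <- function(tree, tip_idx, Q) {
  n <- .n_tips(tree)
  nn <- n + tree$Nnode
  k <- nrow(Q)
  # transition matrices per unique branch length
  lens <- tree$edge.length
  ul <- unique(lens)
  Pu <- lapply(ul, function(t) mk_transition_prob(Q, t))
  P <- Pu[match(lens, ul)]
  L <- matrix(1, nn, k)
  L[seq_len(n), ] <- 0
  L[cbind(seq_len(n), tip_idx)] <- 1
  for (e in .postorder_edges(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    L[p, ] <- L[p, ] * as.numeric(P[[e]] %*% L[ch, ])
  }
  list(L = L, P = P)
}

# log-likelihood with per-node scaling to avoid underflow
.mk_loglik <- function(tree, tip_idx, Q, root_prior) {
  n <- .n_tips(tree)
  nn <- n + tree$Nnode
  k <- nrow(Q)
  lens <- tree$edge.length
  ul <- unique(lens)
  Pu <- lapply(ul, function(t) mk_transition_prob(Q, t))
  P <- Pu[match(lens, ul)]
  L <- matrix(1, nn, k)
  L[seq_len(n), ] <- 0
  L[cbind(seq_len(n), tip_idx)] <- 1
  logscale <- 0
  for (e in .postorder_edges(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    L[p, ] <- L[p, ] * as.numeric(P[[e]] %*% L[ch, ])
    m <- max(L[p, ])
    if (m > 0 && m < 1e-10) {
      L[p, ] <- L[p, ] / m
      logscale <- logscale + log(m)
    }
  }
  root <- n + 1L
  lik <- sum(root_prior * L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}

.tip_state_index <- function(tree, tip_states, states = NULL) {
  if (!is.null(names(tip_states))) tip_states <- tip_states[tree$tip.label]
  tip_states <- as.character(tip_states)
  if (anyNA(tip_states)) stop("missing tip states")
  if (is.null(states)) states <- sort(unique(tip_states))
  idx <- match(tip_states, states)
  if (anyNA(idx)) stop("tip state outside the model's state set")
  list(idx = idx, states = states)
}

#' Fit an Mk model by maximum likelihood
#'
#' Felsenstein pruning likelihood with bounded optimization of the
#' transition rate(s). `ER` (one rate, the default — for a binary character
#' SYM is identical) or `ARD` (all rates distinct).
#'
#' @param tree an [ape::phylo] tree.
#' @param tip_states character/factor vector of observed states, named by
#'   tip or ordered as `tree$tip.label`.
#' @param flavour `"ER"` or `"ARD"`.
#' @param root_prior `"stationary"` (default) or `"uniform"`.
#' @return list of class `mk_model`: `Q`, `states`, `flavour`, `logLik`,
#'   `rates`, `pi` (root prior used).
#' @export
fit_mk <- function(tree, tip_states, flavour = c("ER", "ARD"),
                   root_prior = c("stationary", "uniform")) {
  flavour <- match.arg(flavour)
  root_prior <- match.arg(root_prior)
  ts <- .tip_state_index(tree, tip_states)
  k <- length(ts$states)
  if (k < 2L) {
    warning("invariant character: rate -> 0")
    Q <- matrix(0, 1, 1)
    return(structure(list(Q = Q, states = ts$states, flavour = flavour,
                          logLik = 0, rates = 0, pi = 1), class = "mk_model"))
  }
  build_Q <- function(rates) {
    Q <- matrix(0, k, k)
    if (flavour == "ER") Q[row(Q) != col(Q)] <- rates[1L]
    else Q[row(Q) != col(Q)] <- rates  # column-major over off-diagonals
    diag(Q) <- -rowSums(Q)
    Q
  }
  prior_for <- function(Q) {
    if (root_prior == "uniform") rep(1 / k, k) else .mk_stationary(Q)
  }
  nll <- function(logr) {
    Q <- build_Q(exp(logr))
    -.mk_loglik(tree, ts$idx, Q, prior_for(Q))
  }
  scale0 <- log(k / sum(tree$edge.length))  # one expected change on the tree
  if (flavour == "ER") {
    opt <- stats::optimize(nll, scale0 + c(-12, 8))
    rates <- exp(opt$minimum); logL <- -opt$objective
  } else {
    np <- k * (k - 1L)
    opt <- stats::optim(rep(scale0, np), nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    rates <- exp(opt$par); logL <- -opt$value
  }
  Q <- build_Q(rates)
  dimnames(Q) <- list(ts$states, ts$states)
  structure(list(Q = Q, states = ts$states, flavour = flavour,
                 logLik = logL, rates = rates, pi = prior_for(Q)),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("Mk model (%s), %d states, logLik %.4f\n", x$flavour,
              length(x$states), x$logLik))
  print(round(x$Q, 6))
  invisible(x)
}
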