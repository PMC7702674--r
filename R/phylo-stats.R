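# Phylogenetically informed ANOVA/regression with residual-randomization
# permutations, Holm adjustment, PCA, two-block PLS.

#' Holm step-down adjustment of p-values
#'
#' Validates the input and applies the Holm method: sort ascending,
#' multiply by (m - rank + 1), enforce monotonicity, cap at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Phylogenetically informed ANOVA / regression with RRPP permutations
#'
#' Pipeline: (1) fit Pagel's lambda by ML GLS for `trait ~ predictor`;
#' (2) clamp lambda to \[0, 1\]; (3) build the lambda-transformed BM
#' covariance; (4) whiten trait and design by the inverse Cholesky factor;
#' (5) F statistic from the whitened fit; (6) permutation p by residual
#' randomization of the reduced (intercept-only) model; (7) for a
#' categorical predictor, pairwise LS-mean distances with permutation p and
#' Holm adjustment.
#'
#' @param trait named numeric vector (tip labels) or in `tip.label` order.
#' @param predictor factor/character (groups) or numeric (covariate),
#'   named or ordered like `trait`.
#' @param tree an [ape::phylo] tree.
#' @param n_perm number of RRPP permutations.
#' @param seed RNG seed (mandatory for reproducible permutation p-values).
#' @param lambda fix lambda instead of estimating it (e.g. 0 to recover an
#'   ordinary permutation ANOVA on a star phylogeny).
#' @param vcv optional precomputed [phylo_vcv()].
#' @return object of class `phylo_anova`: `lambda_used`, `clamped`, `F`,
#'   `p`, `pairwise` (data frame or NULL), `n_perm`, `seed`, `df`.
#' @export
phylo_anova_rrpp <- function(trait, predictor, tree, n_perm = 10000L,
                             seed = 1L, lambda = NULL, vcv = NULL) {
  y <- .order_by_tips(tree, trait)
  n <- length(y)
  if (!is.null(names(predictor))) predictor <- predictor[tree$tip.label]
  categorical <- is.character(predictor) || is.factor(predictor)
  if (categorical) {
    g <- factor(predictor)
    if (nlevels(g) < 2L) stop("need at least 2 groups")
    if (any(table(g) < 2L)) stop("every group needs at least 2 members")
    X <- stats::model.matrix(~g)
  } else {
    X <- cbind(1, as.numeric(predictor))
  }
  if (qr(X)$rank < ncol(X)) stop("singular design")
  if (is.null(vcv)) vcv <- phylo_vcv(tree)

  clamped <- FALSE
  if (is.null(lambda)) {
    lf <- fit_lambda_ml(tree, y, X = X, vcv = vcv)
    lambda <- lf$lambda
    clamped <- lf$clamped
  }
  V <- lambda_transform(vcv, lambda)
  C <- chol(V)
  z <- backsolve(C, y, transpose = TRUE)
  W <- backsolve(C, X, transpose = TRUE)
  W0 <- backsolve(C, matrix(1, n, 1L), transpose = TRUE)

  hat <- function(A) A %*% solve(crossprod(A), t(A))
  Hf <- hat(W); H0 <- hat(W0)
  df1 <- ncol(X) - 1L
  df2 <- n - ncol(X)
  rss <- function(Yc, H) colSums((Yc - H %*% Yc)^2)
  zm <- matrix(z, n, 1L)
  rss0_obs <- rss(zm, H0); rssf_obs <- rss(zm, Hf)
  F_obs <- ((rss0_obs - rssf_obs) / df1) / (rssf_obs / df2)

  set.seed(seed)
  fitted0 <- H0 %*% zm
  resid0 <- z - drop(fitted0)
  perms <- replicate(n_perm, sample.int(n))
  Yp <- matrix(resid0[perms], n, n_perm) + drop(fitted0)
  rss0_p <- rss(Yp, H0); rssf_p <- rss(Yp, Hf)
  F_p <- ((rss0_p - rssf_p) / df1) / (rssf_p / df2)
  p_overall <- (sum(F_p >= F_obs) + 1) / (n_perm + 1)

  pairwise <- NULL
  if (categorical) {
    # LS means in whitened space from the model coefficients
    XtXi <- solve(crossprod(W))
    coef_of <- function(Y) XtXi %*% crossprod(W, Y)
    lsm <- function(b) {
      m <- b[1L, ] + rbind(0, b[-1L, , drop = FALSE])
      m
    }
    m_obs <- lsm(coef_of(zm))
    m_p <- lsm(coef_of(Yp))
    lev <- levels(g)
    combs <- utils::combn(seq_along(lev), 2L)
    raw <- numeric(ncol(combs)); dobs <- numeric(ncol(combs))
    for (k in seq_len(ncol(combs))) {
      i <- combs[1L, k]; j <- combs[2L, k]
      dobs[k] <- abs(m_obs[i, 1L] - m_obs[j, 1L])
      dp <- abs(m_p[i, ] - m_p[j, ])
      raw[k] <- (sum(dp >= dobs[k]) + 1) / (n_perm + 1)
    }
    pairwise <- data.frame(group1 = lev[combs[1L, ]],
                           group2 = lev[combs[2L, ]],
                           distance = dobs, p = raw,
                           p_holm = holm_adjust(raw),
                           stringsAsFactors = FALSE)
  }
  structure(list(lambda_used = lambda, clamped = clamped,
                 F = unname(F_obs), p = p_overall, pairwise = pairwise,
                 n_perm = n_perm, seed = seed, df = c(df1, df2)),
            class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat(sprintf("phylo ANOVA (RRPP, %d perms): lambda = %.3f%s, F(%d,%d) = %.3f, p = %.4g\n",
              x$n_perm, x$lambda_used, if (x$clamped) " [clamped]" else "",
              x$df[1L], x$df[2L], x$F, x$p))
  if (!is.null(x$pairwise)) print(x$pairwise, digits = 4)
  invisible(x)
}

#' Principal component analysis of a trait table
#'
#' Eigendecomposition of the correlation (default, since the traits mix mm,
#' percentages and ratios) or covariance matrix, via `stats::princomp`.
#'
#' @param traits numeric matrix/data frame, complete cases, >= 2 columns.
#' @param standardize use the correlation matrix (default TRUE).
#' @return list with `loadings`, `scores`, `var_frac` and `sdev`.
#' @export
pca_traits <- function(traits, standardize = TRUE) {
  X <- as.matrix(traits)
  if (ncol(X) < 2L) stop("need at least 2 variables")
  if (anyNA(X)) stop("complete cases required")
  if (standardize && any(apply(X, 2L, stats::sd) == 0))
    stop("constant column cannot be standardized")
  pc <- stats::princomp(X, cor = standardize)
  v <- unname(pc$sdev^2)
  list(loadings = unclass(pc$loadings), scores = pc$scores,
       var_frac = v / sum(v), sdev = pc$sdev)
}

#' Two-block partial least squares
#'
#' SVD of the centred cross-covariance of two blocks; `r_pls` is the
#' correlation of the first pair of singular scores; significance by
#' permuting the rows of one block.
#'
#' @param X,Y numeric matrices with the same number of rows.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `pls_result`: `r_pls`, `p`, `singular_values`,
#'   `x_scores`, `y_scores`.
#' @export
two_block_pls <- function(X, Y, n_perm = 1000L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("blocks must have the same number of rows")
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  r_of <- function(Yc) {
    S <- crossprod(Xc, Yc)
    sv <- svd(S)
    if (sv$d[1L] < 1e-12) return(c(0, 0))
    u <- Xc %*% sv$u[, 1L]; v <- Yc %*% sv$v[, 1L]
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(c(0, sv$d[1L]))
    c(abs(stats::cor(u, v)), sv$d[1L])
  }
  obs <- r_of(Yc)
  if (obs[2L] < 1e-12) warning("rank-0 cross-covariance: r_pls = 0")
  set.seed(seed)
  rp <- replicate(n_perm, r_of(Yc[sample.int(nrow(Yc)), , drop = FALSE])[1L])
  S <- crossprod(Xc, Yc); sv <- svd(S)
  structure(list(r_pls = obs[1L],
                 p = (sum(rp >= obs[1L]) + 1) / (n_perm + 1),
                 singular_values = sv$d,
                 x_scores = Xc %*% sv$u[, 1L], y_scores = Yc %*% sv$v[, 1L]),
            class = "pls_result")
}

#' Phylogeny-versus-lifestyle two-block PLS
#'
#' Convenience wrapper testing for correlation between phylogeny and
#' ecological groups: block X = principal coordinates of the patristic
#' distance matrix (components covering `var_cutoff` of the positive
#' eigenvalue mass), block Y = one-hot lifestyle indicators.
#'
#' @param tree an [ape::phylo] tree.
#' @param groups factor/character of group membership, named by tip.
#' @param var_cutoff fraction of positive PCoA eigenvalue mass retained.
#' @inheritParams two_block_pls
#' @return a `pls_result` (see [two_block_pls()]).
#' @export
pls_phylo_groups <- function(tree, groups, n_perm = 1000L, seed = 1L,
                             var_cutoff = 0.95) {
  if (!is.null(names(groups))) groups <- groups[tree$tip.label]
  D <- ape::cophenetic.phylo(tree)
  pc <- stats::cmdscale(D, k = min(nrow(D) - 1L, 50L), eig = TRUE)
  pos <- pc$eig > 1e-9
  cum <- cumsum(pc$eig[pos]) / sum(pc$eig[pos])
  keep <- min(which(cum >= var_cutoff))
  X <- pc$points[, seq_len(keep), drop = FALSE]
  Y <- stats::model.matrix(~0 + factor(groups))
  two_block_pls(X, Y, n_perm = n_perm, seed = seed)
}
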