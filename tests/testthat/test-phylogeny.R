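test_that("Newick parsing validates and round-trips topology and lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3L)
  D <- ape::cophenetic.phylo(tr)
  expect_equal(D["A", "C"], 4)
  expect_equal(unname(ape::node.depth.edgelength(tr)[match("A", tr$tip.label)]), 2)

  big <- random_tree(99L, seed = 1)
  rt <- parse_newick(write_newick(big))
  expect_equal(ape::cophenetic.phylo(rt)[big$tip.label, big$tip.label],
               ape::cophenetic.phylo(big)[big$tip.label, big$tip.label],
               tolerance = 1e-9)

  expect_error(parse_newick("((A:1,A:1):1,B:1);"), "duplicate")
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "parse")
})

test_that("pruning preserves patristic distances among kept tips", {
  tr <- random_tree(50L, seed = 2)
  keep <- sample(tr$tip.label, 10L)
  pr <- prune_tree(tr, keep)
  expect_setequal(pr$tip.label, keep)
  expect_equal(ape::cophenetic.phylo(pr)[keep, keep],
               ape::cophenetic.phylo(tr)[keep, keep], tolerance = 1e-10)

  all_kept <- prune_tree(tr, tr$tip.label)
  expect_equal(ape::cophenetic.phylo(all_kept), ape::cophenetic.phylo(tr))
  expect_error(prune_tree(tr, c("t1", "nosuch")), "nosuch")
})

test_that("phylogenetic covariance equals shared root-to-MRCA path lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  V <- phylo_vcv(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "A"], 2)
  expect_equal(V["A", "C"], 0)

  star <- ape::stree(5, "star")
  star$edge.length <- rep(2, 5)
  expect_equal(phylo_vcv(star), diag(2, 5) + 0 * phylo_vcv(star),
               ignore_attr = TRUE)

  ultra <- gen_tree(20, 0.2, 3)
  expect_equal(unname(diag(phylo_vcv(ultra))),
               rep(max(ape::node.depth.edgelength(ultra)), 20),
               tolerance = 1e-9)

  # random battery against the patristic-distance identity oracle
  for (s in 1:20) {
    n <- sample(4:12, 1L)
    tr2 <- random_tree(n, seed = 100 + s)
    expect_equal(unname(phylo_vcv(tr2)[tr2$tip.label, tr2$tip.label]),
                 unname(oracle_vcv(tr2)), tolerance = 1e-10)
  }
})

test_that("lambda transform scales only the off-diagonal covariance", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  V <- phylo_vcv(tr)
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(diag(V)), ignore_attr = TRUE)
  expect_equal(lambda_transform(V, 0.5)["A", "B"], 0.5)
  expect_error(lambda_transform(V, 1.2), "clamp")
})

test_that("lambda ML recovers signal, clamps at bounds, and is optimal", {
  tr <- gen_tree(100, 0.1, 4)
  V <- phylo_vcv(tr)
  sims <- simulate_bm(tr, 1, 0, 30, seed = 5)$tips
  lam_bm <- apply(sims, 2L, function(y)
    fit_lambda_ml(tr, stats::setNames(y, rownames(sims)), vcv = V)$lambda)
  expect_gt(mean(lam_bm), 0.9)

  set.seed(6)
  lam_wn <- replicate(30, {
    y <- stats::setNames(rnorm(100), tr$tip.label)
    fit_lambda_ml(tr, y, vcv = V)$lambda
  })
  expect_lt(median(lam_wn), 0.1)

  f <- fit_lambda_ml(tr, stats::setNames(sims[, 1L], rownames(sims)), vcv = V)
  for (b in c(0, 1)) {
    gb <- skullconv:::.gls_loglik(lambda_transform(V, b),
                                  sims[match(tr$tip.label, rownames(sims)), 1L],
                                  matrix(1, 100, 1))$logL
    expect_gte(f$logL + 1e-6, gb)
  }
  expect_error(fit_lambda_ml(tr, stats::setNames(rep(1, 100), tr$tip.label)),
               "variance")
})

test_that("lambda ML agrees with an independent GLS implementation", {
  tr <- gen_tree(60, 0.1, 7)
  set.seed(8)
  y <- simulate_bm(tr, 1, 0, 1, seed = 8)$tips[, 1L] +
    rnorm(60, 0, 0.5)  # partial signal so the optimum is interior
  names(y) <- tr$tip.label
  ours <- fit_lambda_ml(tr, y)
  ph <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(ours$lambda, ph$lambda, tolerance = 0.02)
})

test_that("BM simulation matches the analytic covariance structure", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  sims <- simulate_bm(tr, 2, 0, 5000, seed = 9)$tips
  expect_equal(var(sims["A", ]), 2 * 2, tolerance = 0.2)
  expect_equal(cov(sims["A", ], sims["B", ]), 2 * 1, tolerance = 0.3)
  expect_lt(abs(cov(sims["A", ], sims["C", ])), 0.2)

  z <- parse_newick("((A:0,B:1):1,C:2);")
  s0 <- simulate_bm(z, 1, 0, 10, seed = 10)
  parent_vals <- s0$nodes[z$edge[z$edge[, 2L] == match("A", z$tip.label), 1L], ]
  expect_equal(s0$tips["A", ], parent_vals)
})

test_that("continuous ancestral states match closed forms and the GLS oracle", {
  star <- ape::stree(3, "star")
  star$edge.length <- rep(1, 3)
  star$tip.label <- c("A", "B", "C")
  expect_equal(unname(asr_continuous(star, c(A = 1, B = 2, C = 3))), 2)

  two <- parse_newick("(A:1,B:3);")
  expect_equal(unname(asr_continuous(two, c(A = 0, B = 4))), 1.0)

  tr <- random_tree(8L, seed = 11)
  const <- stats::setNames(rep(3.3, 8), tr$tip.label)
  expect_equal(unname(asr_continuous(tr, const)), rep(3.3, tr$Nnode))

  for (s in 1:10) {
    tr2 <- random_tree(sample(4:10, 1L), seed = 200 + s)
    y <- stats::setNames(rnorm(length(tr2$tip.label)), tr2$tip.label)
    expect_equal(unname(asr_continuous(tr2, y)), unname(oracle_asr(tr2, y)),
                 tolerance = 1e-8)
  }

  # root state equals the lambda = 1 GLS intercept
  tr3 <- random_tree(12L, seed = 12)
  y3 <- stats::setNames(rnorm(12), tr3$tip.label)
  root <- asr_continuous(tr3, y3)[1L]
  gls <- skullconv:::.gls_loglik(phylo_vcv(tr3), y3[tr3$tip.label],
                                 matrix(1, 12, 1))
  expect_equal(unname(root), unname(gls$beta[1L]), tolerance = 1e-8)
})

test_that("Mk pruning likelihood equals brute-force enumeration", {
  set.seed(13)
  for (rep in 1:20) {
    tr <- random_tree(5L, seed = 300 + rep)
    k <- sample(2:3, 1L)
    r <- runif(1, 0.05, 1)
    Q <- matrix(r, k, k); diag(Q) <- -(k - 1) * r
    states <- sample.int(k, 5L, replace = TRUE)
    if (length(unique(states)) < 2L) states[1:2] <- c(1L, 2L)
    prior <- rep(1 / k, k)
    expect_equal(skullconv:::.mk_loglik(tr, states, Q, prior),
                 log(oracle_mk_lik(tr, states, Q, prior)), tolerance = 1e-9)
  }
})

test_that("Mk ML is at a likelihood optimum and ER recovers the rate", {
  tr <- gen_tree(150, 0.1, 14)
  Q <- matrix(c(-0.05, 0.05, 0.05, -0.05), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  set.seed(15)
  est <- replicate(25, {
    ls <- gen_lifestyle(tr, Q, "a", sample.int(1e6, 1))
    if (length(unique(ls$tip_states)) < 2L) NA else
      fit_mk(tr, ls$tip_states, "ER")$rates[1L]
  })
  expect_gt(median(est, na.rm = TRUE), 0.025)
  expect_lt(median(est, na.rm = TRUE), 0.1)

  ls <- gen_lifestyle(tr, Q, "a", 16)
  fit <- fit_mk(tr, ls$tip_states, "ER")
  ts <- skullconv:::.tip_state_index(tr, ls$tip_states, fit$states)
  for (fac in c(0.5, 2)) {
    Qp <- fit$Q * fac
    expect_gte(fit$logLik + 1e-8,
               skullconv:::.mk_loglik(tr, ts$idx, unname(Qp), fit$pi))
  }
})

test_that("Fitch steps and retention index match exhaustive search", {
  # one clade's membership: a single step, RI = 1
  tr <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);")
  states <- c(A = "x", B = "x", C = "y", D = "y", E = "y", F = "y")
  expect_equal(fitch_steps(tr, states), 1L)
  expect_equal(retention_index(tr, states), 1)

  # alternating states on a ladder: maximal homoplasy, RI = 0
  lad <- ape::stree(6, "left")
  lad$edge.length <- rep(1, nrow(lad$edge))
  alt <- stats::setNames(rep(c("x", "y"), 3L), lad$tip.label)
  expect_equal(retention_index(lad, alt), 0)

  set.seed(17)
  for (rep in 1:30) {
    n <- sample(4:6, 1L)
    tr2 <- random_tree(n, seed = 400 + rep)
    k <- sample(2:3, 1L)
    st <- sample.int(k, n, replace = TRUE)
    if (length(unique(st)) < 2L) st[1:2] <- c(1L, 2L)
    names(st) <- tr2$tip.label
    expect_equal(fitch_steps(tr2, letters[st]),
                 oracle_fitch(tr2, st[tr2$tip.label], max(st)))
  }

  expect_error(retention_index(tr, stats::setNames(rep("x", 6),
                                                   names(states))),
               "invariant")
})

test_that("retention index agrees with phangorn", {
  set.seed(18)
  for (rep in 1:10) {
    tr <- random_tree(10L, seed = 500 + rep)
    st <- sample(c("p", "q"), 10L, replace = TRUE)
    if (length(unique(st)) < 2L) st[1:2] <- c("p", "q")
    names(st) <- tr$tip.label
    dat <- phangorn::phyDat(matrix(st[tr$tip.label], ncol = 1L,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("p", "q"))
    expect_equal(retention_index(tr, st), phangorn::RI(tr, dat))
  }
})
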