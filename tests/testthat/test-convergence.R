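test_that("C1 hits its boundary cases", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # identical focal tips with divergent ancestors: complete convergence
  y1 <- c(A = 0, B = 10, C = -10, D = 0)
  r1 <- c1_univariate(tr, y1, list("A", "D"))
  expect_equal(r1$C1, 1)

  # focal tips are the two extremes: no convergence
  y2 <- c(A = 0, B = 2, C = 2.1, D = 4)
  r2 <- c1_univariate(tr, y2, list("A", "D"))
  expect_equal(r2$C1, 0)

  expect_error(c1_univariate(tr, c(A = 1, B = 1, C = 1, D = 1),
                             list("A", "D")), "undefined")
  expect_error(c1_univariate(tr, y2, list("A")), "2 focal")
  expect_error(c1_univariate(tr, y2, list(c("A", "B"), c("B", "C"))),
               "disjoint")
})

test_that("C1 and C5 match exhaustive oracles on random small trees", {
  set.seed(1)
  for (case in 1:100) {
    n <- sample(4:6, 1L)
    tr <- random_tree(n, seed = 1000 + case)
    y <- stats::setNames(rnorm(n), tr$tip.label)
    focal <- list(tr$tip.label[1L], tr$tip.label[n])
    expect_equal(c1_univariate(tr, y, focal)$C1,
                 unname(oracle_c1(tr, y[tr$tip.label], focal)),
                 tolerance = 1e-7)
    ftips <- tr$tip.label[c(1L, n)]
    expect_equal(c5_univariate(tr, y, list(ftips))$C5,
                 oracle_c5(tr, y[tr$tip.label], ftips))
  }
})

test_that("C1 is affine invariant; C5 is monotone-affine invariant", {
  tr <- random_tree(10L, seed = 2)
  set.seed(3)
  y <- stats::setNames(rnorm(10), tr$tip.label)
  focal <- list(tr$tip.label[1:2], tr$tip.label[9:10])
  base1 <- c1_univariate(tr, y, focal)$C1
  base5 <- c5_univariate(tr, y, focal)$C5
  for (ab in list(c(3, 2), c(-0.5, 7), c(100, -4))) {
    yt <- ab[1L] * y + ab[2L]
    expect_equal(c1_univariate(tr, yt, focal)$C1, base1, tolerance = 1e-9)
    if (ab[1L] > 0)
      expect_equal(c5_univariate(tr, yt, focal)$C5, base5)
  }
  # per-pair values identical whether or not within-clade pairs would enter
  r <- c1_univariate(tr, y, focal)
  solo <- c1_univariate(tr, y, list(focal[[1L]][1L], focal[[2L]][1L]))
  shared <- paste(solo$per_pair$tip1, solo$per_pair$tip2)
  full <- paste(r$per_pair$tip1, r$per_pair$tip2)
  expect_equal(solo$per_pair$C1, r$per_pair$C1[match(shared, full)])
})

test_that("C5 counts region entries along branch segments", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  y <- c(A = 0, B = 2, C = 2.1, D = 4)
  # region spanning the full trait range: only the root entry
  r <- c5_univariate(tr, y, list(c("A", "D")))
  expect_equal(r$C5, 1L)
  expect_true(r$root_entry)

  # narrow region around two focal tips whose stem ancestors sit outside
  y2 <- c(A = 5, B = 0, C = 0.1, D = 5.2)
  r2 <- c5_univariate(tr, y2, list("A", "D"))
  expect_gte(r2$C5, 2L)
  expect_equal(r2$C5, oracle_c5(tr, y2[tr$tip.label], c("A", "D")))
})

test_that("C1/C5 simulation p-values behave under null and planted convergence", {
  tr <- gen_tree(40, 0.1, 4)
  tips <- tr$tip.label
  focal <- list(tips[1:3], tips[35:37])
  y <- simulate_bm(tr, 1, 0, 1, seed = 5)$tips[, 1L]
  names(y) <- tips
  r <- c1_pvalue(tr, y, focal, n_sim = 200L, seed = 6)
  expect_true(r$p > 0 && r$p <= 1)
  # monotonicity: a larger observed C1 cannot raise p on the same sims
  p_hi <- (sum(r$sim_C1 >= r$C1 + 0.1) + 1) / (r$n_sim + 1)
  expect_lte(p_hi, r$p)

  # planted convergence: two sizeable clades pulled to a shared optimum
  tr2 <- gen_tree(60, 0.1, 4)
  tips2 <- tr2$tip.label
  focal2 <- list(tips2[1:8], tips2[45:52])
  y2 <- simulate_bm(tr2, 1, 0, 1, seed = 5)$tips[, 1L]
  names(y2) <- tips2
  y2[unlist(focal2)] <- rnorm(16, 25, 0.3)
  r2 <- c1_pvalue(tr2, y2, focal2, n_sim = 200L, seed = 7)
  expect_lt(r2$p, 0.05)
  r5 <- c5_pvalue(tr2, y2, focal2, n_sim = 200L, seed = 7)
  expect_lt(r5$p, 0.05)
  expect_error(c5_pvalue(tr2, y2, focal2, n_sim = 0L), "positive")
})

test_that("minimum enclosing ellipse is tight and contains its points", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  e <- min_enclosing_ellipse(sq)
  expect_equal(e$center, c(0.5, 0.5), tolerance = 1e-4)
  expect_equal(unname(e$A), diag(2, 2), tolerance = 1e-3)  # circumcircle r^2 = 1/2

  set.seed(8)
  for (i in 1:10) {
    P <- matrix(rnorm(24), 12, 2)
    e2 <- min_enclosing_ellipse(P)
    q <- apply(P, 1L, function(x)
      drop(t(x - e2$center) %*% e2$A %*% (x - e2$center)))
    expect_lte(max(q), 1 + 1e-7)
  }
})

test_that("bivariate C5 walks 2-D segments into the focal ellipse", {
  tr <- gen_tree(40, 0.1, 9)
  tips <- tr$tip.label
  focal <- list(tips[1:4], tips[30:33])
  set.seed(10)
  b1 <- simulate_bm(tr, 1, 0, 1, seed = 11)$tips[, 1L]
  b2 <- simulate_bm(tr, 1, 0, 1, seed = 12)$tips[, 1L]
  # focal tips spanning far beyond the rest: everything stays inside the
  # ellipse, so the root entry is the only event
  w1 <- b1; w2 <- b2
  w1[unlist(focal)] <- c(-80, 80, 0, 0, -80, 80, 0, 0)
  w2[unlist(focal)] <- c(0, 0, -80, 80, 0, 0, -80, 80)
  all_in <- c5_bivariate(tr, cbind(w1, w2), focal)
  expect_true(all_in$root_entry)
  expect_equal(all_in$C5, 1L)

  # planted 2-clade convergence toward a shared 2-D optimum
  y1 <- b1; y2 <- b2
  y1[unlist(focal)] <- rnorm(8, 30, 0.1)
  y2[unlist(focal)] <- rnorm(8, -30, 0.1)
  conv <- c5_bivariate(tr, cbind(y1, y2), focal)
  expect_gte(conv$C5, 2L)
  # ellipse contains every focal tip
  Pf <- cbind(y1, y2)[match(unlist(focal), tips), ]
  q <- apply(Pf, 1L, function(x)
    drop(t(x - conv$ellipse$center) %*% conv$ellipse$A %*%
           (x - conv$ellipse$center)))
  expect_lte(max(q), 1 + 1e-7)

  # degenerate focal set falls back to a padded ellipse with a flag
  two <- c5_bivariate(tr, cbind(y1, y2), list(tips[1L], tips[2L]))
  expect_true(two$degenerate)
})

test_that("mean converging vector is the arithmetic mean of entering segments", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  y2 <- c(A = 5, B = 0, C = 0.1, D = 5.2)
  r <- c5_univariate(tr, y2, list("A", "D"))
  expect_equal(mean_convergence_vectors(r),
               mean(r$entering$child_val - r$entering$parent_val))

  fake <- structure(list(entering = data.frame(
    parent_x = c(0, 1, 2), parent_y = c(0, 0, 0),
    child_x = c(1, 3, 2), child_y = c(2, -2, 3))), class = "c5_result")
  expect_equal(unname(mean_convergence_vectors(fake)), c(1, 1))

  opp <- structure(list(entering = data.frame(
    parent_x = c(0, 0), parent_y = c(0, 0),
    child_x = c(1, -1), child_y = c(2, -2))), class = "c5_result")
  expect_equal(unname(mean_convergence_vectors(opp)), c(0, 0))

  none <- structure(list(entering = data.frame()), class = "c5_result")
  expect_error(mean_convergence_vectors(none), "no entering")
})
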