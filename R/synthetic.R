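# Synthetic studies with known ground truth: pure-birth tree, Mk lifestyle
# history, regime-switching OU traits, procedural cross-section masks.

#' Default configuration of the synthetic-study generator
#'
#' The defaults emulate the statistical structure of a fossorial-lepidosaur
#' skull-roof study: 99 tips, a three-state lifestyle (non-/semi-/fully
#' fossorial) evolving slowly enough to form clusters, and state-dependent
#' Ornstein-Uhlenbeck traits whose fully-fossorial optima are a compact
#' (96%), relatively thick (3.5%) skull roof with strong bone overlap
#' (60%), an elongate parietal (rfp 0.7), an elongate cranium (elo 3.0) and
#' a small diameter (5 mm), against non-fossorial optima of 80%, 2.2%,
#' 35%, 1.2, 2.1 and 9 mm (semi-fossorial intermediate). A neutral
#' Brownian-motion control trait (`ctrl`) carries no lifestyle structure.
#'
#' @param n_tips number of tips.
#' @param birth_rate pure-birth speciation rate (per My).
#' @param seed master seed.
#' @return a `sim_config` list; override any element by name via `...` in
#'   [gen_dataset()].
#' @export
sim_config <- function(n_tips = 99L, birth_rate = 0.1, seed = 1L) {
  states <- c("non", "semi", "fully")
  # entry into the fully fossorial state is rare and nearly irreversible,
  # so acquisitions form a few deep clades, as in the empirical system
  Q <- matrix(c(-0.016,  0.015,  0.001,
                 0.010, -0.022,  0.012,
                 0.0005, 0.0015, -0.002),
              3L, 3L, byrow = TRUE, dimnames = list(states, states))
  opt <- rbind(
    c     = c(non = 80,  semi = 85,  fully = 96),
    d     = c(non = 2.2, semi = 2.5, fully = 3.5),
    ovl   = c(non = 35,  semi = 40,  fully = 60),
    rfp   = c(non = 1.2, semi = 1.1, fully = 0.7),
    elo   = c(non = 2.1, semi = 2.3, fully = 3.0),
    dia   = c(non = 9,   semi = 8,   fully = 5))
  ou <- data.frame(alpha = rep(0.5, 6L),
                   sigma = c(1.0, 0.20, 3.5, 0.08, 0.15, 0.8),
                   row.names = rownames(opt))
  list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
       Q = Q, root_state = "non",
       # planted design: redraw the lifestyle history until the study
       # structure is realized (several independent fully-fossorial clades)
       min_fully = 10L, max_fully = 45L, min_clades = 3L,
       optima = opt, ou = ou,
       ctrl_sigma2 = 1,
       mask = list(height_px = 12L, aspect = 6L, margin = 2L),
       seed = as.integer(seed))
}

#' Simulate a pure-birth ultrametric tree
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate.
#' @param seed RNG seed.
#' @return an ultrametric [ape::phylo] tree with tips `t1..tn`.
#' @export
gen_tree <- function(n_tips, birth_rate = 0.1, seed = 1L) {
  if (n_tips < 3L) stop("need at least 3 tips")
  set.seed(seed)
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

#' Simulate a lifestyle character with full branch history
#'
#' Runs the Mk process from the root towards the tips, recording every
#' transition, so the realized history is available as ground truth for
#' validating stochastic character mapping.
#'
#' @param tree an [ape::phylo] tree.
#' @param Q rate matrix with state dimnames.
#' @param root_state state at the root.
#' @param seed RNG seed.
#' @return list with `tip_states` (named), `history` (per-edge named
#'   duration vectors, phytools maps convention), `node_states`,
#'   `n_transitions`.
#' @export
gen_lifestyle <- function(tree, Q, root_state = rownames(Q)[1L], seed = 1L) {
  set.seed(seed)
  states <- rownames(Q)
  k <- length(states)
  n <- .n_tips(tree)
  node_state <- character(n + tree$Nnode)
  node_state[n + 1L] <- root_state
  history <- vector("list", nrow(tree$edge))
  n_trans <- 0L
  for (e in .preorder_edges(tree)) {
    s <- node_state[tree$edge[e, 1L]]
    len <- tree$edge.length[e]
    segs <- numeric(0); labs <- character(0)
    t0 <- 0
    repeat {
      rate <- -Q[s, s]
      dt <- if (rate > 0) stats::rexp(1L, rate) else Inf
      if (t0 + dt >= len) {
        segs <- c(segs, len - t0); labs <- c(labs, s)
        break
      }
      segs <- c(segs, dt); labs <- c(labs, s)
      t0 <- t0 + dt
      pr <- Q[s, ]; pr[s] <- 0
      s <- sample(states, 1L, prob = pr)
      n_trans <- n_trans + 1L
    }
    names(segs) <- labs
    history[[e]] <- segs
    node_state[tree$edge[e, 2L]] <- s
  }
  tips <- node_state[seq_len(n)]
  names(tips) <- tree$tip.label
  list(tip_states = tips, history = history, node_states = node_state,
       n_transitions = n_trans)
}

# exact OU transition over one constant-regime segment
.ou_step <- function(x, theta, alpha, sigma, dt) {
  if (alpha == 0) return(x + stats::rnorm(length(x), 0, sigma * sqrt(dt)))
  e <- exp(-alpha * dt)
  v <- sigma^2 * (1 - e^2) / (2 * alpha)
  theta + (x - theta) * e + stats::rnorm(length(x), 0, sqrt(v))
}

#' Simulate state-switching OU traits along a lifestyle history
#'
#' Each trait follows an Ornstein-Uhlenbeck process whose optimum is set by
#' the lifestyle regime active at that point of the branch (exact Gaussian
#' transition per constant-regime segment; alpha = 0 reduces to Brownian
#' motion). A neutral BM control trait (`ctrl`) is appended.
#'
#' @param tree an [ape::phylo] tree.
#' @param lifestyle result of [gen_lifestyle()].
#' @param config a [sim_config()] list.
#' @param seed RNG seed.
#' @return data frame of per-tip traits (rownames/column `taxon`), columns
#'   `c` (%), `d`, `ovl`, `rfp`, `elo`, `dia`, `ctrl`, `lifestyle`.
#' @export
gen_traits <- function(tree, lifestyle, config = sim_config(), seed = 1L) {
  set.seed(seed)
  n <- .n_tips(tree)
  nn <- n + tree$Nnode
  traits <- rownames(config$optima)
  pre <- .preorder_edges(tree)
  out <- matrix(NA_real_, n, length(traits) + 1L,
                dimnames = list(tree$tip.label, c(traits, "ctrl")))
  for (tr in traits) {
    th <- config$optima[tr, ]
    a <- config$ou[tr, "alpha"]; sg <- config$ou[tr, "sigma"]
    val <- numeric(nn)
    val[n + 1L] <- th[[config$root_state]]
    for (e in pre) {
      x <- val[tree$edge[e, 1L]]
      seg <- lifestyle$history[[e]]
      for (i in seq_along(seg))
        x <- .ou_step(x, th[[names(seg)[i]]], a, sg, seg[i])
      val[tree$edge[e, 2L]] <- x
    }
    out[, tr] <- val[seq_len(n)]
  }
  ctrl <- simulate_bm(tree, config$ctrl_sigma2, 0, 1L)$tips[, 1L]
  out[, "ctrl"] <- ctrl[tree$tip.label]
  df <- as.data.frame(out)
  # keep physical traits in their valid ranges
  df$c <- pmin(pmax(df$c, 40), 99.8)
  df$d <- pmax(df$d, 0.5)
  df$rfp <- pmax(df$rfp, 0.2)
  df$elo <- pmax(df$elo, 1.2)
  df$dia <- pmax(df$dia, 1.5)
  df$taxon <- tree$tip.label
  df$lifestyle <- unname(lifestyle$tip_states[tree$tip.label])
  df
}

#' Generate one cross-section mask of controlled compactness
#'
#' Builds a solid rectangular bone silhouette and excavates cavity pixels
#' sampled from its eroded interior (never touching the outer boundary), so
#' the realized compactness is exact bookkeeping: 1 - cavities / area.
#'
#' @param target_compactness fraction in (0, 1].
#' @param height_px,width_px silhouette size in pixels (margin of
#'   background is added around it).
#' @param pixel_size mm per pixel.
#' @param bone,section_index passed to [section_mask()].
#' @param margin background margin in pixels.
#' @return a [section_mask] with attribute `realized_compactness`.
#' @export
gen_section_mask <- function(target_compactness, height_px, width_px,
                             pixel_size, bone = "frontal",
                             section_index = 1L, margin = 2L) {
  if (target_compactness <= 0 || target_compactness > 1)
    stop("target compactness must be in (0, 1]")
  h <- as.integer(height_px); w <- as.integer(width_px)
  if (h < 4L || w < 4L) stop("silhouette too small")
  nr <- h + 2L * margin; nc <- w + 2L * margin
  m <- matrix(0L, nr, nc)
  rows <- (margin + 1L):(margin + h)
  cols <- (margin + 1L):(margin + w)
  m[rows, cols] <- 1L
  area <- h * w
  n_cav <- round((1 - target_compactness) * area)
  interior <- as.matrix(expand.grid(rows[-c(1L, h)], cols[-c(1L, w)]))
  if (n_cav > nrow(interior))
    stop("target compactness unreachable for this geometry")
  if (n_cav > 0L) {
    pick <- interior[sample.int(nrow(interior), n_cav), , drop = FALSE]
    m[pick] <- 0L
  }
  msk <- section_mask(m, pixel_size, bone, section_index)
  attr(msk, "realized_compactness") <- 1 - n_cav / area
  msk
}

# per-taxon specimen geometry consistent with the planted traits; returns
# the 8 section rows plus derived bone placement
.specimen_geometry <- function(traits_row, config) {
  l_cran <- traits_row$elo * traits_row$dia
  Tlen <- l_cran
  L <- c(premaxilla = 0.10 * Tlen, nasal = 0.20 * Tlen,
         frontal = NA, parietal = NA)
  Lpar <- 0.55 * Tlen / (1 + traits_row$rfp)
  L["frontal"] <- traits_row$rfp * Lpar
  L["parietal"] <- Lpar
  bones <- names(L)
  start <- numeric(4L); start[1L] <- 0
  for (i in 2:4) {
    delta <- (2 / 3 - traits_row$ovl / 100) * (L[i - 1L] + L[i]) / 2
    secA2 <- start[i - 1L] + 2 * L[i - 1L] / 3
    start[i] <- secA2 + delta - L[i] / 3
  }
  sec <- data.frame(
    bone = rep(bones, each = 2L),
    section_index = rep(1:2, 4L),
    pos_mm = c(rbind(start + L / 3, start + 2 * L / 3)),
    bone_length_mm = rep(unname(L), each = 2L))
  span <- max(start + L) - 0   # profile: anterior premaxilla limit to
  sec$s_position <- sec$pos_mm / span  # posterior parietal limit
  list(sections = sec, dims = list(l_cran = l_cran,
                                   w_cran = traits_row$dia,
                                   h_cran = traits_row$dia),
       profile_length_mm = span)
}

#' Generate a complete synthetic study
#'
#' Writes (or returns in memory) everything the pipeline consumes: Newick
#' tree, specimen table, lifestyle table, one PNG mask per bone section,
#' and a ground-truth JSON with the planted trait values, realized mask
#' compactness, and the true lifestyle history summary.
#'
#' @param config a [sim_config()].
#' @param dir output directory; `NULL` keeps everything in memory.
#' @param write_masks write PNG mask files (requires `dir`).
#' @return a study bundle (list): `tree`, `traits` (planted), `lifestyle`,
#'   `specimens` (section table), `masks` (named list per taxon),
#'   `truth` (ground-truth list), `dir`.
#' @export
gen_dataset <- function(config = sim_config(), dir = NULL,
                        write_masks = !is.null(dir)) {
  seed <- config$seed
  tree <- gen_tree(config$n_tips, config$birth_rate, seed)
  # draw lifestyle histories until the planted design is realized
  for (try in 0:199) {
    ls <- gen_lifestyle(tree, config$Q, config$root_state,
                        seed + 1L + 1000L * try)
    nf <- sum(ls$tip_states == "fully")
    ncl <- length(.true_focal_clades(tree, ls))
    if (nf >= config$min_fully && nf <= config$max_fully &&
        ncl >= config$min_clades) break
    if (try == 199L) stop("could not realize the planted lifestyle design")
  }
  traits <- gen_traits(tree, ls, config, seed + 2L)

  set.seed(seed + 3L)
  bones <- c("premaxilla", "nasal", "frontal", "parietal")
  spec_rows <- vector("list", config$n_tips)
  masks <- vector("list", config$n_tips)
  names(masks) <- tree$tip.label
  realized <- matrix(NA_real_, config$n_tips, 8L,
                     dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(config$n_tips)) {
    tx <- tree$tip.label[i]
    row <- traits[tx, ]
    geo <- .specimen_geometry(row, config)
    d_abs <- (2 * row$d) / 100 * row$dia  # constant d_rel = 2 d -> integral d
    h_px <- config$mask$height_px
    px <- d_abs / h_px
    mlist <- vector("list", 8L)
    names(mlist) <- paste0(rep(bones, each = 2L), rep(1:2, 4L))
    for (j in seq_len(8L)) {
      msk <- gen_section_mask(row$c / 100, h_px, h_px * config$mask$aspect,
                              px, bone = rep(bones, each = 2L)[j],
                              section_index = rep(1:2, 4L)[j],
                              margin = config$mask$margin)
      mlist[[j]] <- msk
      realized[i, j] <- attr(msk, "realized_compactness")
    }
    masks[[tx]] <- mlist
    sr <- geo$sections
    sr$taxon <- tx
    sr$l_cran <- geo$dims$l_cran
    sr$w_cran <- geo$dims$w_cran
    sr$h_cran <- geo$dims$h_cran
    sr$pixel_size_mm <- px
    sr$lifestyle <- row$lifestyle
    spec_rows[[i]] <- sr
  }
  specimens <- do.call(rbind, spec_rows)
  specimens <- specimens[, c("taxon", "bone", "section_index", "s_position",
                             "bone_length_mm", "l_cran", "w_cran", "h_cran",
                             "pixel_size_mm", "lifestyle")]

  # true focal clades: fully-fossorial tips grouped by the acquisition
  # branch of the realized history
  truth_clades <- .true_focal_clades(tree, ls)
  truth <- list(seed = seed, n_tips = config$n_tips,
                n_transitions = ls$n_transitions,
                tip_lifestyle = as.list(ls$tip_states),
                planted_traits = traits[, c("taxon", "c", "d", "ovl", "rfp",
                                            "elo", "dia", "ctrl")],
                realized_compactness = rowMeans(realized),
                focal_clades = truth_clades)
  # planted traits are ground truth, not measurements: the pipeline's
  # measure stage recovers them from the masks
  bundle <- list(tree = tree, traits = NULL, traits_true = traits,
                 extra_traits = data.frame(taxon = traits$taxon,
                                           ctrl = traits$ctrl),
                 lifestyle = ls, specimens = specimens, masks = masks,
                 truth = truth, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(write_newick(tree), file.path(dir, "tree.nwk"))
    utils::write.csv(specimens, file.path(dir, "specimens.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(taxon = names(ls$tip_states),
                                lifestyle = unname(ls$tip_states)),
                     file.path(dir, "lifestyle.csv"), row.names = FALSE)
    utils::write.csv(traits, file.path(dir, "traits_true.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$extra_traits, file.path(dir, "extra_traits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (write_masks) {
      mdir <- file.path(dir, "masks")
      dir.create(mdir, showWarnings = FALSE)
      for (tx in names(masks))
        for (nm in names(masks[[tx]]))
          write_mask(masks[[tx]][[nm]],
                     file.path(mdir, paste0(tx, "_", nm, ".png")))
    }
  }
  bundle
}

# group fully-fossorial tips by their nearest ancestral branch on which the
# realized history entered the "fully" state (and stayed until the child end)
.true_focal_clades <- function(tree, ls, focal_state = "fully") {
  n <- .n_tips(tree)
  paths <- .root_paths(tree)
  edge_of <- integer(n + tree$Nnode)
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  # acquisition branch: parent-side state != focal, child-side == focal
  acq <- which(vapply(seq_len(nrow(tree$edge)), function(e) {
    seg <- ls$history[[e]]
    names(seg)[1L] != focal_state && names(seg)[length(seg)] == focal_state
  }, logical(1)))
  acq_child <- tree$edge[acq, 2L]
  focal_tips <- which(ls$tip_states == focal_state)
  if (!length(focal_tips)) return(list())
  grp <- vapply(focal_tips, function(tip) {
    anc <- rev(paths[[tip]])
    hit <- anc[anc %in% acq_child]
    if (length(hit)) as.character(hit[1L]) else "root"
  }, character(1))
  split(tree$tip.label[focal_tips], grp)
}
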