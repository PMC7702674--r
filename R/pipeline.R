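# Study bundle loading, the end-to-end analysis pipeline, and report output.

#' Default pipeline configuration
#'
#' Permutation and simulation counts default to full-study values (10,000
#' RRPP permutations, 10,000 stochastic maps, 30,000 BM simulations); any
#' reduced run is labelled in the report.
#'
#' @param n_perm RRPP permutations.
#' @param n_maps stochastic character maps.
#' @param n_sim BM simulations for the C1/C5 null.
#' @param seed master seed; every stage derives its stream from it.
#' @param trait_cols trait columns analysed.
#' @param alpha significance level used in trait selection for the PCA.
#' @return a named list.
#' @export
pipeline_config <- function(n_perm = 10000L, n_maps = 10000L,
                            n_sim = 30000L, seed = 1L,
                            trait_cols = c("c", "d", "ovl", "rfp", "elo",
                                           "dia", "ctrl"),
                            alpha = 0.05) {
  list(n_perm = as.integer(n_perm), n_maps = as.integer(n_maps),
       n_sim = as.integer(n_sim), seed = as.integer(seed),
       trait_cols = trait_cols, alpha = alpha,
       reduced = n_perm < 10000L || n_maps < 10000L || n_sim < 30000L)
}

#' Load a study bundle from disk
#'
#' Reads the tree (Newick), the specimen section table, the lifestyle
#' table and, when present, the mask PNGs; validates schemas and
#' cross-references every specimen taxon against the tree.
#'
#' @param dir directory written by [gen_dataset()] or following the same
#'   layout (`tree.nwk`, `specimens.csv`, `lifestyle.csv`, `masks/`).
#' @param config a [pipeline_config()].
#' @param load_masks read mask PNGs (default: when `masks/` exists).
#' @return a study bundle list with `tree`, `specimens`, `lifestyle`,
#'   `masks` (or NULL), `traits` (NULL until measured), `config`,
#'   `unmatched` (taxa absent from the tree).
#' @export
load_dataset <- function(dir, config = pipeline_config(),
                         load_masks = dir.exists(file.path(dir, "masks"))) {
  tree_file <- file.path(dir, "tree.nwk")
  spec_file <- file.path(dir, "specimens.csv")
  ls_file <- file.path(dir, "lifestyle.csv")
  for (f in c(tree_file, spec_file, ls_file))
    if (!file.exists(f)) stop("missing input file: ", f)
  tree <- parse_newick(readLines(tree_file))
  specimens <- utils::read.csv(spec_file, stringsAsFactors = FALSE)
  need <- c("taxon", "bone", "section_index", "s_position", "bone_length_mm",
            "l_cran", "w_cran", "h_cran", "pixel_size_mm", "lifestyle")
  miss <- setdiff(need, names(specimens))
  if (length(miss))
    stop("specimens.csv lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(specimens$bone_length_mm) |
               specimens$bone_length_mm <= 0)
  if (length(bad))
    stop("specimens.csv row ", bad[1L], ": non-positive bone_length_mm")
  lifestyle <- utils::read.csv(ls_file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "lifestyle") %in% names(lifestyle)))
    stop("lifestyle.csv needs columns taxon, lifestyle")
  unmatched <- setdiff(unique(specimens$taxon), tree$tip.label)
  if (length(unmatched))
    warning("taxa not on the tree: ", paste(unmatched, collapse = ", "))
  masks <- NULL
  if (load_masks) {
    mdir <- file.path(dir, "masks")
    masks <- lapply(split(specimens, specimens$taxon), function(sp) {
      out <- list()
      for (r in seq_len(nrow(sp))) {
        nm <- paste0(sp$bone[r], sp$section_index[r])
        f <- file.path(mdir, paste0(sp$taxon[r], "_", nm, ".png"))
        if (file.exists(f))
          out[[nm]] <- read_mask(f, sp$pixel_size_mm[r], sp$bone[r],
                                 sp$section_index[r])
      }
      out
    })
  }
  extra <- NULL
  ef <- file.path(dir, "extra_traits.csv")
  if (file.exists(ef)) extra <- utils::read.csv(ef, stringsAsFactors = FALSE)
  list(tree = tree, specimens = specimens, lifestyle = lifestyle,
       masks = masks, traits = NULL, extra_traits = extra, config = config,
       unmatched = unmatched, dir = dir)
}

#' Measure all specimens of a bundle
#'
#' Runs [specimen_traits()] for every taxon with masks, producing the tidy
#' trait table the statistical stages consume.
#'
#' @param bundle a study bundle ([load_dataset()] or [gen_dataset()]).
#' @return the bundle with `traits` filled (columns taxon, c (%), c_log,
#'   d, ovl, rfp, elo, dia, lifestyle).
#' @export
measure_bundle <- function(bundle) {
  if (is.null(bundle$masks)) stop("bundle has no masks to measure")
  specs <- split(bundle$specimens, bundle$specimens$taxon)
  rows <- lapply(names(bundle$masks), function(tx) {
    sp <- specs[[tx]]
    tv <- specimen_traits(bundle$masks[[tx]], sp,
                          list(l_cran = sp$l_cran[1L], w_cran = sp$w_cran[1L],
                               h_cran = sp$h_cran[1L]),
                          taxon = tx)
    tv$lifestyle <- sp$lifestyle[1L]
    tv
  })
  traits <- do.call(rbind, rows)
  traits$c <- traits$c * 100   # report compactness in percent
  # tip traits that do not come from masks (e.g. a neutral control trait)
  if (!is.null(bundle$extra_traits)) {
    et <- bundle$extra_traits
    traits <- cbind(traits,
                    et[match(traits$taxon, et$taxon),
                       setdiff(names(et), "taxon"), drop = FALSE])
  }
  rownames(traits) <- traits$taxon
  bundle$traits <- traits
  bundle
}

#' Run the full analysis pipeline on a study bundle
#'
#' Stages: measure masks (skipped when a trait table is already present),
#' phylogenetically informed ANOVA per trait, Pagel's lambda signal,
#' stochastic mapping of the binarized lifestyle with branch posteriors and
#' focal-clade derivation, C1/C5 convergence per trait, PCA of the
#' converging signal-bearing traits, Retention Index and
#' phylogeny-vs-lifestyle two-block PLS. Deterministic given
#' `bundle$config$seed`.
#'
#' @param bundle a study bundle; `bundle$traits` may be supplied directly
#'   (data frame with `taxon`, trait columns, `lifestyle`) to start at the
#'   ANOVA stage.
#' @param config overrides `bundle$config`.
#' @return a `skullconv_report` list with per-stage results and a `log`.
#' @export
run_full_pipeline <- function(bundle, config = NULL) {
  cfg <- if (!is.null(config)) config
         else if (!is.null(bundle$config)) bundle$config
         else pipeline_config()
  log <- c(sprintf("seed=%d n_perm=%d n_maps=%d n_sim=%d%s", cfg$seed,
                   cfg$n_perm, cfg$n_maps, cfg$n_sim,
                   if (isTRUE(cfg$reduced)) " [reduced counts]" else ""))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  tree <- bundle$tree
  if (is.null(bundle$traits)) bundle <- stage("measure", measure_bundle(bundle))
  traits <- bundle$traits
  traits <- traits[match(tree$tip.label, traits$taxon), ]
  lifestyle <- stats::setNames(traits$lifestyle, traits$taxon)
  trait_cols <- intersect(cfg$trait_cols, names(traits))
  vcv <- phylo_vcv(tree)

  anova <- list(); lambda <- list()
  for (i in seq_along(trait_cols)) {
    tc <- trait_cols[i]
    y <- stats::setNames(traits[[tc]], traits$taxon)
    anova[[tc]] <- stage(paste0("anova:", tc),
      phylo_anova_rrpp(y, lifestyle, tree, n_perm = cfg$n_perm,
                       seed = cfg$seed + 100L + i, vcv = vcv))
    lambda[[tc]] <- stage(paste0("signal:", tc),
                          fit_lambda_ml(tree, y, vcv = vcv))
  }

  binary <- ifelse(lifestyle == "fully", "fully", "other")
  anc <- stage("ancmap", {
    mk <- fit_mk(tree, binary, flavour = "ER")
    maps <- simmap_sample(tree, binary, mk, n_maps = cfg$n_maps,
                          seed = cfg$seed + 200L)
    post <- branch_posterior(maps, "fully")
    clades <- derive_focal_clades(maps, "fully", post)
    list(mk = mk, posterior = post, focal_clades = clades,
         ri = tryCatch(retention_index(tree, binary), error = function(e) NA))
  })

  converge <- list()
  focal <- anc$focal_clades
  for (i in seq_along(trait_cols)) {
    tc <- trait_cols[i]
    y <- stats::setNames(traits[[tc]], traits$taxon)
    converge[[tc]] <- stage(paste0("converge:", tc), {
      if (length(focal) >= 2L) {
        c1 <- c1_pvalue(tree, y, focal, n_sim = cfg$n_sim,
                        seed = cfg$seed + 300L + i)
        c5 <- c5_pvalue(tree, y, focal, n_sim = cfg$n_sim,
                        seed = cfg$seed + 300L + i)
        list(C1 = c1$C1, p_C1 = c1$p, C5 = c5$C5, p_C5 = c5$p)
      } else list(C1 = NA, p_C1 = NA, C5 = NA, p_C5 = NA)
    })
  }

  conv_tab <- data.frame(
    trait = trait_cols,
    lambda = vapply(lambda, `[[`, numeric(1), "lambda"),
    F = vapply(anova, `[[`, numeric(1), "F"),
    p_anova = vapply(anova, `[[`, numeric(1), "p"),
    C1 = vapply(converge, function(x) as.numeric(x$C1), numeric(1)),
    p_C1 = vapply(converge, function(x) as.numeric(x$p_C1), numeric(1)),
    C5 = vapply(converge, function(x) as.numeric(x$C5), numeric(1)),
    p_C5 = vapply(converge, function(x) as.numeric(x$p_C5), numeric(1)),
    row.names = NULL)

  sel <- with(conv_tab, trait[!is.na(p_C1) & p_C1 < cfg$alpha &
                              p_anova < cfg$alpha])
  sel <- setdiff(sel, "ctrl")
  if (length(sel) < 2L) sel <- setdiff(trait_cols, "ctrl")
  pca <- stage("pca",
    pca_traits(traits[, sel, drop = FALSE], standardize = TRUE))

  pls <- stage("pls", pls_phylo_groups(tree, binary,
                                       n_perm = min(cfg$n_perm, 1000L),
                                       seed = cfg$seed + 400L))

  structure(list(traits = traits, anova = anova, lambda = lambda,
                 ancmap = anc, converge = converge, summary = conv_tab,
                 pca = pca, pca_traits = sel, pls = pls,
                 ri = anc$ri, config = cfg, log = log),
            class = "skullconv_report")
}

#' @export
print.skullconv_report <- function(x, ...) {
  cat("skullconv pipeline report\n")
  cat(x$log, sep = "\n")
  cat(sprintf("focal clades: %d | RI = %.3f | r-PLS = %.3f (p = %.3g)\n",
              length(x$ancmap$focal_clades), x$ri, x$pls$r_pls, x$pls$p))
  print(x$summary, digits = 3)
  cat(sprintf("PCA on (%s): PC1 = %.1f%% of variance\n",
              paste(x$pca_traits, collapse = ", "),
              100 * x$pca$var_frac[1L]))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits CSV tables (trait table, per-trait summary, pairwise ANOVA, PCA
#' loadings and scores), a JSON summary, a run log, and optional plots
#' (LOESS compactness profile and the bivariate morphospace).
#'
#' @param report a `skullconv_report`.
#' @param dir output directory (created if needed).
#' @param plots also write PDF figures.
#' @param bundle the measured bundle (needed for the profile plot).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, plots = FALSE, bundle = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  pw <- do.call(rbind, lapply(names(report$anova), function(tc) {
    p <- report$anova[[tc]]$pairwise
    if (is.null(p)) return(NULL)
    cbind(trait = tc, p)
  }))
  if (!is.null(pw))
    utils::write.csv(pw, file.path(dir, "anova_pairwise.csv"),
                     row.names = FALSE)
  utils::write.csv(as.data.frame(report$pca$loadings),
                   file.path(dir, "pca_loadings.csv"))
  utils::write.csv(as.data.frame(report$pca$scores),
                   file.path(dir, "pca_scores.csv"))
  summ <- list(seed = report$config$seed,
               reduced_counts = isTRUE(report$config$reduced),
               ri = report$ri, r_pls = report$pls$r_pls,
               p_pls = report$pls$p,
               n_focal_clades = length(report$ancmap$focal_clades),
               pc1_var_frac = report$pca$var_frac[[1L]],
               traits = report$summary)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(dir, "run_log.txt"))
  if (plots) {
    grDevices::pdf(file.path(dir, "morphospace.pdf"), width = 6, height = 6)
    tr <- report$traits
    plot(tr$dia, tr$c, col = factor(tr$lifestyle), pch = 19,
         xlab = "skull diameter [mm]", ylab = "compactness [%]",
         main = "bivariate morphospace")
    grDevices::dev.off()
  }
  invisible(dir)
}
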