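#' Build a normalized cranial profile from ordered landmarks
#'
#' The skull-roof profile is the polyline of shortest straight lines through
#' the anterior premaxilla limit, the eight section intersections, and the
#' posterior parietal limit. Positions are reported as cumulative chord
#' length normalized to \[0, 1\].
#'
#' @param landmarks numeric matrix (rows = landmarks in anteroposterior
#'   order, columns = 2-D or 3-D coordinates) or a numeric vector of
#'   positions along a line.
#' @return object of class `cranial_profile`: list with `s` (normalized
#'   positions), `length_mm` (total polyline length in input units) and the
#'   landmark coordinates.
#' @export
build_profile <- function(landmarks) {
  if (is.vector(landmarks) && is.numeric(landmarks))
    landmarks <- matrix(landmarks, ncol = 1L)
  if (!is.matrix(landmarks) || nrow(landmarks) < 2L)
    stop("need at least 2 landmarks")
  seg <- sqrt(rowSums((landmarks[-1L, , drop = FALSE] -
                       landmarks[-nrow(landmarks), , drop = FALSE])^2))
  if (any(seg == 0)) stop("duplicated consecutive landmarks (zero-length segment)")
  cum <- c(0, cumsum(seg))
  structure(list(s = cum / cum[length(cum)], length_mm = cum[length(cum)],
                 landmarks = landmarks),
            class = "cranial_profile")
}

#' Anteroposterior bone overlap
#'
#' Overlap between an anterior bone A and its posterior neighbour B,
#' computed from their lengths and the signed distance Delta between A's
#' posterior cross-section (at 2/3 of L_A) and B's anterior cross-section
#' (at 1/3 of L_B):
#' \deqn{ovl = 100 (2/3 - 2\Delta/(L_A + L_B))}
#' 100% corresponds to fully centred alignment of the two bones; 0% to B's
#' anterior limit coinciding with A's posterior limit. Values are not
#' clamped: a gap gives a negative overlap.
#'
#' @param L_A,L_B anteroposterior bone lengths, mm (> 0).
#' @param delta signed distance (mm) between A's posterior section and B's
#'   anterior section, positive when B's section lies posterior to A's.
#' @return overlap in percent.
#' @export
overlap <- function(L_A, L_B, delta) {
  if (any(L_A <= 0) || any(L_B <= 0)) stop("bone lengths must be positive")
  100 * (2 / 3 - 2 * delta / (L_A + L_B))
}

#' Scalar skull traits: diameter, elongation, frontal/parietal ratio
#'
#' `dia` is the geometric mean of cranial width and height (a size
#' descriptor robust to lifestyle-driven width/height changes), `elo` the
#' size-normalized skull length, `rfp` the frontal-to-parietal length ratio.
#'
#' @param l_cran,w_cran,h_cran cranial length, width, height in mm (> 0).
#' @param L_frontal,L_parietal bone lengths in mm (> 0).
#' @return named list with `dia` (mm), `elo`, `rfp`.
#' @export
scalar_traits <- function(l_cran, w_cran, h_cran, L_frontal, L_parietal) {
  vals <- c(l_cran, w_cran, h_cran, L_frontal, L_parietal)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dimensions and lengths must be positive")
  dia <- sqrt(w_cran * h_cran)
  list(dia = dia, elo = l_cran / dia, rfp = L_frontal / L_parietal)
}

#' Integral of relative skull-roof thickness over the anterior profile half
#'
#' Integrates the piecewise-linear interpolant of relative thickness
#' d_rel(s) over s in \[0, 0.5\]. No measurement exists at s = 0, so the
#' default extrapolates the first measured value as a constant back to 0;
#' alternatively the integral can be truncated at the first section.
#'
#' @param s strictly increasing section positions in \[0, 1\].
#' @param d_rel relative thickness (% of skull diameter) at each position.
#' @param extrapolate `"constant"` (default) or `"truncate"` for the
#'   anterior boundary.
#' @return the integral (units of d_rel, i.e. %).
#' @export
thickness_integral <- function(s, d_rel, extrapolate = c("constant", "truncate")) {
  extrapolate <- match.arg(extrapolate)
  if (length(s) != length(d_rel)) stop("`s` and `d_rel` lengths differ")
  if (length(s) < 2L) stop("need at least 2 measurement positions")
  if (any(diff(s) <= 0)) stop("`s` must be strictly increasing")
  if (any(s < 0 | s > 1)) stop("`s` must lie in [0, 1]")
  if (min(s) > 0.5) stop("no section at s <= 0.5: integral undefined")
  upper <- 0.5
  # value at 0.5 by interpolation between flanking sections (or last value
  # if all sections are anterior to 0.5)
  f <- stats::approxfun(s, d_rel, rule = 2)
  ss <- sort(unique(c(s[s < upper], upper)))
  vv <- f(ss)
  area <- sum(diff(ss) * (vv[-1L] + vv[-length(vv)]) / 2)
  if (extrapolate == "constant" && s[1L] > 0)
    area <- area + s[1L] * d_rel[1L]
  area
}

#' Log-transformed compactness
#'
#' Compactness aggregates tightly between 95 and 100%; the transform
#' \deqn{c_{log} = -\log_{10}((105 - c)/105)}
#' spreads that interval. The conversion is dilated horizontally by 5% so
#' the function has no asymptote at c = 100%. The logarithm base (10) is a
#' package constant; any base only rescales the axis.
#'
#' @param c_percent compactness in percent, in \[0, 105\].
#' @return dimensionless log-compactness; 0 maps to 0, monotone increasing.
#' @export
log_compactness <- function(c_percent) {
  if (any(c_percent > 105) || any(c_percent < 0))
    stop("compactness must lie in [0, 105] percent")
  -log10((105 - c_percent) / 105)
}

#' LOESS curve of a trait along the cranial profile
#'
#' Locally weighted linear regression (tricube weights) of trait values
#' against section position, evaluated on a regular grid over \[0, 1\].
#' Used for per-lifestyle compactness/thickness profile curves.
#'
#' @param positions section positions in \[0, 1\].
#' @param values trait values.
#' @param span LOESS span in (0, 1].
#' @param n_grid number of grid points.
#' @return list with `grid` and `fitted`.
#' @export
loess_profile <- function(positions, values, span = 0.75, n_grid = 100L) {
  if (length(positions) < 4L) stop("need at least 4 points for a LOESS fit")
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]")
  fit <- stats::loess(values ~ positions, degree = 1, span = span,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(positions), max(positions), length.out = n_grid)
  list(grid = grid, fitted = as.numeric(stats::predict(fit, grid)))
}

#' All skull-roof traits for one specimen
#'
#' Orchestrates the full measurement chain: mean compactness over the eight
#' cross-sections, mean anteroposterior overlap over the three bone pairs
#' (premaxilla-nasal, nasal-frontal, frontal-parietal), the relative
#' thickness integral, and the scalar traits. Missing sections are
#' tolerated: means are taken over available sections and the result is
#' flagged.
#'
#' @param masks named list of up to 8 [section_mask]s; names
#'   `<bone><index>`, e.g. `"frontal1"`.
#' @param sections data frame with columns `bone`, `section_index`,
#'   `s_position` (normalized profile position of each section) and
#'   `bone_length_mm`.
#' @param dims named list/vector with `l_cran`, `w_cran`, `h_cran` (mm).
#' @param taxon taxon id to stamp on the result.
#' @param profile_length_mm physical length of the cranial profile used to
#'   convert normalized positions to mm. Default `NULL` estimates it from
#'   the section geometry itself: sections of one bone sit at 1/3 and 2/3
#'   of its length, so L/3 = (s2 - s1) * total; the estimate is averaged
#'   over bones.
#' @param extrapolate passed to [thickness_integral()].
#' @return a one-row data frame (trait vector) with columns `taxon`, `c`
#'   (fraction), `c_log`, `d` (%), `ovl` (%), `rfp`, `elo`, `dia` (mm),
#'   `n_sections`, `missing` (logical flag).
#' @export
specimen_traits <- function(masks, sections, dims, taxon = "specimen",
                            profile_length_mm = NULL,
                            extrapolate = "constant") {
  bones <- c("premaxilla", "nasal", "frontal", "parietal")
  stopifnot(all(c("bone", "section_index", "s_position", "bone_length_mm")
                %in% names(sections)))
  key <- paste0(sections$bone, sections$section_index)
  rownames(sections) <- key

  have <- intersect(paste0(rep(bones, each = 2L), rep(1:2, 4L)), names(masks))
  if (length(have) == 0L) stop("no section masks supplied")
  missing_any <- length(have) < 8L

  c_vals <- vapply(masks[have], compactness, numeric(1))
  d_abs  <- vapply(masks[have], mean_thickness, numeric(1))

  dims <- as.list(dims)
  L <- function(b) sections$bone_length_mm[match(b, sections$bone)]
  sc <- scalar_traits(dims$l_cran, dims$w_cran, dims$h_cran,
                      L("frontal"), L("parietal"))

  if (is.null(profile_length_mm)) {
    est <- vapply(bones, function(b) {
      s1 <- sections[paste0(b, 1L), "s_position"]
      s2 <- sections[paste0(b, 2L), "s_position"]
      sections$bone_length_mm[match(b, sections$bone)] / (3 * (s2 - s1))
    }, numeric(1))
    profile_length_mm <- mean(est, na.rm = TRUE)
  }

  ovl_pairs <- vapply(seq_len(3L), function(i) {
    a <- bones[i]; b <- bones[i + 1L]
    dmm <- (sections[paste0(b, 1L), "s_position"] -
            sections[paste0(a, 2L), "s_position"]) * profile_length_mm
    overlap(L(a), L(b), dmm)
  }, numeric(1))

  s_pos <- sections[have, "s_position"]
  ord <- order(s_pos)
  d_rel <- d_abs / sc$dia * 100
  d_int <- thickness_integral(s_pos[ord], d_rel[ord], extrapolate = extrapolate)

  c_mean <- mean(c_vals)
  data.frame(taxon = taxon,
             c = c_mean,
             c_log = log_compactness(100 * c_mean),
             d = d_int,
             ovl = mean(ovl_pairs),
             rfp = sc$rfp, elo = sc$elo, dia = sc$dia,
             n_sections = length(have),
             missing = missing_any,
             stringsAsFactors = FALSE)
}
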