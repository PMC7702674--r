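#' Section mask constructor
#'
#' A `section_mask` holds one binary transverse cross-section of a skull-roof
#' bone: an integer raster (1 = bone tissue, 0 = background), the physical
#' pixel size in mm, the bone identity and the section index (1 = section at
#' one third of the anteroposterior bone length, 2 = at two thirds).
#'
#' @param raster integer/logical matrix, foreground (bone) coded as 1/TRUE.
#' @param pixel_size physical edge length of one pixel in mm; must be > 0.
#' @param bone one of `"premaxilla"`, `"nasal"`, `"frontal"`, `"parietal"`.
#' @param section_index 1 or 2.
#' @return an object of class `section_mask`.
#' @export
section_mask <- function(raster, pixel_size,
                         bone = c("premaxilla", "nasal", "frontal", "parietal"),
                         section_index = 1L) {
  bone <- match.arg(bone)
  if (!is.matrix(raster)) stop("`raster` must be a matrix")
  m <- matrix(as.integer(raster != 0), nrow(raster), ncol(raster))
  if (sum(m) == 0L) stop("mask has no foreground (bone) pixels")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (mm/pixel)")
  if (!section_index %in% c(1L, 2L)) stop("`section_index` must be 1 or 2")
  structure(list(raster = m, pixel_size = pixel_size, bone = bone,
                 section_index = as.integer(section_index)),
            class = "section_mask")
}

#' @export
print.section_mask <- function(x, ...) {
  cat(sprintf("section_mask: %s #%d, %d x %d px @ %.4g mm/px, %d bone px\n",
              x$bone, x$section_index, nrow(x$raster), ncol(x$raster),
              x$pixel_size, sum(x$raster)))
  invisible(x)
}

.mask_raster <- function(x) {
  if (inherits(x, "section_mask")) x$raster
  else if (is.matrix(x)) matrix(as.integer(x != 0), nrow(x), ncol(x))
  else stop("expected a section_mask or a binary matrix")
}

#' Read a binary cross-section mask from a PNG or TIFF file
#'
#' Single-channel images are expected; any non-zero grey value counts as
#' bone. Multi-channel images are collapsed by their first channel.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @inheritParams section_mask
#' @return a [section_mask].
#' @export
read_mask <- function(path, pixel_size, bone, section_index) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF masks requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported mask format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  section_mask(img > 0, pixel_size, bone, section_index)
}

#' Write a mask as an 8-bit greyscale PNG (background 0, bone 255)
#' @param mask a [section_mask] or binary matrix.
#' @param path output .png path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- .mask_raster(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Otsu threshold convenience for greyscale rasters
#'
#' Masks normally arrive binary; this helper binarizes a greyscale raster by
#' Otsu's criterion for the occasional unthresholded input.
#'
#' @param gray numeric matrix in \[0, 1\].
#' @return logical matrix (TRUE = foreground).
#' @export
otsu_threshold <- function(gray) {
  if (!is.matrix(gray)) stop("`gray` must be a matrix")
  thr <- EBImage::otsu(EBImage::Image(gray), range = range(gray))
  gray > thr
}

#' Fill interior cavities of a binary mask
#'
#' Background components not connected to the raster border are considered
#' interior ("inside the outer bone limits") and are converted to foreground.
#' Background connectivity is 4-neighbour, foreground 8-neighbour.
#'
#' @param mask a [section_mask] or binary matrix.
#' @return integer matrix with cavities filled.
#' @export
fill_mask_holes <- function(mask) {
  m <- .mask_raster(mask)
  f <- EBImage::fillHull(EBImage::Image(m))
  matrix(as.integer(EBImage::imageData(f) != 0), nrow(m), ncol(m))
}

#' Cross-section compactness
#'
#' Ratio of bone-tissue pixels to all pixels inside the outer bone limits
#' (the hole-filled silhouette). A solid section returns 1; interior
#' cavities lower the value.
#'
#' @param mask a [section_mask] or binary matrix with at least one
#'   foreground pixel.
#' @return compactness as a fraction in (0, 1].
#' @export
compactness <- function(mask) {
  m <- .mask_raster(mask)
  fg <- sum(m)
  if (fg == 0L) stop("mask has no foreground pixels")
  fg / sum(fill_mask_holes(m))
}

#' Local-thickness map of a binary mask
#'
#' Interior cavities are filled first, then each foreground pixel receives
#' the diameter of the largest inscribed disc that contains it
#' (Hildebrand-Ruegsegger local thickness in 2-D). Disc radii come from the
#' Euclidean distance transform; a pixel p belongs to the disc centred at q
#' when |p - q| < r(q).
#'
#' @param mask a [section_mask] or binary matrix.
#' @return numeric matrix of thickness values in pixels (0 on background).
#' @export
local_thickness <- function(mask) {
  m <- fill_mask_holes(mask)
  edt <- EBImage::imageData(EBImage::distmap(EBImage::Image(m)))
  paint_local_thickness(m, matrix(as.numeric(edt), nrow(m), ncol(m)))
}

#' Mean local thickness of a cross-section
#'
#' Mean of the local-thickness map over foreground pixels, scaled to mm.
#' Cavities are filled before the computation, so a hollow and a solid
#' section of identical outline give the same value.
#'
#' @param mask a [section_mask] (needed for its pixel size) or a binary
#'   matrix with `pixel_size` supplied.
#' @param pixel_size mm per pixel; taken from the mask when omitted.
#' @return mean thickness in mm.
#' @export
mean_thickness <- function(mask, pixel_size = NULL) {
  if (is.null(pixel_size)) {
    if (!inherits(mask, "section_mask"))
      stop("supply `pixel_size` when `mask` is a bare matrix")
    pixel_size <- mask$pixel_size
  }
  th <- local_thickness(mask)
  fg <- fill_mask_holes(mask) == 1L
  if (!any(fg)) stop("mask has no foreground pixels")
  mean(th[fg]) * pixel_size
}
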