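#' Configuration for unsupervised pseudo-mask extraction
#'
#' Parameters of the contour-based extraction stage. The defaults mirror the
#' settings used for the real SEM data: a 9x9 Gaussian smoothing kernel,
#' hysteresis thresholds of 50 (weak) and 100 (strong) on the Sobel gradient
#' magnitude of the 0-255 image, and a contour line width of 1 pixel.
#'
#' @param gaussian_kernel odd kernel side length for Gaussian smoothing.
#' @param low_threshold weak-edge hysteresis threshold, gradient-magnitude
#'   units of the 8-bit image.
#' @param high_threshold strong-edge threshold; must exceed `low_threshold`.
#' @param contour_width edge line width in pixels; widths above 1 dilate the
#'   edge map.
#' @param open_radius structuring-element radius for contour cleanup: gaps
#'   up to this scale are sealed and speck components smaller than the
#'   element footprint are discarded.
#' @param area_keep_frac connected foreground components with area below
#'   this fraction of the largest component are discarded as impurities
#'   (ties at equal area are kept for any value <= 1).
#' @param min_area absolute floor on component area, pixels.
#' @param qc_area_bounds `(min_frac, max_frac)` of image area a mask's
#'   foreground must occupy to pass automated quality control.
#' @param qc_max_components maximum number of foreground components QC
#'   accepts (the scenes contain a single particle).
#' @return an `extraction_config` object.
#' @export
extraction_config <- function(gaussian_kernel = 9,
                              low_threshold = 50,
                              high_threshold = 100,
                              contour_width = 1,
                              open_radius = 1,
                              area_keep_frac = 0.5,
                              min_area = 16,
                              qc_area_bounds = c(0.05, 0.80),
                              qc_max_components = 1) {
  stopifnot(
    gaussian_kernel >= 3, gaussian_kernel %% 2 == 1,
    low_threshold > 0, high_threshold > low_threshold,
    contour_width >= 1,
    open_radius >= 0,
    area_keep_frac > 0, area_keep_frac <= 1,
    min_area >= 0,
    length(qc_area_bounds) == 2, qc_area_bounds[1] < qc_area_bounds[2]
  )
  structure(
    list(
      gaussian_kernel = as.integer(gaussian_kernel),
      low_threshold = low_threshold,
      high_threshold = high_threshold,
      contour_width = as.integer(contour_width),
      open_radius = as.integer(open_radius),
      area_keep_frac = area_keep_frac,
      min_area = as.integer(min_area),
      qc_area_bounds = qc_area_bounds,
      qc_max_components = as.integer(qc_max_components)
    ),
    class = "extraction_config"
  )
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D numeric matrix", call. = FALSE)
  }
  if (any(image < 0 | image > 255)) {
    stop("image values must lie in the 8-bit range [0, 255]", call. = FALSE)
  }
  invisible(image)
}

#' Canny edge detection
#'
#' Gaussian smoothing (kernel side `cfg$gaussian_kernel`, sigma derived as
#' `0.3 * ((k - 1)/2 - 1) + 0.8`), Sobel gradient, 4-bin non-maximum
#' suppression, and dual-threshold hysteresis: weak edges (magnitude >=
#' `low_threshold`) survive only when 8-connected to a strong edge
#' (>= `high_threshold`). Thresholds apply to the raw gradient magnitude of
#' the 0-255 image. `contour_width > 1` thickens the result by dilation.
#'
#' @param image numeric matrix in \[0, 255\].
#' @param cfg an [extraction_config()].
#' @return logical matrix of edge pixels (same dimensions as `image`).
#' @export
canny_edges <- function(image, cfg = extraction_config()) {
  check_image(image)
  edges <- cpp_canny(image, cfg$gaussian_kernel, cfg$low_threshold, cfg$high_threshold)
  if (cfg$contour_width > 1) {
    brush <- EBImage::makeBrush(2 * ((cfg$contour_width) %/% 2) + 1, shape = "disc")
    edges <- EBImage::dilate(edges * 1, brush) > 0
  }
  edges
}

#' Clean a contour map
#'
#' Smooths boundary curves and removes small-scale speck responses while
#' leaving enclosed region areas essentially unchanged: a morphological
#' closing (dilation then erosion) with a disc of radius `open_radius` seals
#' pinhole gaps, then connected edge components smaller than the structuring
#' element footprint (and `min_area` at minimum 1) are discarded. A plain
#' erosion-first opening would annihilate 1-pixel contour lines outright,
#' which is why speck removal is done at the component level. Idempotent.
#'
#' @param edges logical edge matrix from [canny_edges()].
#' @param cfg an [extraction_config()].
#' @return cleaned logical edge matrix.
#' @export
open_contours <- function(edges, cfg = extraction_config()) {
  stopifnot(is.matrix(edges), is.logical(edges))
  if (cfg$open_radius > 0) {
    brush <- EBImage::makeBrush(2 * cfg$open_radius + 1, shape = "disc")
    closed <- EBImage::erode(EBImage::dilate(edges * 1, brush), brush) > 0
    min_keep <- sum(brush)
  } else {
    closed <- edges
    min_keep <- 2
  }
  lab <- cpp_label(closed, 8L)
  if (max(lab) == 0) return(closed)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_keep)
  closed & matrix(lab %in% keep, nrow(edges), ncol(edges))
}

#' Fill closed contours and keep large regions
#'
#' Background is identified by a 4-connected flood fill from the image
#' border; pixels the fill cannot reach (contour interiors and the contour
#' lines bounding them) become foreground. 8-connected foreground components
#' with area below `area_keep_frac` times the largest component's area, or
#' below `min_area` pixels, are discarded as impurities. Components tied
#' with the largest are always kept.
#'
#' @param edges cleaned logical edge matrix.
#' @param cfg an [extraction_config()].
#' @return logical mask with attribute `empty` set to `TRUE` when no closed
#'   region was found.
#' @export
fill_and_select <- function(edges, cfg = extraction_config()) {
  stopifnot(is.matrix(edges), is.logical(edges))
  bg <- cpp_reach_border(edges)
  fg <- !bg
  lab <- cpp_label(fg, 8L)
  n_comp <- max(lab)
  enclosed_exists <- any(fg & !edges)  # some pixel strictly inside a contour
  if (n_comp == 0 || !enclosed_exists) {
    out <- matrix(FALSE, nrow(edges), ncol(edges))
    attr(out, "empty") <- TRUE
    return(out)
  }
  areas <- tabulate(lab[lab > 0], nbins = n_comp)
  amax <- max(areas)
  keep <- which(areas >= cfg$area_keep_frac * amax & areas >= cfg$min_area)
  out <- matrix(lab %in% keep, nrow(edges), ncol(edges))
  attr(out, "empty") <- !any(out)
  out
}

#' Automated quality control for a pseudo mask
#'
#' Stand-in for expert visual screening of extraction failures: a mask is
#' accepted when its foreground fraction lies inside `qc_area_bounds` and it
#' has at most `qc_max_components` connected components.
#'
#' @param mask logical mask.
#' @param cfg an [extraction_config()].
#' @return list with `accept` (logical) and `reason` (`"ok"`, `"empty"`,
#'   `"too_small"`, `"too_large"`, or `"fragmented"`).
#' @export
qc_mask <- function(mask, cfg = extraction_config()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  frac <- mean(mask)
  if (frac == 0) return(list(accept = FALSE, reason = "empty", foreground_frac = 0))
  if (frac < cfg$qc_area_bounds[1]) {
    return(list(accept = FALSE, reason = "too_small", foreground_frac = frac))
  }
  if (frac > cfg$qc_area_bounds[2]) {
    return(list(accept = FALSE, reason = "too_large", foreground_frac = frac))
  }
  n_comp <- max(cpp_label(mask, 8L))
  if (n_comp > cfg$qc_max_components) {
    return(list(accept = FALSE, reason = "fragmented", foreground_frac = frac))
  }
  list(accept = TRUE, reason = "ok", foreground_frac = frac)
}

#' Extract an unsupervised pseudo mask from a micrograph
#'
#' Full contour-based extraction: Canny edges, contour cleanup, flood fill
#' with area-based impurity filtering, and automated QC. The result is the
#' pseudo label used to train the segmenter without any pixel annotation.
#'
#' @param image numeric matrix in \[0, 255\].
#' @param cfg an [extraction_config()].
#' @return list with `mask` (logical matrix) and `qc` (see [qc_mask()]).
#' @export
#' @examples
#' s <- generate_sample(synthetic_spec(image_size = 64, seed = 3))
#' pm <- extract_pseudo_mask(s$image)
#' pm$qc$reason
extract_pseudo_mask <- function(image, cfg = extraction_config()) {
  edges <- canny_edges(image, cfg)
  cleaned <- open_contours(edges, cfg)
  mask <- fill_and_select(cleaned, cfg)
  qc <- qc_mask(mask, cfg)
  list(mask = mask, qc = qc)
}

#' Intersection over union of two binary masks
#'
#' @param a,b logical matrices of equal dimensions.
#' @return IoU in \[0, 1\]; defined as 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
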