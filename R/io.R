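# Manifest and raster I/O. Coordinate convention throughout the package:
# (row, col), top-left origin. Images are stored as 8-bit grayscale PNG and
# handled in R as numeric matrices on the 0-255 scale; masks use the strict
# {0, 255} dialect.

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground is stored as 255, background as 0.
#' @param mask logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' Strict dialect: any pixel value other than 0 or 255 is an error, so a
#' mask survives a save/load round trip bit-for-bit.
#' @param path PNG file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  px <- round(v * 255)
  if (!all(px %in% c(0, 255))) {
    stop(sprintf("non-binary mask in '%s': pixel values other than {0, 255}", path),
         call. = FALSE)
  }
  px == 255
}

#' Write a grayscale image as an 8-bit PNG
#' @param image numeric matrix on the 0-255 scale.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  check_image(image)
  png::writePNG(round(image) / 255, path)
  invisible(path)
}

#' Read a grayscale image from PNG (or grayscale TIFF)
#' @param path file path; `.tif`/`.tiff` files are read with the tiff
#'   package.
#' @return numeric matrix on the 0-255 scale.
#' @export
read_gray_image <- function(path) {
  v <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(v)) == 3) v <- v[, , 1]
  round(v * 255)
}

#' Load and validate a dataset manifest
#'
#' A manifest is a CSV with columns `path`, `label`, `split`, and optionally
#' `mask_path`; paths are resolved relative to the manifest's directory when
#' not absolute. Rows with unknown labels or splits, duplicate paths, or
#' missing image files are rejected with the offending row named.
#'
#' @param path manifest CSV path.
#' @param classes allowed label set (integer ids).
#' @return tibble manifest with absolute paths.
#' @export
load_manifest <- function(path, classes = 0:2) {
  if (!file.exists(path)) stop(sprintf("manifest '%s' not found", path), call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "split")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns path, label, split", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  absolutize <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  m$path <- absolutize(m$path)
  if ("mask_path" %in% names(m)) m$mask_path <- absolutize(m$mask_path)
  for (i in seq_len(nrow(m))) {
    if (!m$label[i] %in% classes) {
      stop(sprintf("manifest row %d: label '%s' not in the configured class set",
                   i, m$label[i]), call. = FALSE)
    }
    if (!m$split[i] %in% c("train", "test")) {
      stop(sprintf("manifest row %d: split '%s' must be train or test",
                   i, m$split[i]), call. = FALSE)
    }
    if (!file.exists(m$path[i])) {
      stop(sprintf("manifest row %d: image '%s' missing", i, m$path[i]),
           call. = FALSE)
    }
  }
  if (anyDuplicated(m$path)) {
    stop(sprintf("duplicate image path in manifest: '%s'",
                 m$path[anyDuplicated(m$path)]), call. = FALSE)
  }
  tibble::as_tibble(m)
}

#' Load the samples a manifest describes
#'
#' @param manifest tibble from [load_manifest()].
#' @param with_masks read `mask_path` masks as ground truth when present.
#' @return list of `labeled_sample` objects.
#' @export
load_samples <- function(manifest, with_masks = TRUE) {
  lapply(seq_len(nrow(manifest)), function(i) {
    gt <- if (with_masks && "mask_path" %in% names(manifest) &&
              !is.na(manifest$mask_path[i]) && nzchar(manifest$mask_path[i])) {
      read_mask(manifest$mask_path[i])
    } else NULL
    structure(
      list(image = read_gray_image(manifest$path[i]),
           label = as.integer(manifest$label[i]),
           gt_mask = gt, split = manifest$split[i]),
      class = "labeled_sample"
    )
  })
}
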