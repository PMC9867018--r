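#' Class-activation heat map from activations and gradients
#'
#' Core Grad-CAM arithmetic, exposed separately so it can be driven with
#' hand-set gradients: each channel weight is the global average of the
#' gradient of the class score over that channel's spatial positions,
#' `alpha_k = (1/Z) * sum_ij dy/dA_k(i,j)` with `Z = width x height`, and
#' the raw map is `ReLU(sum_k alpha_k * A_k)`.
#'
#' @param A activations of the last convolutional layer, array `(H, W, K)`.
#' @param gA gradient of the target class score with respect to `A`, same
#'   dimensions.
#' @return list with `alpha` (length-K weights), `raw` (pre-ReLU weighted
#'   sum, matrix) and `heatmap` (post-ReLU matrix at feature resolution).
#' @export
cam_from_grads <- function(A, gA) {
  stopifnot(all(dim(A) == dim(gA)))
  A <- as_cube(A); gA <- as_cube(gA)
  alpha <- apply(gA, 3, mean)
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[3])) raw <- raw + alpha[k] * A[, , k]
  list(alpha = alpha, raw = raw, heatmap = pmax(raw, 0))
}

#' Grad-CAM heat map of a classifier decision
#'
#' Runs the image through the classifier, backpropagates a one-hot signal
#' for `target_class` (gradient 1 for the desired class score, 0 for all
#' others) to the last convolutional feature stack, forms the
#' gradient-weighted activation map, upsamples it bilinearly to image
#' resolution and min-max normalises it to \[0, 1\] (an identically zero
#' map stays zero).
#'
#' @param model a `pollenseg_classifier`.
#' @param input model input array (see [mask_guided_input()]), values in
#'   \[0, 1\].
#' @param target_class class id in `0:(num_classes-1)`; during training-time
#'   label refinement this is the true image-level label.
#' @return a `cam_heatmap`: list with `values` (normalised matrix at input
#'   resolution), `feature_map` (normalised map at feature resolution),
#'   `target_class`.
#' @export
grad_cam <- function(model, input, target_class) {
  if (!inherits(model, "pollenseg_classifier")) {
    stop("model must be a pollenseg_classifier with a convolutional feature stack",
         call. = FALSE)
  }
  nc <- model$arch$num_classes
  if (!(target_class %in% 0:(nc - 1))) {
    stop(sprintf("target_class must lie in 0..%d", nc - 1), call. = FALSE)
  }
  fw <- cls_forward(model, input)
  gA <- cls_grad_A(model, fw$cache, target_class)
  cam <- cam_from_grads(fw$cache$A, gA)
  input <- as_cube(input)
  up <- cpp_bilinear_resize(cam$heatmap, dim(input)[1], dim(input)[2])
  structure(
    list(values = normalize01(up), feature_map = normalize01(cam$heatmap),
         target_class = target_class, logits = fw$logits),
    class = "cam_heatmap"
  )
}

normalize01 <- function(m) {
  mx <- max(m); mn <- min(m)
  if (mx == 0) return(m * 0)
  if (mx == mn) return(m / mx)   # constant nonzero map -> all ones
  (m - mn) / (mx - mn)
}

#' Binarize a normalised heat map into a localization map
#'
#' @param heatmap a `cam_heatmap` or a normalised numeric matrix.
#' @param threshold fraction in \[0, 1\]; pixels with value `>= threshold`
#'   become foreground. At `threshold = 0` the convention is strict
#'   (`> 0`), so an identically zero map yields an empty localization map.
#' @return logical localization map.
#' @export
binarize_cam <- function(heatmap, threshold = 0.5) {
  if (inherits(heatmap, "cam_heatmap")) heatmap <- heatmap$values
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  if (threshold == 0) heatmap > 0 else heatmap >= threshold
}

#' Refine a pseudo mask with a localization map
#'
#' Keeps the maximum-intersection region: among the 8-connected components
#' of the pseudo mask, the one with the largest pixel overlap with the
#' localization map survives; the others (typically impurity blobs the
#' contour stage could not reject) are discarded whole, so the retained
#' particle structure is never eroded. Ties are broken toward the larger
#' component, then the component whose lexicographically smallest
#' `(row, col)` pixel comes first. When the localization map is empty or
#' intersects no component, the pseudo mask is returned unchanged with
#' attribute `warning = "no_intersection"`.
#'
#' @param pseudo logical pseudo mask.
#' @param loc logical localization map of the same dimensions.
#' @param mode `"component"` (default, described above) or `"pixel"`
#'   (plain pixelwise intersection, for comparison).
#' @return refined logical mask.
#' @export
refine_mask <- function(pseudo, loc, mode = c("component", "pixel")) {
  mode <- match.arg(mode)
  if (!all(dim(pseudo) == dim(loc))) {
    stop("pseudo mask and localization map dimensions differ", call. = FALSE)
  }
  if (mode == "pixel") return(pseudo & loc)
  lab <- cpp_label(pseudo, 8L)
  n_comp <- max(lab)
  if (n_comp == 0 || !any(loc)) {
    attr(pseudo, "warning") <- "no_intersection"
    return(pseudo)
  }
  inter <- tabulate(lab[loc & lab > 0], nbins = n_comp)
  if (all(inter == 0)) {
    attr(pseudo, "warning") <- "no_intersection"
    return(pseudo)
  }
  areas <- tabulate(lab[lab > 0], nbins = n_comp)
  # anchor: position of the first (row-major) pixel; cpp_label assigns labels
  # in row-major scan order, so the label index itself is the anchor order
  best <- order(-inter, -areas, seq_len(n_comp))[1]
  lab == best
}
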