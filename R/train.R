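#' Training configuration
#'
#' Defaults follow the protocol used on the real SEM data: 100 epochs for
#' both networks, cross-entropy losses, Adam with learning rate 1e-3 for the
#' segmenter and 1e-4 for the classifier, 256 -> 224 random crops when
#' augmentation is on. [desk_config()] provides the reduced profile the
#' package's own experiments and examples run at.
#'
#' @param seg_epochs,cls_epochs training epochs per fit.
#' @param seg_lr,cls_lr Adam learning rates.
#' @param batch_size minibatch size.
#' @param crop_from,crop_to augmentation crop geometry (pixels).
#' @param rounds collaborative rounds after the initial independent fits.
#' @param mask_mode `"weight"` (elementwise image x mask product, 1 channel)
#'   or `"concat"` (2-channel stack).
#' @param augment apply seeded flips/rotations and random crops during
#'   training.
#' @param stop_tol early-stop threshold on the fraction of mask pixels
#'   flipped by a refinement round.
#' @param seg_width,cls_n0,cls_growth,cls_block_layers architecture sizes.
#' @param seed integer seed for weight init, shuffling, augmentation.
#' @return a `train_config` object.
#' @export
train_config <- function(seg_epochs = 100, seg_lr = 1e-3,
                         cls_epochs = 100, cls_lr = 1e-4,
                         batch_size = 16,
                         crop_from = 256, crop_to = 224,
                         rounds = 3, mask_mode = c("weight", "concat"),
                         augment = FALSE, stop_tol = 0.01,
                         seg_width = 8, cls_n0 = 8, cls_growth = 6,
                         cls_block_layers = 2, seed = 1) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(seg_epochs >= 1, cls_epochs >= 1, rounds >= 1,
            crop_to <= crop_from, batch_size >= 1, stop_tol >= 0)
  structure(
    list(seg_epochs = seg_epochs, seg_lr = seg_lr,
         cls_epochs = cls_epochs, cls_lr = cls_lr,
         batch_size = batch_size, crop_from = crop_from, crop_to = crop_to,
         rounds = rounds, mask_mode = mask_mode, augment = augment,
         stop_tol = stop_tol, seg_width = seg_width, cls_n0 = cls_n0,
         cls_growth = cls_growth, cls_block_layers = cls_block_layers,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Desk-scale training profile
#'
#' The reduced configuration the package's experiments, examples and tests
#' run at: 64x64 images, narrow networks, and short schedules that train in
#' seconds on one CPU while preserving every structural property of the
#' full protocol.
#'
#' @param ... overrides passed to [train_config()].
#' @return a `train_config`.
#' @export
desk_config <- function(...) {
  args <- modifyList(
    list(seg_epochs = 12, cls_epochs = 40, cls_lr = 1e-3, rounds = 1,
         crop_from = 64, crop_to = 64, batch_size = 16,
         seg_width = 6, cls_n0 = 8, cls_growth = 6, cls_block_layers = 2),
    list(...)
  )
  do.call(train_config, args)
}

#' Build a classifier input from an image and a mask
#'
#' Weight mode multiplies the normalised image elementwise by the mask so
#' impurity and background pixels are zeroed out; concat mode stacks the
#' image and the mask as two channels.
#'
#' @param image numeric matrix in \[0, 255\].
#' @param mask logical mask of the same dimensions.
#' @param mode `"weight"` or `"concat"`.
#' @return array `(H, W, 1)` in weight mode or `(H, W, 2)` in concat mode;
#'   channel 1 is always the (possibly masked) image.
#' @export
mask_guided_input <- function(image, mask, mode = c("weight", "concat")) {
  mode <- match.arg(mode)
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  img <- image / 255
  if (mode == "weight") {
    as_cube(img * mask)
  } else {
    abind3(as_cube(img), as_cube(mask * 1))
  }
}

#' Seeded augmentation of a labelled sample
#'
#' Random horizontal/vertical flips and quarter-turn rotations followed by a
#' random `crop_from -> crop_to` crop; the identical transform is applied to
#' the image and to its mask so they stay aligned.
#'
#' @param sample a `labeled_sample` (the `gt_mask` field, when present, is
#'   transformed alongside the image; a `mask` field is transformed too).
#' @param seed integer seed.
#' @param crop_to target crop side; the input must be at least this large.
#' @return the transformed sample.
#' @export
augment <- function(sample, seed, crop_to = nrow(sample$image)) {
  if (nrow(sample$image) < crop_to || ncol(sample$image) < crop_to) {
    stop("image smaller than the crop target", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  hflip <- runif(1) < 0.5
  vflip <- runif(1) < 0.5
  k_rot <- sample(0:3, 1)
  i0 <- sample.int(nrow(sample$image) - crop_to + 1, 1)
  j0 <- sample.int(ncol(sample$image) - crop_to + 1, 1)
  tf <- function(m) {
    if (is.null(m)) return(NULL)
    if (hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (k_rot > 0) for (t in seq_len(k_rot)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
    m[i0:(i0 + crop_to - 1), j0:(j0 + crop_to - 1), drop = FALSE]
  }
  sample$image <- tf(sample$image)
  if (!is.null(sample$gt_mask)) sample$gt_mask <- tf(sample$gt_mask)
  if (!is.null(sample$mask)) sample$mask <- tf(sample$mask)
  sample
}

# softmax cross-entropy over per-pixel 2-class scores; returns loss and the
# gradient with respect to the scores (mean reduction over pixels)
seg_ce_loss <- function(scores, mask) {
  np <- length(mask)
  s <- matrix(scores, ncol = 2)        # pixels x classes
  p <- softmax_rows(s)
  y <- as.integer(mask) + 1L           # 1 = background, 2 = pollen
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(np), y)] + eps))
  g <- p
  g[cbind(seq_len(np), y)] <- g[cbind(seq_len(np), y)] - 1
  list(loss = loss, grad = array(g / np, dim(scores)))
}

cls_ce_loss <- function(logits, label) {
  p <- as.vector(softmax_rows(matrix(logits, 1)))
  eps <- 1e-12
  list(loss = -log(p[label + 1] + eps),
       grad = p - (seq_along(p) == label + 1))
}

zero_like <- function(params) lapply(params, function(p) p * 0)
add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
scale_grads <- function(a, s) lapply(a, function(g) g * s)

run_epochs <- function(params_model, samples, cfg, task, epochs, lr,
                       make_input, make_loss, backward) {
  model <- params_model
  params <- flatten_params(model$layers)
  opt <- adam_init(params)
  n <- length(samples)
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    b0 <- 1
    while (b0 <= n) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      acc <- zero_like(params)
      for (i in idx) {
        s <- samples[[i]]
        if (cfg$augment) s <- prepare_augmented(s, cfg)
        x <- make_input(s)
        fw <- if (task == "seg") seg_forward(model, x) else cls_forward(model, x)
        ls <- make_loss(fw, s)
        ep_loss <- ep_loss + ls$loss
        g <- backward(model, fw$cache, ls$grad)
        acc <- add_grads(acc, g)
      }
      acc <- scale_grads(acc, 1 / length(idx))
      st <- adam_step(params, acc, opt, lr)
      params <- st$params
      opt <- st$state
      model$layers <- unflatten_params(params)
      b0 <- b0 + cfg$batch_size
    }
    losses[e] <- ep_loss / n
  }
  list(model = model, loss = losses)
}

prepare_augmented <- function(s, cfg) {
  sd_ <- sample.int(2^30, 1)
  augment(s, seed = sd_, crop_to = min(cfg$crop_to, nrow(s$image)))
}

#' Train the segmentation network
#'
#' Per-pixel softmax cross-entropy on (pseudo or refined) masks, Adam,
#' seeded and reproducible. Returns the fitted model with its per-epoch
#' mean loss curve.
#'
#' @param model a `pollenseg_segmenter` (its weights are the starting
#'   point).
#' @param samples list of lists with `image` (matrix, 0-255) and `mask`
#'   (logical matrix).
#' @param cfg a [train_config()].
#' @return a `pollenseg_fit`: list with `model`, `loss` (per-epoch), `task`.
#' @export
train_segmenter <- function(model, samples, cfg = desk_config()) {
  if (length(samples) == 0) stop("empty training set", call. = FALSE)
  for (s in samples) {
    if (is.null(s$mask)) stop("every sample needs a mask", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 101))
  out <- run_epochs(
    model, samples, cfg, "seg", cfg$seg_epochs, cfg$seg_lr,
    make_input = function(s) as_cube(s$image / 255),
    make_loss = function(fw, s) seg_ce_loss(fw$scores, s$mask),
    backward = seg_backward
  )
  structure(list(model = out$model, loss = out$loss, task = "segmentation"),
            class = "pollenseg_fit")
}

#' Train the classification network
#'
#' Cross-entropy on image-level labels, Adam. When `masks` is supplied the
#' inputs are built with [mask_guided_input()]; otherwise raw images are
#' used (the unguided baseline).
#'
#' @param model a `pollenseg_classifier`.
#' @param samples list of `labeled_sample`-like lists (`image`, `label`).
#' @param masks optional list of logical masks aligned with `samples`.
#' @param cfg a [train_config()].
#' @return a `pollenseg_fit` with `model`, `loss`, `task`.
#' @export
train_classifier <- function(model, samples, masks = NULL, cfg = desk_config()) {
  if (length(samples) == 0) stop("empty training set", call. = FALSE)
  nc <- model$arch$num_classes
  labs <- vapply(samples, `[[`, 0, "label")
  if (any(!labs %in% 0:(nc - 1))) {
    stop(sprintf("labels must lie in 0..%d", nc - 1), call. = FALSE)
  }
  if (!is.null(masks)) {
    stopifnot(length(masks) == length(samples))
    for (i in seq_along(samples)) samples[[i]]$mask <- masks[[i]]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 202))
  out <- run_epochs(
    model, samples, cfg, "cls", cfg$cls_epochs, cfg$cls_lr,
    make_input = function(s) {
      if (is.null(s$mask)) as_cube(s$image / 255)
      else mask_guided_input(s$image, s$mask, cfg$mask_mode)
    },
    make_loss = function(fw, s) cls_ce_loss(fw$logits, s$label),
    backward = cls_backward
  )
  structure(list(model = out$model, loss = out$loss, task = "classification"),
            class = "pollenseg_fit")
}

#' @export
print.pollenseg_fit <- function(x, ...) {
  cat(sprintf("<pollenseg_fit> %s, %d epochs, final loss %.4f\n",
              x$task, length(x$loss), x$loss[length(x$loss)]))
  invisible(x)
}
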