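# Tiny encoder-decoder segmenter and densely connected classifier, written
# directly on the conv primitives with hand-derived backprop. Desk-scale by
# design: the architectures follow the shape of U-Net (skip connections) and
# DenseNet (every layer sees all previous feature maps) at widths small
# enough to train on a single CPU in seconds.

#' Build a U-Net-style binary segmentation network
#'
#' Two-level encoder-decoder with skip connections; the output head yields
#' per-pixel scores for the two classes (background, pollen). Weights are
#' He-initialised from the current RNG state.
#'
#' @param in_channels input channels (1 for a grayscale image).
#' @param width channels of the first encoder stage; later stages use
#'   `2 * width`.
#' @return a `pollenseg_segmenter` object.
#' @export
build_segmenter <- function(in_channels = 1, width = 8) {
  stopifnot(width >= 1, in_channels >= 1)
  layers <- list(
    e1 = init_conv(3, in_channels, width),
    e2 = init_conv(3, width, 2 * width),
    bott = init_conv(3, 2 * width, 2 * width),
    d2 = init_conv(3, 4 * width, width),
    d1 = init_conv(3, 2 * width, width),
    head = init_conv(1, width, 2)
  )
  structure(list(layers = layers,
                 arch = list(in_channels = in_channels, width = width)),
            class = "pollenseg_segmenter")
}

seg_forward <- function(model, x) {
  L <- model$layers
  x <- as_cube(x)
  z_e1 <- conv_fwd(x, L$e1$w, L$e1$b); a_e1 <- relu(z_e1)
  mp1 <- cpp_maxpool2_fwd(a_e1)
  z_e2 <- conv_fwd(mp1$out, L$e2$w, L$e2$b); a_e2 <- relu(z_e2)
  mp2 <- cpp_maxpool2_fwd(a_e2)
  z_b <- conv_fwd(mp2$out, L$bott$w, L$bott$b); a_b <- relu(z_b)
  u2 <- cpp_upsample2_fwd(a_b)
  c2 <- abind3(u2, a_e2)
  z_d2 <- conv_fwd(c2, L$d2$w, L$d2$b); a_d2 <- relu(z_d2)
  u1 <- cpp_upsample2_fwd(a_d2)
  c1 <- abind3(u1, a_e1)
  z_d1 <- conv_fwd(c1, L$d1$w, L$d1$b); a_d1 <- relu(z_d1)
  scores <- conv_fwd(a_d1, L$head$w, L$head$b)
  list(scores = scores,
       cache = list(x = x, z_e1 = z_e1, a_e1 = a_e1, idx1 = mp1$idx, p1 = mp1$out,
                    z_e2 = z_e2, a_e2 = a_e2, idx2 = mp2$idx, p2 = mp2$out,
                    z_b = z_b, c2 = c2, z_d2 = z_d2, c1 = c1, z_d1 = z_d1,
                    a_d1 = a_d1))
}

seg_backward <- function(model, cache, gscores) {
  L <- model$layers
  w <- model$arch$width
  g <- list()
  r <- conv_bwd(cache$a_d1, L$head$w, gscores)
  g$head.w <- r$gw; g$head.b <- r$gb
  gz <- relu_bwd(cache$z_d1, r$gx)
  r <- conv_bwd(cache$c1, L$d1$w, gz)
  g$d1.w <- r$gw; g$d1.b <- r$gb
  g_u1 <- r$gx[, , seq_len(w), drop = FALSE]
  g_skip1 <- r$gx[, , w + seq_len(w), drop = FALSE]
  gz <- relu_bwd(cache$z_d2, cpp_upsample2_bwd(g_u1))
  r <- conv_bwd(cache$c2, L$d2$w, gz)
  g$d2.w <- r$gw; g$d2.b <- r$gb
  g_u2 <- r$gx[, , seq_len(2 * w), drop = FALSE]
  g_skip2 <- r$gx[, , 2 * w + seq_len(2 * w), drop = FALSE]
  gz <- relu_bwd(cache$z_b, cpp_upsample2_bwd(g_u2))
  r <- conv_bwd(cache$p2, L$bott$w, gz)
  g$bott.w <- r$gw; g$bott.b <- r$gb
  g_a_e2 <- cpp_maxpool2_bwd(cache$idx2, r$gx, nrow2(cache$a_e2), ncol2(cache$a_e2)) + g_skip2
  gz <- relu_bwd(cache$z_e2, g_a_e2)
  r <- conv_bwd(cache$p1, L$e2$w, gz)
  g$e2.w <- r$gw; g$e2.b <- r$gb
  g_a_e1 <- cpp_maxpool2_bwd(cache$idx1, r$gx, nrow2(cache$a_e1), ncol2(cache$a_e1)) + g_skip1
  gz <- relu_bwd(cache$z_e1, g_a_e1)
  r <- conv_bwd(cache$x, L$e1$w, gz)
  g$e1.w <- r$gw; g$e1.b <- r$gb
  g
}

abind3 <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}
nrow2 <- function(x) dim(x)[1]
ncol2 <- function(x) dim(x)[2]

#' Predict a binary mask with a trained segmenter
#'
#' @param model a trained `pollenseg_segmenter`.
#' @param image numeric matrix in \[0, 255\].
#' @return logical mask: pixels whose pollen score strictly exceeds the
#'   background score (score ties resolve to the lower class index, i.e.
#'   background).
#' @export
predict_mask <- function(model, image) {
  fw <- seg_forward(model, as_cube(image / 255))
  fw$scores[, , 2] > fw$scores[, , 1]
}

#' Build a densely connected classification network
#'
#' Stem convolution, two dense blocks (each layer takes the concatenation of
#' all previous feature maps in its block as input) joined by a 1x1
#' transition with pooling, global average pooling, and a linear head. The
#' post-concatenation feature stack of the last block is exposed as the
#' "last convolutional layer" for Grad-CAM.
#'
#' @param in_channels input channels (1 raw image, 2 in concat mask mode).
#' @param n0 stem output channels.
#' @param growth channels added by each dense-block layer.
#' @param block_layers layers per dense block.
#' @param num_classes number of output classes.
#' @return a `pollenseg_classifier` object.
#' @export
build_classifier <- function(in_channels = 1, n0 = 8, growth = 6,
                             block_layers = 2, num_classes = 3) {
  stopifnot(n0 >= 1, growth >= 1, block_layers >= 1, num_classes >= 2)
  layers <- list(stem = init_conv(3, in_channels, n0))
  c1 <- n0
  for (l in seq_len(block_layers)) {
    layers[[paste0("b1l", l)]] <- init_conv(3, c1, growth)
    c1 <- c1 + growth
  }
  ct <- max(1L, c1 %/% 2L)
  layers$trans <- init_conv(1, c1, ct)
  c2 <- ct
  for (l in seq_len(block_layers)) {
    layers[[paste0("b2l", l)]] <- init_conv(3, c2, growth)
    c2 <- c2 + growth
  }
  layers$fc <- list(w = matrix(rnorm(num_classes * c2, sd = sqrt(1 / c2)),
                               num_classes, c2),
                    b = rep(0, num_classes))
  structure(list(layers = layers,
                 arch = list(in_channels = in_channels, n0 = n0, growth = growth,
                             block_layers = block_layers, num_classes = num_classes,
                             c_block1 = c1, c_trans = ct, c_last = c2)),
            class = "pollenseg_classifier")
}

dense_block_fwd <- function(layers, prefix, n_layers, s) {
  zs <- vector("list", n_layers)
  stacks <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    stacks[[l]] <- s
    p <- layers[[paste0(prefix, l)]]
    z <- conv_fwd(s, p$w, p$b)
    zs[[l]] <- z
    s <- abind3(s, relu(z))
  }
  list(out = s, zs = zs, stacks = stacks)
}

dense_block_bwd <- function(layers, prefix, n_layers, blk, g_s, grads) {
  growth <- dim(blk$zs[[1]])[3]
  for (l in rev(seq_len(n_layers))) {
    cin <- dim(blk$stacks[[l]])[3]
    g_a <- g_s[, , cin + seq_len(growth), drop = FALSE]
    g_s <- g_s[, , seq_len(cin), drop = FALSE]
    gz <- relu_bwd(blk$zs[[l]], g_a)
    p <- layers[[paste0(prefix, l)]]
    r <- conv_bwd(blk$stacks[[l]], p$w, gz)
    grads[[paste0(prefix, l, ".w")]] <- r$gw
    grads[[paste0(prefix, l, ".b")]] <- r$gb
    g_s <- g_s + r$gx
  }
  list(g_in = g_s, grads = grads)
}

cls_forward <- function(model, x) {
  L <- model$layers
  x <- as_cube(x)
  z0 <- conv_fwd(x, L$stem$w, L$stem$b); a0 <- relu(z0)
  mp0 <- cpp_maxpool2_fwd(a0)
  blk1 <- dense_block_fwd(L, "b1l", model$arch$block_layers, mp0$out)
  zt <- conv_fwd(blk1$out, L$trans$w, L$trans$b); at <- relu(zt)
  mpt <- cpp_maxpool2_fwd(at)
  blk2 <- dense_block_fwd(L, "b2l", model$arch$block_layers, mpt$out)
  A <- blk2$out                              # last-conv feature stack
  f <- apply(A, 3, mean)                     # global average pooling
  logits <- as.vector(L$fc$w %*% f + L$fc$b)
  list(logits = logits,
       cache = list(x = x, z0 = z0, a0 = a0, idx0 = mp0$idx, p0 = mp0$out,
                    blk1 = blk1, zt = zt, idxt = mpt$idx, pt = mpt$out,
                    blk2 = blk2, A = A, f = f))
}

cls_backward <- function(model, cache, glogits) {
  L <- model$layers
  g <- list()
  g$fc.w <- outer(glogits, cache$f)
  g$fc.b <- glogits
  gf <- as.vector(t(L$fc$w) %*% glogits)
  Z <- prod(dim(cache$A)[1:2])
  gA <- array(rep(gf, each = Z) / Z, dim(cache$A))
  b <- dense_block_bwd(L, "b2l", model$arch$block_layers, cache$blk2, gA, g)
  g <- b$grads
  g_pt <- b$g_in
  g_at <- cpp_maxpool2_bwd(cache$idxt, g_pt, nrow2(cache$blk1$out), ncol2(cache$blk1$out))
  gz <- relu_bwd(cache$zt, g_at)
  r <- conv_bwd(cache$blk1$out, L$trans$w, gz)
  g$trans.w <- r$gw; g$trans.b <- r$gb
  b <- dense_block_bwd(L, "b1l", model$arch$block_layers, cache$blk1, r$gx, g)
  g <- b$grads
  g_a0 <- cpp_maxpool2_bwd(cache$idx0, b$g_in, nrow2(cache$a0), ncol2(cache$a0))
  gz <- relu_bwd(cache$z0, g_a0)
  r <- conv_bwd(cache$x, L$stem$w, gz)
  g$stem.w <- r$gw; g$stem.b <- r$gb
  g
}

# gradient of the class-c pre-softmax score with respect to the last-conv
# feature stack A: the head is global-average-pool + linear, so
# d y_c / d A_k(i,j) = W[c, k] / Z
cls_grad_A <- function(model, cache, target_class) {
  W <- model$layers$fc$w
  Z <- prod(dim(cache$A)[1:2])
  array(rep(W[target_class + 1, ], each = Z) / Z, dim(cache$A))
}

#' Predict class labels with a trained classifier
#'
#' @param model a trained `pollenseg_classifier`.
#' @param inputs list of model input arrays (see [mask_guided_input()]).
#' @return integer vector of predicted class ids (0-based); score ties
#'   resolve to the lower class index.
#' @export
predict_classes <- function(model, inputs) {
  vapply(inputs, function(x) {
    lg <- cls_forward(model, x)$logits
    as.integer(which(lg == max(lg))[1] - 1L)
  }, integer(1))
}

#' @export
print.pollenseg_segmenter <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$layers), length, 0L))
  cat(sprintf("<pollenseg_segmenter> width %d, %d parameters\n", x$arch$width, np))
  invisible(x)
}

#' @export
print.pollenseg_classifier <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$layers), length, 0L))
  cat(sprintf("<pollenseg_classifier> %d classes, last-conv channels %d, %d parameters\n",
              x$arch$num_classes, x$arch$c_last, np))
  invisible(x)
}

n_params <- function(model) sum(vapply(flatten_params(model$layers), length, 0L))
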