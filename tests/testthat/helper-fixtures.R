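# fixtures built in code at test time

# a 1-px circular contour of radius r centred in an n x n logical matrix
circle_contour <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  out <- matrix(FALSE, n, n)
  for (t in seq(0, 2 * pi, length.out = ceiling(8 * pi * r))) {
    i <- round(cy + r * sin(t)); j <- round(cx + r * cos(t))
    if (i >= 1 && i <= n && j >= 1 && j <= n) out[i, j] <- TRUE
  }
  out
}

# filled disk
disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xs <- matrix(rep(1:n, each = n), n, n)
  ys <- matrix(rep(1:n, n), n, n)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# vertical step image: columns < c are lo, columns >= c are hi
step_image <- function(n, c, lo = 0, hi = 200) {
  img <- matrix(lo, n, n)
  img[, c:n] <- hi
  img
}

clean_spec <- function(seed = 1, class_id = 0, image_size = 64) {
  synthetic_spec(image_size = image_size, particle_radius_frac = 0.3,
                 radius_jitter = 0, class_id = class_id,
                 impurity_count_range = c(0, 0), noise_sd = 0, seed = seed)
}
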