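#' Specification for one synthetic SEM-like micrograph
#'
#' Describes a single-particle scene the way the detection-preprocessed real
#' data look: one dominant textured particle near the image centre plus small
#' impurity specks, mid-gray background, additive Gaussian noise. Three class
#' families mimic the morphology of the pollen taxa the pipeline targets:
#' class 0 a granular sphere (Cupressaceae-like), class 1 a rounded
#' quadrangular/rectangular grain (Fraxinus-like), class 2 an olive-shaped
#' ellipse of axis ratio ~2 (Ginkgo-like).
#'
#' @param image_size pixels per side of the square image.
#' @param particle_radius_frac mean particle semi-axis as a fraction of the
#'   image side; must lie in (0, 0.5).
#' @param radius_jitter relative jitter applied to the semi-axis.
#' @param class_id particle class, one of 0, 1, 2.
#' @param impurity_count_range integer interval `c(lo, hi)` for the number of
#'   impurity specks.
#' @param impurity_radius_frac mean impurity radius fraction; must stay below
#'   `particle_radius_frac / 3` so the particle dominates every speck, which
#'   is the premise the area-based impurity filter relies on.
#' @param overlap_prob probability that an impurity is placed touching the
#'   particle boundary rather than uniformly in the clear background.
#' @param noise_sd additive Gaussian noise standard deviation, 8-bit
#'   intensity units.
#' @param seed integer seed; identical spec + seed reproduces the sample
#'   bit-for-bit.
#' @return an object of class `synthetic_spec`.
#' @export
#' @examples
#' sp <- synthetic_spec(image_size = 64, class_id = 0, seed = 1)
#' s <- generate_sample(sp)
#' mean(s$gt_mask)
synthetic_spec <- function(image_size = 64,
                           particle_radius_frac = 0.3,
                           radius_jitter = 0.1,
                           class_id = 0,
                           impurity_count_range = c(3, 8),
                           impurity_radius_frac = 0.06,
                           overlap_prob = 0.25,
                           noise_sd = 8,
                           seed = 1) {
  spec <- list(
    image_size = as.integer(image_size),
    particle_radius_frac = particle_radius_frac,
    radius_jitter = radius_jitter,
    class_id = as.integer(class_id),
    impurity_count_range = as.integer(impurity_count_range),
    overlap_prob = overlap_prob,
    impurity_radius_frac = impurity_radius_frac,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  err <- function(field, why) {
    stop(sprintf("invalid synthetic_spec field '%s': %s", field, why), call. = FALSE)
  }
  if (is.na(spec$image_size) || spec$image_size < 16) {
    err("image_size", "must be an integer >= 16")
  }
  if (!(spec$particle_radius_frac > 0 && spec$particle_radius_frac < 0.5)) {
    err("particle_radius_frac", "must lie in (0, 0.5)")
  }
  if (spec$radius_jitter < 0 || spec$radius_jitter >= 1) {
    err("radius_jitter", "must lie in [0, 1)")
  }
  if (!spec$class_id %in% 0:2) err("class_id", "must be one of 0, 1, 2")
  if (length(spec$impurity_count_range) != 2 ||
      any(spec$impurity_count_range < 0) ||
      spec$impurity_count_range[1] > spec$impurity_count_range[2]) {
    err("impurity_count_range", "must be a nondecreasing nonnegative pair")
  }
  if (spec$impurity_radius_frac >= spec$particle_radius_frac / 3) {
    err("impurity_radius_frac",
        "must be < particle_radius_frac / 3 (particle must dominate impurities)")
  }
  if (spec$noise_sd < 0) err("noise_sd", "must be nonnegative")
  if (is.na(spec$seed)) err("seed", "must be an integer")
  invisible(spec)
}

# intensity palette shared by the generator: chosen so the particle/background
# step (~80 units) yields a Sobel response well above the 100 strong-edge
# threshold after 9x9 Gaussian smoothing, while background noise stays far
# below the weak threshold of 50
SYNTH_BG <- 90
SYNTH_FG <- 170

# membership test for the particle shape of each class family, in centred
# rotated coordinates; r is the nominal semi-axis
particle_membership <- function(size, cx, cy, r, theta, class_id) {
  xs <- matrix(rep(seq_len(size), each = size), size, size) # col index
  ys <- matrix(rep(seq_len(size), size), size, size)        # row index
  dx <- xs - cx
  dy <- ys - cy
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  if (class_id == 0L) {          # granular sphere
    u^2 + v^2 <= r^2
  } else if (class_id == 1L) {   # rounded rectangle, aspect ~1.5
    a <- r * 1.15
    b <- r / 1.35
    rc <- r * 0.3                # corner rounding radius
    qu <- pmax(abs(u) - (a - rc), 0)
    qv <- pmax(abs(v) - (b - rc), 0)
    abs(u) <= a & abs(v) <= b & (qu^2 + qv^2 <= rc^2)
  } else {                       # olive: ellipse, axis ratio ~2
    (u / (r * 1.25))^2 + (v / (r * 0.62))^2 <= 1
  }
}

# class-specific interior texture, additive on top of the base intensity;
# local-variance ordering (high / low / medium) is what makes the families
# separable by a texture statistic as well as by shape
particle_texture <- function(size, class_id, r, theta) {
  if (class_id == 0L) {
    matrix(rnorm(size * size, sd = 40), size, size)   # granular speckle
  } else if (class_id == 1L) {
    xs <- matrix(rep(seq_len(size), each = size), size, size)
    5 * sin(2 * pi * xs / size) +
      matrix(rnorm(size * size, sd = 3), size, size)  # smooth shading
  } else {
    xs <- matrix(rep(seq_len(size), each = size), size, size)
    ys <- matrix(rep(seq_len(size), size), size, size)
    u <- cos(theta) * xs + sin(theta) * ys
    20 * sin(2 * pi * u / (r * 0.8)) +
      matrix(rnorm(size * size, sd = 5), size, size)  # banded ridges
  }
}

disk_membership <- function(size, cx, cy, r) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), size), size, size)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Generate one labelled synthetic micrograph
#'
#' Draws a single textured particle whose support is returned as the
#' ground-truth mask, scatters impurity specks of similar intensity (never
#' added to the ground truth), and adds Gaussian noise. Deterministic in
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a `labeled_sample`: list with `image` (numeric matrix, 0-255),
#'   `label` (class id), `gt_mask` (logical matrix), `split` (`NA` until
#'   assigned by [generate_dataset()]).
#' @export
generate_sample <- function(spec) {
  validate_spec(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n <- spec$image_size
  r0 <- spec$particle_radius_frac * n
  r <- r0 * (1 + runif(1, -spec$radius_jitter, spec$radius_jitter))
  cx <- n / 2 + runif(1, -0.05, 0.05) * n
  cy <- n / 2 + runif(1, -0.05, 0.05) * n
  theta <- runif(1, 0, pi)

  gt <- particle_membership(n, cx, cy, r, theta, spec$class_id)
  img <- matrix(SYNTH_BG, n, n)
  tex <- particle_texture(n, spec$class_id, r, theta)
  img[gt] <- SYNTH_FG + tex[gt]

  k <- if (spec$impurity_count_range[2] > 0) {
    sample(spec$impurity_count_range[1]:spec$impurity_count_range[2], 1)
  } else 0L
  if (k > 0) {
    for (t in seq_len(k)) {
      ir <- max(1.2, spec$impurity_radius_frac * n * runif(1, 0.6, 1.6))
      if (runif(1) < spec$overlap_prob) {
        # place the speck on the particle boundary so its contour merges
        ang <- runif(1, 0, 2 * pi)
        # boundary distance along ang (worst case semi-axis is fine at cartoon fidelity)
        bx <- cx + cos(ang) * r * 1.05
        by <- cy + sin(ang) * r * 1.05
      } else {
        # rejection-sample a clear-background position; small images may
        # leave no room, in which case the speck is skipped
        placed <- FALSE
        for (try in 1:50) {
          bx <- runif(1, ir + 1, n - ir)
          by <- runif(1, ir + 1, n - ir)
          if ((bx - cx)^2 + (by - cy)^2 > (r + ir + 2)^2) { placed <- TRUE; break }
        }
        if (!placed) next
      }
      sp <- disk_membership(n, bx, by, ir)
      sp <- sp & !gt   # impurities never claim ground-truth pixels
      spk <- matrix(rnorm(n * n, sd = 35), n, n)
      img[sp] <- SYNTH_FG - 5 + spk[sp]
    }
  }

  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(n * n, sd = spec$noise_sd), n, n)
  }
  img <- pmin(pmax(round(img), 0), 255)

  structure(
    list(image = img, label = spec$class_id, gt_mask = gt, split = NA_character_),
    class = "labeled_sample"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# largest-remainder apportionment of n over proportions; ties by class index
largest_remainder <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    rem <- raw - base
    ord <- order(-rem, seq_along(rem))   # ties broken by lower class index
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Generate a labelled synthetic dataset with a train/test split
#'
#' Class counts follow largest-remainder rounding of `n * class_proportions`
#' (ties to the lower class index); the train/test partition is a seeded
#' random split at `train_frac`.
#'
#' @param spec_template a [synthetic_spec()] supplying every per-image
#'   parameter except `class_id` and `seed`, which are assigned per sample.
#' @param n number of samples (>= 3).
#' @param class_proportions length-3 nonnegative vector summing to 1.
#' @param train_frac fraction of samples assigned to the training split.
#' @param seed integer seed controlling per-sample seeds and the split.
#' @return list of `labeled_sample` objects with `split` set.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(image_size = 48), n = 6, seed = 7)
#' table(vapply(ds, `[[`, 0L, "label"))
generate_dataset <- function(spec_template, n,
                             class_proportions = c(805, 248, 271) / 1324,
                             train_frac = 0.8, seed = 1) {
  stopifnot(n >= 3)
  if (length(class_proportions) != 3 || any(class_proportions < 0)) {
    stop("class_proportions must be 3 nonnegative values", call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  counts <- largest_remainder(n, class_proportions)
  labels <- rep(0:2, times = counts)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_train <- round(n * train_frac)
  split <- rep("test", n)
  split[sample.int(n, n_train)] <- "train"

  lapply(seq_len(n), function(i) {
    sp <- spec_template
    sp$class_id <- labels[i]
    sp$seed <- derive_seed(seed, i)
    s <- generate_sample(sp)
    s$split <- split[i]
    s
  })
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat(sprintf(
    "<labeled_sample> %dx%d image, class %d, split %s, gt foreground %.3f\n",
    nrow(x$image), ncol(x$image), x$label,
    ifelse(is.na(x$split), "unassigned", x$split), mean(x$gt_mask)
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Images and ground-truth masks are written as 8-bit grayscale PNG (masks
#' use the 0/255 convention) and a manifest CSV with columns
#' `path,label,split,mask_path` is returned invisibly as a tibble.
#'
#' @param samples list of `labeled_sample` objects.
#' @param dir output directory, created if missing.
#' @return tibble manifest (invisibly); also written to `dir/manifest.csv`.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    ip <- file.path(dir, sprintf("img_%04d.png", i))
    mp <- file.path(dir, sprintf("mask_%04d.png", i))
    write_gray_png(s$image, ip)
    write_mask(s$gt_mask, mp)
    tibble::tibble(path = ip, label = s$label, split = s$split, mask_path = mp)
  })
  manifest <- dplyr::bind_rows(rows)
  # the stored manifest uses paths relative to its own directory, so the
  # dataset directory can be moved or read from any working directory
  stored <- manifest
  stored$path <- basename(stored$path)
  stored$mask_path <- basename(stored$mask_path)
  utils::write.csv(stored, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
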