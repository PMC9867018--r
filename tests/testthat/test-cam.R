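test_that("channel weights are the global average of the gradients", {
  A <- array(c(1, 2, 3, 4), c(2, 2, 1))
  gA <- array(c(1, 1, 1, 3), c(2, 2, 1))
  cam <- cam_from_grads(A, gA)
  expect_equal(cam$alpha, 1.5)
  expect_equal(cam$raw, 1.5 * A[, , 1])
  expect_equal(cam$heatmap, pmax(1.5 * A[, , 1], 0))
})

test_that("the weighted activation sum scales linearly with the gradients", {
  set.seed(4)
  A <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  gA <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  base <- cam_from_grads(A, gA)
  scaled <- cam_from_grads(A, 2.5 * gA)
  expect_equal(scaled$raw, 2.5 * base$raw)
})

test_that("zero gradients yield an identically zero heat map", {
  set.seed(7)
  model <- build_classifier(1)
  # make class 0's score constant in the feature stack
  model$layers$fc$w[1, ] <- 0
  s <- generate_sample(clean_spec(seed = 2))
  hm <- grad_cam(model, array(s$image / 255, c(64, 64, 1)), 0)
  expect_true(all(hm$values == 0))
})

test_that("heat maps are nonnegative and normalised to [0, 1]", {
  set.seed(8)
  model <- build_classifier(1)
  s <- generate_sample(synthetic_spec(seed = 3))
  for (cl in 0:2) {
    hm <- grad_cam(model, array(s$image / 255, c(64, 64, 1)), cl)
    expect_gte(min(hm$values), 0)
    expect_lte(max(hm$values), 1)
    expect_true(max(hm$values) %in% c(0, 1))  # max 1 unless identically 0
    expect_equal(dim(hm$values), dim(s$image))
  }
})

test_that("invalid Grad-CAM targets are rejected", {
  set.seed(9)
  model <- build_classifier(1)
  x <- array(0.5, c(16, 16, 1))
  expect_error(grad_cam(model, x, 7), "target_class")
  expect_error(grad_cam(list(), x, 0), "classifier")
})

test_that("binarization follows the threshold conventions", {
  zero <- matrix(0, 4, 4)
  expect_false(any(binarize_cam(zero, 0.3)))
  expect_false(any(binarize_cam(zero, 0)))   # strict-at-zero convention
  hm <- matrix(c(0.2, 0.8, 0.2, 0.8), 2, 2)
  expect_equal(binarize_cam(hm, 0.5), hm >= 0.5)
  expect_true(all(binarize_cam(hm, 0)))      # all values > 0
  expect_error(binarize_cam(hm, 1.2), "threshold")
})

test_that("refinement keeps the maximum-intersection component", {
  pseudo <- matrix(FALSE, 20, 20)
  pseudo[2:11, 2:11] <- TRUE    # component A, area 100
  pseudo[15:18, 15:18] <- TRUE  # component B, area 16
  loc <- matrix(FALSE, 20, 20)
  loc[2:11, 2:6] <- TRUE        # covers 50 px of A
  loc[15:17, 15] <- TRUE        # covers 3 px of B
  out <- refine_mask(pseudo, loc)
  expect_true(all(out[2:11, 2:11]))
  expect_false(any(out[15:18, 15:18]))
})

test_that("a single covered component passes through unchanged", {
  pseudo <- disk_mask(24, 6)
  out <- refine_mask(pseudo, pseudo)
  expect_equal(unname(out), unname(pseudo))
})

test_that("an empty localization map leaves the pseudo mask with a warning flag", {
  pseudo <- disk_mask(24, 6)
  out <- refine_mask(pseudo, matrix(FALSE, 24, 24))
  expect_equal(unname(out) | FALSE, unname(pseudo))
  expect_equal(attr(out, "warning"), "no_intersection")
})

test_that("dimension mismatches are rejected", {
  expect_error(refine_mask(matrix(TRUE, 4, 4), matrix(TRUE, 5, 5)), "dimensions")
})

test_that("refinement agrees with a brute-force oracle on random masks", {
  for (seed in 1:50) {
    set.seed(seed)
    pseudo <- matrix(runif(64) < 0.35, 8, 8)
    loc <- matrix(runif(64) < 0.4, 8, 8)
    ours <- refine_mask(pseudo, loc)
    attr(ours, "warning") <- NULL
    ref <- oracle_refine(pseudo, loc)
    expect_identical(unname(ours), unname(ref))
  }
})

test_that("refined masks never add pixels and are single components", {
  for (seed in 1:25) {
    set.seed(seed)
    pseudo <- matrix(runif(144) < 0.3, 12, 12)
    loc <- matrix(runif(144) < 0.4, 12, 12)
    out <- refine_mask(pseudo, loc)
    expect_true(all(!out | pseudo))   # subset
    lab <- oracle_label(pseudo, 8)
    if (max(lab) > 0 && any(loc & pseudo)) {
      expect_equal(max(oracle_label(out, 8)), 1)
    }
  }
})

test_that("pixelwise mode is a plain intersection", {
  pseudo <- disk_mask(16, 5)
  loc <- matrix(FALSE, 16, 16); loc[1:8, ] <- TRUE
  expect_equal(refine_mask(pseudo, loc, mode = "pixel"), pseudo & loc)
})

test_that("refining a contaminated pseudo mask improves IoU against truth", {
  s <- generate_sample(clean_spec(seed = 21))
  impurity <- disk_mask(64, 4, cx = 56, cy = 8)
  pseudo <- s$gt_mask | impurity          # co-occurring impurity component
  loc <- disk_mask(64, 24)                # localization covers the particle
  refined <- refine_mask(pseudo, loc)
  expect_gt(mask_iou(refined, s$gt_mask), mask_iou(pseudo, s$gt_mask))
  expect_equal(unname(refined) | FALSE, unname(s$gt_mask) | FALSE)
})
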