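test_that("a constant image produces no edges", {
  img <- matrix(128, 32, 32)
  expect_false(any(canny_edges(img)))
})

test_that("a vertical intensity step localizes to within one column", {
  img <- step_image(48, 24)
  edges <- canny_edges(img, extraction_config())
  expect_true(any(edges))
  cols <- which(edges, arr.ind = TRUE)[, 2]
  expect_true(all(abs(cols - 24) <= 1))
})

test_that("edges agree with an independent reference implementation", {
  cfg <- extraction_config()
  for (seed in 1:10) {
    set.seed(seed)
    img <- matrix(runif(32 * 32, 0, 255), 32, 32)
    # smooth random fields so structured gradients exist
    img <- (img + step_image(32, sample(8:24, 1), 40, 210)) / 2
    ours <- canny_edges(img, cfg)
    ref <- oracle_canny(img, cfg$gaussian_kernel, cfg$low_threshold,
                        cfg$high_threshold)
    expect_gte(binary_iou(ours, ref), 0.9)
  }
})

test_that("non-matrix input to edge detection is rejected", {
  expect_error(canny_edges(array(0, c(4, 4, 2))), "2-D")
  expect_error(canny_edges(matrix(300, 4, 4)), "8-bit")
})

test_that("contour cleanup removes isolated specks and is idempotent", {
  cfg <- extraction_config(open_radius = 1)
  speck <- matrix(FALSE, 32, 32); speck[16, 16] <- TRUE
  expect_false(any(open_contours(speck, cfg)))

  ring <- circle_contour(64, 20)
  once <- open_contours(ring, cfg)
  twice <- open_contours(once, cfg)
  expect_identical(once, twice)
})

test_that("cleanup preserves the enclosed area of a large contour", {
  cfg <- extraction_config(open_radius = 2)
  ring <- circle_contour(64, 20)
  enclosed_before <- sum(!oracle_background(ring))
  cleaned <- open_contours(ring, cfg)
  enclosed_after <- sum(!oracle_background(cleaned))
  expect_equal(enclosed_after, enclosed_before, tolerance = 0.1)
})

test_that("closed contours are filled to their analytic area", {
  cfg <- extraction_config()
  ring <- circle_contour(48, 10)
  mask <- fill_and_select(ring, cfg)
  expect_equal(sum(mask), pi * 100, tolerance = 0.15)
})

test_that("small components are discarded relative to the largest", {
  cfg <- extraction_config(area_keep_frac = 0.5, min_area = 1)
  edges <- circle_contour(64, 10, cx = 22, cy = 22)
  # a 4-px closed speck: border of a 4x4 block encloses 2x2
  edges[48:51, 48] <- TRUE; edges[48:51, 51] <- TRUE
  edges[48, 48:51] <- TRUE; edges[51, 48:51] <- TRUE
  mask <- fill_and_select(edges, cfg)
  lab <- oracle_label(mask, 8)
  expect_equal(max(lab), 1)
  expect_true(mask[22, 22])       # the disk survived
  expect_false(any(mask[47:52, 47:52]))
})

test_that("equal-area components tie and both survive", {
  cfg <- extraction_config(area_keep_frac = 1, min_area = 1)
  e <- matrix(FALSE, 40, 40)
  for (off in c(5, 25)) {
    e[off + 0:9, off] <- TRUE; e[off + 0:9, off + 9] <- TRUE
    e[off, off + 0:9] <- TRUE; e[off + 9, off + 0:9] <- TRUE
  }
  mask <- fill_and_select(e, cfg)
  expect_equal(max(oracle_label(mask, 8)), 2)
})

test_that("filled foreground never leaks outside closed regions", {
  cfg <- extraction_config(area_keep_frac = 0.01, min_area = 1)
  for (seed in 1:20) {
    set.seed(seed)
    e <- matrix(runif(32 * 32) < 0.2, 32, 32)
    mask <- fill_and_select(e, cfg)
    closed_union <- !oracle_background(e)
    expect_true(all(!mask | closed_union))
  }
})

test_that("mask QC applies area bounds and component count", {
  cfg <- extraction_config(qc_area_bounds = c(0.05, 0.80))
  ok <- matrix(FALSE, 20, 20); ok[4:15, 4:13] <- TRUE   # fraction 0.30
  expect_true(qc_mask(ok, cfg)$accept)
  empty <- matrix(FALSE, 20, 20)
  expect_equal(qc_mask(empty, cfg)$reason, "empty")
  big <- matrix(TRUE, 20, 20); big[1, 1:2] <- FALSE     # fraction 0.995
  expect_equal(qc_mask(big, cfg)$reason, "too_large")
  frag <- matrix(FALSE, 20, 20); frag[2:8, 2:8] <- TRUE; frag[12:18, 12:18] <- TRUE
  expect_equal(qc_mask(frag, cfg)$reason, "fragmented")
})

test_that("pseudo masks recover clean synthetic particles accurately", {
  for (cl in 0:2) {
    s <- generate_sample(clean_spec(seed = 10 + cl, class_id = cl))
    pm <- extract_pseudo_mask(s$image)
    expect_true(pm$qc$accept)
    expect_gte(mask_iou(pm$mask, s$gt_mask), 0.9)
  }
})

test_that("a constant image yields an empty, QC-rejected mask", {
  pm <- extract_pseudo_mask(matrix(100, 64, 64))
  expect_false(any(pm$mask))
  expect_false(pm$qc$accept)
  expect_equal(pm$qc$reason, "empty")
})

test_that("small non-overlapping impurities are excluded from the mask", {
  sp <- synthetic_spec(impurity_count_range = c(5, 5), overlap_prob = 0,
                       noise_sd = 0, seed = 17)
  s <- generate_sample(sp)
  bg <- as.numeric(names(which.max(table(s$image))))  # uniform background value
  impurity_support <- s$image != bg & !s$gt_mask
  pm <- extract_pseudo_mask(s$image)
  expect_equal(sum(pm$mask & impurity_support), 0)
})

test_that("the retained component contains the particle centroid", {
  accepted <- 0L
  for (seed in 1:50) {
    s <- generate_sample(synthetic_spec(seed = seed, class_id = seed %% 3))
    pm <- extract_pseudo_mask(s$image)
    if (!pm$qc$accept) next
    accepted <- accepted + 1L
    cen <- round(colMeans(which(s$gt_mask, arr.ind = TRUE)))
    expect_true(pm$mask[cen[1], cen[2]])
  }
  expect_gte(accepted, 40)  # extraction succeeds on the vast majority of scenes
})
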