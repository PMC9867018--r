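test_that("a clean circular particle covers the analytic disk area", {
  s <- generate_sample(clean_spec(seed = 1))
  expect_equal(mean(s$gt_mask), pi * 0.3^2, tolerance = 0.05)
  # particle support equals the mask support: foreground intensity differs
  # from the uniform background exactly on the mask
  expect_true(all(s$image[!s$gt_mask] == s$image[1, 1]))
})

test_that("identical spec and seed reproduce a sample bit-for-bit", {
  sp <- synthetic_spec(seed = 42, class_id = 2)
  a <- generate_sample(sp)
  b <- generate_sample(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$gt_mask, b$gt_mask)
})

test_that("impurities appear outside the ground-truth mask and stay small", {
  sp <- synthetic_spec(impurity_count_range = c(5, 5), noise_sd = 0,
                       overlap_prob = 0, seed = 9)
  s <- generate_sample(sp)
  outside <- s$image > 130 & !s$gt_mask   # bright blobs off the particle
  lab <- oracle_label(outside, 8)
  expect_gte(max(lab), 1)
  areas <- tabulate(lab[lab > 0])
  expect_true(all(areas < sum(s$gt_mask)))
})

test_that("ground-truth foreground is a single connected component", {
  for (cl in 0:2) {
    s <- generate_sample(synthetic_spec(class_id = cl, seed = 30 + cl))
    expect_equal(max(oracle_label(s$gt_mask, 8)), 1)
  }
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(synthetic_spec(particle_radius_frac = 0.6), "particle_radius_frac")
  expect_error(synthetic_spec(class_id = 5), "class_id")
  expect_error(synthetic_spec(particle_radius_frac = 0.3,
                              impurity_radius_frac = 0.2), "impurity_radius_frac")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
})

test_that("dataset class counts follow largest-remainder rounding", {
  ds <- generate_dataset(synthetic_spec(image_size = 16), n = 10,
                         class_proportions = c(0.6, 0.2, 0.2), seed = 3)
  expect_equal(as.vector(table(vapply(ds, `[[`, 0L, "label"))[c("0", "1", "2")]),
               c(6L, 2L, 2L))
  # the empirical imbalance of the real collection reproduces exactly
  ds2 <- generate_dataset(synthetic_spec(image_size = 16), n = 1324,
                          class_proportions = c(805, 248, 271) / 1324, seed = 3)
  counts <- table(factor(vapply(ds2, `[[`, 0L, "label"), levels = 0:2))
  expect_equal(unname(c(counts)), c(805L, 248L, 271L))
})

test_that("train fraction yields the expected split sizes", {
  ds <- generate_dataset(synthetic_spec(image_size = 16), n = 10,
                         train_frac = 0.8, seed = 5)
  split <- vapply(ds, `[[`, "", "split")
  expect_equal(sum(split == "train"), 8L)
  expect_equal(sum(split == "test"), 2L)
})

test_that("proportions that do not sum to 1 are rejected", {
  expect_error(
    generate_dataset(synthetic_spec(image_size = 16), n = 6,
                     class_proportions = c(0.5, 0.2, 0.2)),
    "sum to 1"
  )
})

test_that("particle area dominates every impurity component", {
  for (seed in 1:20) {
    s <- generate_sample(synthetic_spec(seed = seed, noise_sd = 0,
                                        overlap_prob = 0,
                                        class_id = seed %% 3))
    outside <- s$image > 130 & !s$gt_mask
    lab <- oracle_label(outside, 8)
    if (max(lab) > 0) {
      expect_true(all(tabulate(lab[lab > 0]) < sum(s$gt_mask)))
    }
  }
})

test_that("texture variance inside the particle separates the class families", {
  vars <- sapply(0:2, function(cl) {
    mean(vapply(1:34, function(i) {
      s <- generate_sample(synthetic_spec(class_id = cl, seed = 500 + 3 * i + cl))
      stats::var(s$image[s$gt_mask])
    }, 0))
  })
  # granular (0) >> banded (2) >> smooth (1), with clear margins
  expect_gt(vars[1], vars[3] + 100)
  expect_gt(vars[3], vars[2] + 50)
})
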