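test_that("augmentation transforms image and mask identically", {
  s <- generate_sample(clean_spec(seed = 5, image_size = 32))
  # find a seed whose draw is a pure horizontal flip (no vflip/rotation)
  pure_hflip <- NULL
  for (sd in 1:200) {
    set.seed(sd)
    h <- runif(1) < 0.5; v <- runif(1) < 0.5; k <- sample(0:3, 1)
    if (h && !v && k == 0) { pure_hflip <- sd; break }
  }
  expect_false(is.null(pure_hflip))
  once <- augment(s, seed = pure_hflip)
  twice <- augment(once, seed = pure_hflip)
  expect_identical(twice$image, s$image)         # flip is an involution
  expect_identical(twice$gt_mask, s$gt_mask)
  expect_identical(once$gt_mask,
                   s$gt_mask[, rev(seq_len(ncol(s$gt_mask)))])
})

test_that("random cropping produces the configured geometry", {
  big <- list(image = matrix(128, 256, 256), gt_mask = matrix(TRUE, 256, 256))
  class(big) <- "labeled_sample"
  out <- augment(big, seed = 3, crop_to = 224)
  expect_equal(dim(out$image), c(224L, 224L))
  expect_equal(dim(out$gt_mask), c(224L, 224L))
  small <- list(image = matrix(0, 100, 100))
  expect_error(augment(small, seed = 1, crop_to = 224), "smaller")
})

test_that("the segmenter overfits a handful of clean samples", {
  samples <- lapply(1:5, function(i) {
    s <- generate_sample(clean_spec(seed = 60 + i, class_id = i %% 3,
                                    image_size = 32))
    list(image = s$image, mask = s$gt_mask)
  })
  set.seed(11)
  model <- build_segmenter(1, 6)
  fit <- train_segmenter(model, samples,
                         desk_config(seg_epochs = 250, batch_size = 5, seed = 11))
  acc <- mean(vapply(samples, function(s) {
    mean(predict_mask(fit$model, s$image) == s$mask)
  }, 0))
  expect_gte(acc, 0.99)
  expect_lte(fit$loss[length(fit$loss)], fit$loss[1])
})

test_that("segmenter training is reproducible under a fixed seed", {
  samples <- list(list(image = generate_sample(clean_spec(seed = 1, image_size = 32))$image,
                       mask = generate_sample(clean_spec(seed = 1, image_size = 32))$gt_mask))
  run <- function() {
    set.seed(99)
    train_segmenter(build_segmenter(1, 2), samples,
                    desk_config(seg_epochs = 4, seed = 7))$loss
  }
  expect_identical(run(), run())
})

test_that("the classifier overfits six samples, two per class", {
  samples <- lapply(1:6, function(i) {
    generate_sample(synthetic_spec(image_size = 32, class_id = (i - 1) %% 3,
                                   seed = 300 + i))
  })
  set.seed(12)
  model <- build_classifier(1)
  fit <- train_classifier(model, samples,
                          cfg = desk_config(cls_epochs = 120, cls_lr = 1e-3,
                                            batch_size = 6, seed = 12))
  inputs <- lapply(samples, function(s) array(s$image / 255, dim = c(32, 32, 1)))
  acc <- mean(predict_classes(fit$model, inputs) ==
                vapply(samples, `[[`, 0, "label"))
  expect_equal(acc, 1.0)
})

test_that("classifier training validates labels and reproduces under a seed", {
  s <- generate_sample(clean_spec(seed = 2, image_size = 32))
  bad <- s; bad$label <- 7L
  set.seed(1)
  expect_error(train_classifier(build_classifier(1), list(bad)), "labels")
  expect_error(train_classifier(build_classifier(1), list()), "empty")
  run <- function() {
    set.seed(5)
    train_classifier(build_classifier(1), list(s),
                     cfg = desk_config(cls_epochs = 3, seed = 3))$loss
  }
  expect_identical(run(), run())
})

test_that("raw-image mode consumes 1-channel inputs, concat mode 2-channel", {
  set.seed(6)
  m1 <- build_classifier(in_channels = 1)
  expect_equal(dim(m1$layers$stem$w)[3], 1L)
  m2 <- build_classifier(in_channels = 2)
  expect_equal(dim(m2$layers$stem$w)[3], 2L)
})

test_that("training rejects samples without masks", {
  set.seed(8)
  expect_error(train_segmenter(build_segmenter(1, 2), list(), desk_config()),
               "empty")
  expect_error(
    train_segmenter(build_segmenter(1, 2),
                    list(list(image = matrix(0, 16, 16))), desk_config()),
    "mask"
  )
})

test_that("tidiers summarise fits", {
  s <- generate_sample(clean_spec(seed = 3, image_size = 32))
  set.seed(2)
  fit <- train_segmenter(build_segmenter(1, 2),
                         list(list(image = s$image, mask = s$gt_mask)),
                         desk_config(seg_epochs = 3, seed = 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3L)
  gl <- glance(fit)
  expect_equal(gl$final_loss, fit$loss[3])
  expect_gt(gl$n_params, 0)
})
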