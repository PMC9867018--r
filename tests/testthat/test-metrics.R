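test_that("F1 reproduces the published worked examples", {
  expect_equal(report_round(f1_from_pr(0.864, 0.857)), 0.860)
  expect_equal(report_round(f1_from_pr(0.747, 0.692)), 0.718)
  expect_equal(report_round(f1_from_pr(0.704, 0.685)), 0.694)
  expect_equal(f1_from_pr(1, 1), 1)
  expect_equal(f1_from_pr(0, 0), 0)
  expect_error(f1_from_pr(1.2, 0.5), "\\[0, 1\\]")
})

test_that("macro averaging reconciles per-class rows with overall summaries", {
  expect_equal(report_round(macro_average(c(0.935, 0.775, 0.861))), 0.857)
  expect_equal(report_round(macro_average(c(0.858, 0.843, 0.892))), 0.864)
  expect_equal(macro_average(0.4), 0.4)
  expect_error(macro_average(numeric(0)), "empty")
  expect_equal(macro_average(c(1, 0), weights = c(3, 1)), 0.75)
})

test_that("perfect predictions score 1 on every metric", {
  r <- classification_metrics(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2), 3)
  expect_equal(r$accuracy, 1)
  expect_true(all(r$per_class$precision == 1))
  expect_true(all(r$per_class$f1 == 1))
  expect_equal(r$macro$recall, 1)
})

test_that("the symmetric TP=FP=FN=TN case scores 0.5 everywhere", {
  r <- classification_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1), 2)
  row0 <- r$per_class[r$per_class$class == 0, ]
  expect_equal(row0$tp, 1); expect_equal(row0$fp, 1)
  expect_equal(row0$fn, 1); expect_equal(row0$tn, 1)
  expect_equal(row0$precision, 0.5)
  expect_equal(row0$recall, 0.5)
  expect_equal(row0$specificity, 0.5)
  expect_equal(row0$f1, 0.5)
})

test_that("confusion counts agree with a brute-force oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 50
    true <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    r <- suppressWarnings(classification_metrics(true, pred, 3))
    for (cl in 0:2) {
      o <- oracle_confusion(true, pred, cl)
      row <- r$per_class[r$per_class$class == cl, ]
      expect_equal(c(row$tp, row$fp, row$fn, row$tn), unname(o))
      if (o["tp"] + o["fp"] > 0) {
        expect_equal(row$precision, o["tp"] / (o["tp"] + o["fp"]),
                     ignore_attr = TRUE)
      }
    }
    expect_equal(r$accuracy, mean(true == pred))
  }
})

test_that("zero denominators yield 0 with a warning", {
  w <- capture_warnings(r <- classification_metrics(c(0, 0), c(0, 0), 2))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(r$per_class$precision[2], 0)
})

test_that("input validation catches malformed label vectors", {
  expect_error(classification_metrics(c(0, 1), c(0), 2), "length")
  expect_error(classification_metrics(c(0, 5), c(0, 1), 2), "labels")
})

test_that("segmentation metrics reproduce hand-enumerated 2x2 cases", {
  gt <- matrix(FALSE, 2, 2); gt[1, 1] <- TRUE
  pred <- matrix(FALSE, 2, 2); pred[1, 1] <- TRUE; pred[1, 2] <- TRUE
  m <- segmentation_metrics(pred, gt)
  expect_equal(m$miou, 7 / 12)        # fg 1/2, bg 2/3
  gt2 <- matrix(FALSE, 2, 2); gt2[2, 2] <- TRUE
  pred2 <- matrix(FALSE, 2, 2); pred2[1, 1] <- TRUE
  expect_equal(segmentation_metrics(pred2, gt2)$miou, 0.25)  # fg 0, bg 1/2
  ident <- segmentation_metrics(gt, gt)
  expect_equal(ident$miou, 1); expect_equal(ident$mpa, 1)
  expect_equal(ident$pixel_accuracy, 1)
})

test_that("MIoU is symmetric but MPA need not be", {
  set.seed(41)
  for (rep in 1:10) {
    a <- matrix(runif(36) < 0.4, 6, 6)
    b <- matrix(runif(36) < 0.4, 6, 6)
    ab <- suppressWarnings(segmentation_metrics(a, b))
    ba <- suppressWarnings(segmentation_metrics(b, a))
    expect_equal(ab$miou, ba$miou)
  }
  gt <- matrix(FALSE, 2, 2); gt[1, 1] <- TRUE
  pred <- matrix(FALSE, 2, 2); pred[1, 1] <- TRUE; pred[1, 2] <- TRUE
  expect_false(isTRUE(all.equal(segmentation_metrics(pred, gt)$mpa,
                                segmentation_metrics(gt, pred)$mpa)))
})

test_that("classes absent from both maps are excluded from the means", {
  gt <- matrix(0L, 3, 3); gt[2, 2] <- 1L
  pred <- gt
  m <- segmentation_metrics(pred, gt, num_classes = 4)
  expect_equal(nrow(m$per_class), 2L)   # classes 2 and 3 never occur
  expect_equal(m$miou, 1)
})

test_that("F1 obeys the harmonic-geometric-arithmetic mean ordering", {
  set.seed(51)
  p <- runif(200); r <- runif(200)
  f1 <- f1_from_pr(p, r)
  expect_true(all(f1 <= sqrt(p * r) + 1e-12))
  expect_true(all(sqrt(p * r) <= (p + r) / 2 + 1e-12))
})

test_that("display rounding is half-up at 3 decimals", {
  expect_equal(report_round(0.8605), 0.861)
  expect_equal(report_round(0.8604999), 0.860)
  expect_equal(report_round(0.7185), 0.719)
})
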