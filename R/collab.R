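#' Collaborative segmentation/classification training
#'
#' The alternating loop in which the two tasks supervise each other using
#' only image-level labels. Round 0 trains both networks independently: the
#' segmenter on the QC-accepted unsupervised pseudo masks, the classifier
#' on raw images. Each later round (i) computes Grad-CAM localization maps
#' from the current classifier at every training image's true label,
#' (ii) refines each current training mask by maximum-intersection component
#' selection ([refine_mask()]), (iii) retrains the segmenter from scratch on
#' the refined masks, (iv) feeds the fresh segmenter's predicted masks
#' through [mask_guided_input()] to retrain the classifier, and (v) records
#' metrics. The loop stops after `cfg$rounds` rounds or as soon as a
#' refinement round flips fewer than `cfg$stop_tol` of all mask pixels.
#'
#' Samples whose pseudo mask fails QC never enter segmenter training but
#' stay in the classifier's training set; the localization threshold is
#' `cam_threshold` on the normalised heat map.
#'
#' @param samples list of `labeled_sample` objects with `split` set
#'   (`"train"` / `"test"`). Ground-truth masks, when present, are used only
#'   for reporting, never for training.
#' @param extraction_cfg an [extraction_config()].
#' @param cfg a [train_config()].
#' @param cam_threshold binarization threshold for the heat maps.
#' @return a `collab_state`: `history` (tibble, one row per completed round
#'   including round 0), `masks` (final training masks), `initial_masks`,
#'   `qc` (tibble of QC outcomes), `segmenter`, `classifier`,
#'   `rounds_run`, `config`.
#' @export
collaborative_loop <- function(samples, extraction_cfg = extraction_config(),
                               cfg = desk_config(), cam_threshold = 0.5) {
  splits <- vapply(samples, `[[`, "", "split")
  train_idx <- which(splits == "train")
  test_idx <- which(splits == "test")
  if (length(train_idx) == 0) stop("no training samples", call. = FALSE)

  extraction <- lapply(samples[train_idx], function(s) {
    extract_pseudo_mask(s$image, extraction_cfg)
  })
  qc_tbl <- tibble::tibble(
    index = train_idx,
    accepted = vapply(extraction, function(e) e$qc$accept, TRUE),
    reason = vapply(extraction, function(e) e$qc$reason, ""),
    foreground_frac = vapply(extraction, function(e) e$qc$foreground_frac, 0)
  )
  if (!any(qc_tbl$accepted)) {
    stop("all pseudo masks rejected by QC; cannot start segmenter training",
         call. = FALSE)
  }
  masks <- lapply(extraction, `[[`, "mask")
  initial_masks <- masks

  has_gt <- !is.null(samples[[train_idx[1]]]$gt_mask)
  in_ch_cls <- if (cfg$mask_mode == "concat") 2L else 1L

  fit_seg <- function(current_masks, round_seed) {
    keep <- which(qc_tbl$accepted)
    train_set <- lapply(keep, function(t) {
      list(image = samples[[train_idx[t]]]$image, mask = current_masks[[t]])
    })
    scfg <- cfg; scfg$seed <- round_seed
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(round_seed, 11))
    model <- build_segmenter(1, cfg$seg_width)
    train_segmenter(model, train_set, scfg)
  }
  fit_cls <- function(cls_masks, in_channels, round_seed) {
    ccfg <- cfg; ccfg$seed <- round_seed
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(round_seed, 22))
    model <- build_classifier(in_channels, cfg$cls_n0, cfg$cls_growth,
                              cfg$cls_block_layers, 3)
    train_classifier(model, samples[train_idx], cls_masks, ccfg)
  }

  eval_round <- function(seg_model, cls_model, masked, current_masks) {
    cls_acc <- NA_real_
    seg_miou <- NA_real_
    if (length(test_idx) > 0) {
      inputs <- lapply(samples[test_idx], function(s) {
        if (masked) {
          mask_guided_input(s$image, predict_mask(seg_model, s$image), cfg$mask_mode)
        } else as_cube(s$image / 255)
      })
      pred <- predict_classes(cls_model, inputs)
      truth <- vapply(samples[test_idx], `[[`, 0, "label")
      cls_acc <- mean(pred == truth)
      if (has_gt) {
        seg_miou <- mean(vapply(test_idx, function(i) {
          segmentation_metrics(predict_mask(seg_model, samples[[i]]$image),
                               samples[[i]]$gt_mask)$miou
        }, 0))
      }
    }
    mask_iou_gt <- if (has_gt) {
      mean(vapply(seq_along(train_idx), function(t) {
        mask_iou(current_masks[[t]], samples[[train_idx[t]]]$gt_mask)
      }, 0))
    } else NA_real_
    list(cls_acc = cls_acc, seg_miou = seg_miou, mask_iou_gt = mask_iou_gt)
  }

  # round 0: independent initial training
  seg_fit <- fit_seg(masks, derive_seed(cfg$seed, 1000))
  cls_fit <- fit_cls(NULL, 1L, derive_seed(cfg$seed, 2000))
  ev <- eval_round(seg_fit$model, cls_fit$model, masked = FALSE, masks)
  history <- tibble::tibble(
    round = 0L, cls_test_accuracy = ev$cls_acc, seg_test_miou = ev$seg_miou,
    train_mask_iou_vs_gt = ev$mask_iou_gt, flipped_frac = NA_real_
  )

  rounds_run <- 0L
  for (r in seq_len(cfg$rounds)) {
    # (i) localization maps from the current classifier at the true label
    locs <- lapply(seq_along(train_idx), function(t) {
      s <- samples[[train_idx[t]]]
      input <- if (r == 1) {
        as_cube(s$image / 255)
      } else {
        mask_guided_input(s$image, predict_mask(seg_fit$model, s$image),
                          cfg$mask_mode)
      }
      hm <- grad_cam(cls_fit$model, input, s$label)
      binarize_cam(hm, cam_threshold)
    })
    # (ii) refine the current masks
    new_masks <- lapply(seq_along(masks), function(t) {
      m <- refine_mask(masks[[t]], locs[[t]])
      attr(m, "warning") <- NULL
      m
    })
    flipped <- sum(vapply(seq_along(masks), function(t) {
      sum(xor(masks[[t]], new_masks[[t]]))
    }, 0))
    total_px <- sum(vapply(masks, length, 0))
    flipped_frac <- flipped / total_px
    masks <- new_masks
    # (iii) retrain segmenter from scratch on refined masks
    seg_fit <- fit_seg(masks, derive_seed(cfg$seed, 1000 + r))
    # (iv) segmenter predictions guide the classifier
    pred_masks <- lapply(samples[train_idx], function(s) {
      predict_mask(seg_fit$model, s$image)
    })
    cls_fit <- fit_cls(pred_masks, in_ch_cls, derive_seed(cfg$seed, 2000 + r))
    # (v) record metrics
    ev <- eval_round(seg_fit$model, cls_fit$model, masked = TRUE, masks)
    history <- dplyr::bind_rows(history, tibble::tibble(
      round = r, cls_test_accuracy = ev$cls_acc, seg_test_miou = ev$seg_miou,
      train_mask_iou_vs_gt = ev$mask_iou_gt, flipped_frac = flipped_frac
    ))
    rounds_run <- r
    if (flipped_frac < cfg$stop_tol) break
  }

  structure(
    list(history = history, masks = masks, initial_masks = initial_masks,
         qc = qc_tbl, segmenter = seg_fit$model, classifier = cls_fit$model,
         rounds_run = rounds_run, config = cfg,
         train_idx = train_idx, test_idx = test_idx),
    class = "collab_state"
  )
}

#' @export
print.collab_state <- function(x, ...) {
  cat(sprintf("<collab_state> %d collaborative round(s) + round 0\n", x$rounds_run))
  print(x$history)
  invisible(x)
}
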