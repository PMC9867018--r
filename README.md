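# pollenseg

Weakly supervised collaborative segmentation and classification of
single-particle pollen micrographs.

## The problem

Identifying airborne pollen taxa from scanning electron micrographs is a
routine need in aerobiology, but real micrographs are cluttered with dust
and sand-like impurities that sit next to — and sometimes on — the grain.
Classifiers trained on whole images learn the clutter; pixelwise masks
would fix that but are expensive to annotate. `pollenseg` trains a
segmenter and a classifier **from image-level class labels only**, letting
each model improve the other's supervision:

1. **Unsupervised pseudo masks.** Canny edges (Gaussian smoothing, Sobel
   gradient, non-maximum suppression, dual-threshold hysteresis at 50/100),
   contour cleanup, border flood fill, and an area filter that keeps the
   dominant region — the grain is much larger than any impurity. An
   automated QC rule replaces manual screening of failed extractions.
2. **Grad-CAM refinement.** For the true class *c* the classifier yields
   the activation map *L<sup>c</sup>* = ReLU(Σ<sub>k</sub> α<sub>k</sub><sup>c</sup> A<sup>k</sup>)
   with α<sub>k</sub><sup>c</sup> = (1/Z) Σ<sub>ij</sub> ∂y<sup>c</sup>/∂A<sup>k</sup><sub>ij</sub>.
   Binarised, it selects the **maximum-intersection component** of the
   pseudo mask, discarding impurity blobs whole.
3. **Mask-guided classification.** The classifier consumes the image
   weighted by its predicted mask (or a 2-channel concatenation), so
   clutter pixels are suppressed.
4. **Collaborative rounds** alternate (refine masks → retrain segmenter →
   retrain classifier on mask-guided inputs) until a round changes almost
   nothing.

A seeded synthetic micrograph generator (one textured particle per image in
three morphology classes, hard impurity clutter, Gaussian noise, the
805:248:271 class imbalance of the motivating collection) provides
ground-truth masks so the whole pipeline is testable offline. Metric
utilities cover precision/recall/specificity/F1 with macro averaging, and
mean IoU / mean pixel accuracy over classes including background.

## Worked example

```r
library(pollenseg)

ds <- generate_dataset(synthetic_spec(image_size = 64), n = 100, seed = 1)
state <- collaborative_loop(ds, extraction_config(), desk_config(seed = 1))
tidy(state)
```

```
# A tibble: 2 × 5
  round cls_test_accuracy seg_test_miou train_mask_iou_vs_gt flipped_frac
  <int>             <dbl>         <dbl>                <dbl>        <dbl>
1     0              0.85         0.869                0.863           NA
2     1              0.9          0.881                0.863            0
```

Row 0 is the independent initial training: the segmenter fitted on the
QC-accepted unsupervised pseudo masks (mean IoU 0.863 against ground
truth, held-out MIoU 0.869) and a raw-image classifier (test accuracy
0.85). Row 1 is the first collaborative round: the classifier now sees
mask-guided inputs built from the segmenter's predictions and reaches
accuracy 0.90, and the retrained segmenter's held-out MIoU rises to
0.881. `flipped_frac = 0`
says activation refinement found nothing left to remove — on these scenes
the area filter already deleted every clutter component — so the loop
stops early. `autoplot(state)` plots the history;
`plot_micrograph(ds[[1]]$image, state$masks[[1]])` overlays a mask;
`grad_cam()` / `binarize_cam()` / `refine_mask()` expose the refinement
steps individually.

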