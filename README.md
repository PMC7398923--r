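# insectseg

Instance segmentation of insect anatomy from images: detect, classify and
pixel-extract the **thorax**, **abdomen**, **wings** and **legs** of a
mosquito-like insect, entirely on CPU, with no deep-learning framework
dependency.

The package is aimed at two audiences: vector-surveillance and taxonomy
workflows that want anatomical components cut out of specimen photographs
for downstream identification, and method developers who want a compact,
fully inspectable implementation of an anchor-based instance segmentation
pipeline — every forward and backward pass is in this package (R plus
Rcpp/RcppArmadillo kernels), cross-checked against finite differences and
brute-force oracles in the test suite.

## The method

The pipeline is a two-stage anchor-based instance segmenter:

* a residual backbone with a **feature pyramid** (strides 4/8/16,
  configurable depth) extracts multi-scale features;
* a **region-proposal stage** scores anchors (3 sub-scales × 5 aspect
  ratios per grid cell) for objectness and regresses box offsets
  $t_x = (x^*-x_a)/w_a$, $t_y = (y^*-y_a)/h_a$, $t_w = \log(w^*/w_a)$,
  $t_h = \log(h^*/h_a)$;
* three **parallel heads** on bilinearly RoI-aligned patches classify each
  region (4 anatomy classes + background, cross-entropy loss $-\log p$),
  tighten its box (smooth-L1 on the four delta residuals), and predict a
  28×28 instance mask (per-pixel **focal loss**
  $-(1-p_t)^\gamma \log p_t$, $\gamma = 2$, which keeps the rare thin-leg
  pixels from being drowned out by background).

Training is SGD with momentum 0.9, weight decay 0.001 and a four-phase
step schedule (1e-3, 5e-4, 1e-5, 1e-6 at epoch fractions 0.2/0.4/0.8).
Evaluation reports per-class precision, recall and average precision at
mask-IoU thresholds 0.30/0.50/0.70, plus mAP (the mean AP over the four
classes).

A built-in generator produces synthetic insect images with exact polygon
ground truth, reproducing the structural challenges of the real task —
above all the extreme background-vs-leg pixel imbalance of 1–3 px legs —
so the whole pipeline can be trained and evaluated reproducibly in
minutes. Ground truth can also come from VGG Image Annotator (VIA)
project JSON (`read_via()` / `write_via()`).

## Worked example

Train a tiny model on 14 synthetic insects and evaluate it on 4 held-out
ones (about two minutes on one CPU core):

```r
library(insectseg)

imgs <- generate_dataset(18, list(), seed = 42)
fit  <- train(imgs[1:14], train_config(epochs = 40, batch_size = 1, seed = 7))
tail(fit$log[, c("epoch", "lr", "loss_cls", "loss_mask", "loss_reg")], 3)
#>    epoch    lr  loss_cls  loss_mask   loss_reg
#> 38    38 2e-05 0.8740326 0.06964918 0.05787412
#> 39    39 2e-05 0.8574891 0.06847805 0.05390072
#> 40    40 2e-05 0.8856635 0.07101946 0.05661098

dets <- detect(imgs[[15]], fit)
dets[[1]]
#> <detection abdomen score=0.958 box=(62.4,63.1,26.3,22.0) mask=309 px>
```

Each detection carries a class label, a confidence, a tightened box and a
full-resolution binary pixel mask; `extract_anatomy()` writes one RGBA
cut-out PNG per detection (source pixels under the mask, transparent
elsewhere). Evaluating against the exact ground truth:

```r
va   <- imgs[15:18]
dd   <- lapply(va, function(im) detect(im, fit))
gts  <- lapply(va, image_ground_truth)
names(dd) <- names(gts) <- sapply(va, `[[`, "image_id")
evaluate_dataset(dd, gts, thresholds = c(0.3, 0.5, 0.7))
#> Anatomy   IoU=0.30  Prec(%)  Rec(%)   IoU=0.50  Prec(%)  Rec(%)   IoU=0.70  Prec(%)  Rec(%)
#> thorax                27.27   75.00              27.27   75.00               9.09   25.00
#> abdomen               17.39  100.00              17.39  100.00               8.70   50.00
#> wing                   0.00    0.00               0.00    0.00               0.00    0.00
#> leg                   11.71   59.09               4.50   22.73               0.00    0.00
#>
#> mAP by IoU threshold:
#>   IoU=0.3  mAP=0.3365 (33.65%)
#>   IoU=0.5  mAP=0.2638 (26.38%)
#>   IoU=0.7  mAP=0.0495 (4.95%)
```

Reading the table: recall for the compact body parts is already high
after this very short run, while the semi-transparent wings and the thin
legs — the hard classes by design — need longer training and remain the
limiting factor at stricter IoU thresholds. Precision here is the
instance-level fraction of detections that match a ground truth at the
given mask IoU; the matching is greedy in score order, and AP integrates
the precision–recall curve with 101-point interpolation.

A command-line interface covering `simulate`, `convert`, `train`,
`infer` and `evaluate` is installed at `inst/cli/insectseg`; every run
writes a JSON manifest sufficient to reproduce it.

See the vignette (`vignettes/insect-anatomy-segmentation.Rmd`) for the
model, the losses, what the synthetic generator does and does not
emulate, and the design decisions.

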