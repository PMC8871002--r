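# saxfcn

Fully convolutional network (FCN) segmentation of the left ventricle (LV)
cavity and myocardium in short-axis cardiac MR slices — an end-to-end,
dependency-light R implementation of the whole pipeline: data conversion,
class weighting, a compact encoder–decoder network, training, and a full
segmentation-metric suite, exercisable entirely on built-in synthetic
phantoms.

## The problem

Quantifying cardiac function (ejection fraction, LV volume, LV mass)
requires delineating the LV cavity and the myocardial wall on short-axis MR
slices. Manual contouring is slow and error-prone, so the task is posed as
per-pixel classification: each pixel of a 256 × 192 slice is assigned to
background (class 0), LV cavity (class 1) or myocardium (class 2).
Delayed-enhancement datasets ship as 3D NIfTI volumes with 5-code masks
(0 background, 1 cavity, 2 normal myocardium, 3 infarction, 4 no-reflow);
the pathology codes are folded into myocardium for this 3-class task.

Two practical obstacles dominate:

* **Pixel representation.** Volumes are exported to 8-bit slice images with
  min–max normalization, `NP = 255 · (N − min N)/(max N − min N)` rounded
  half-up, so a {0, 1, 2} label matrix maps to {0, 128, 255}.
* **Class imbalance.** Background is > 85 % of pixels, so an unweighted
  classifier collapses onto it. Each class is weighted by inverse
  frequency, normalized as `w_c = 1/(C · f_c)`, which makes
  `w_c f_c = 1/C` for every present class: each class contributes equally
  to the expected loss.

## The network

A 15-layer fully convolutional encoder–decoder (≈ 40 k parameters):

| stage | layers | output |
|---|---|---|
| encoder | 3×3 conv (16) → BN → ReLU → 2×2/s2 max-pool | 128 × 96 × 16 |
| bottleneck | 3×3 conv (32) → BN → ReLU → 3×3 conv (64) → BN → ReLU | 128 × 96 × 64 |
| decoder | 4×4/s2 transpose conv (16) | 256 × 192 × 16 |
| head | 3×3 conv (C) → softmax → pixel classification | 256 × 192 × C |

All convolutions are same-padded; the transpose convolution's raw `2H+2`
output is symmetrically cropped to `2H`. Training minimizes class-weighted
cross-entropy `L = −Σ_p w_{t(p)} log ŷ_p[t(p)] / Σ_p w_{t(p)}` under SGDM,
Adam or RMSProp; the reference operating point is Adam, learning rate
0.001, mini-batch 4. Evaluation reports per-class and foreground-mean
Dice `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)`, sensitivity, specificity,
PPV, NPV, global/mean accuracy, mean/weighted IoU, and the boundary-F1
(BF) score with tolerance 0.75 % of the image diagonal.

There is no pre-installed deep-learning framework in this stack: the
convolution, batch-norm, pooling and transpose-convolution layers and their
backward passes are implemented in this package (Rcpp/RcppArmadillo,
im2col + GEMM), and every gradient is verified against central finite
differences in the test suite.

## Worked example

Synthetic phantoms (bright disk cavity + annular myocardium on a noisy,
background-dominated field) stand in for clinical slices, here at 64 × 48
so the example runs in ~20 s on one CPU:

```r
library(saxfcn)

params <- phantom_params(height = 64, width = 48,
                         cavity_radius_range = c(6, 12),
                         myo_thickness_range = c(3, 6),
                         center_jitter = 3)
ds <- generate_dataset(100, params, seed = 11)

cw <- training_class_weights(ds)
print(cw)
#>   class  frequency    weight
#> 1     0 0.86120605 0.3870541
#> 2     1 0.05493164 6.0681481
#> 3     2 0.08386230 3.9747695

spec <- fcn_spec(input_shape = c(64, 48, 1), num_classes = 3)
net  <- build_network(spec, seed = 1011)
fit  <- train(net, ds$slices[ds$split$train],
              train_config("adam", learning_rate = 0.001, epochs = 5,
                           mini_batch = 4, seed = 2011),
              weights = cw)

test <- ds$slices[ds$split$test]
report <- metric_report(predict_masks(fit$network, test),
                        lapply(test, `[[`, "mask"))
print(report)
#> Per-class metrics:
#>   class   dice jaccard sensitivity specificity    ppv    npv
#> 1     0 0.9970  0.9940      0.9942      0.9987 0.9998 0.9600
#> 2     1 0.9651  0.9326      0.9349      0.9999 0.9974 0.9973
#> 3     2 0.9542  0.9124      0.9968      0.9917 0.9150 0.9997
#>
#> Foreground means:
#>      dice     jaccard sensitivity specificity         ppv         npv
#>    0.9597      0.9225      0.9659      0.9958      0.9562      0.9985
#>
#> Dataset summaries:
#> global_accuracy   mean_accuracy        mean_iou    weighted_iou   mean_bf_score
#>          0.9921          0.9753          0.9463          0.9849          1.0000
```

The weight table shows the imbalance correction: background (86 % of
pixels) is down-weighted to 0.39 while the cavity (5.5 %) gets 6.07, and
`weight × frequency = 1/3` for each class. After five epochs the held-out
foreground mean Dice is 0.96 — on phantoms, whose geometry is far easier
than clinical anatomy (see the vignette for what this does and does not
establish).

Real volumes enter through the same path:

```r
vol <- read_volume("Case_P001.nii.gz", "Case_P001_gt.nii.gz")
slices <- volume_to_slices(vol, exclude_empty = TRUE)   # Eq.-1 normalize,
                                                        # remap, 256 x 192
```

A command-line front end covers the same stages
(`phantom | convert | weights | train | evaluate | predict | pipeline |
sweep`):

```sh
Rscript -e 'saxfcn::saxfcn_main()' pipeline --out run1 --seed 1
```

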