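# pdcnet

Segmentation of small, irregular, low-contrast lesions in 2-D grayscale
medical images — the regime of pituitary adenomas in brain MRI, where the
lesion occupies a few percent of the image, its boundary is ragged and its
intensity barely differs from surrounding tissue.

The package implements, end to end and without any deep-learning
framework dependency:

- a U-Net-style **encoder–decoder** whose levels pair a basic convolution
  with a **parallel dilated convolutional module (PDCM)**: five branches —
  a 1×1 convolution, three 3×3 convolutions at dilation rates 2/4/6
  (receptive fields 1/5/9/13), and a squeeze-excitation-style **channel
  attention** branch — fused progressively (branch *k* receives the
  previous branch's output added to the projected input) and summed;
- **residual connections** at every level, with 1×1 projections where
  channel counts change;
- the **soft Dice loss** `1 − 2Σyŷ/(Σy² + Σŷ²)` for class imbalance, and
  the four confusion-count metrics Sensitivity `TP/(TP+FP)` (as printed in
  the reference definitions; a `standard = TRUE` switch gives the
  conventional `TP/(TP+FN)`), Specificity `TN/(FP+TN)`, Dice
  `2TP/(2TP+FN+FP)` and IoU `TP/(TP+FN+FP)`;
- Adam training with best-on-validation-loss checkpointing, a per-epoch
  CSV history, and an **ablation harness** over the architecture variants
  (`no_pdcm`, `pdcm_no_previous`, `pdcm_previous`, each ± residual);
- a seeded **synthetic phantom generator** producing image/mask pairs in
  the same regime (lesion fraction 0.5–3%, irregular star-convex outline,
  contrast 0.12, noise 0.05), so the full pipeline runs with no data;
- PNG image/mask I/O, padded prediction export, qualitative montages, and
  read-only NIfTI slice import.

All layers, backpropagation and the optimizer are implemented in the
package (convolution kernels in compiled code); analytic gradients are
verified against finite differences in the test suite.

## Worked example

Train on eight 32×32 phantoms (a deliberate overfit probe) and evaluate:

```r
library(pdcnet)

p    <- PhantomParams(imageSize = 32, seed = 11)
ds   <- generateDataset(p, 8, "train")
data <- list(train = ds, val = ds)

cfg <- ModelConfig(depth = 3, baseChannels = 8)   # pdcm_previous + residual
buildModel(cfg, seed = 5)
#> PDCNet segmentation network
#>   variant:   pdcm_previous + residual
#>   encoder:   8 -> 16 -> 32 channels, 2 poolings
#>   params:    63,851
#>   init seed: 5

tc  <- TrainConfig(batchSize = 8, epochs = 80, learningRate = 1e-3, seed = 5)
fit <- trainModel(buildModel(cfg, seed = 5), data, tc)
round(tail(fit$history, 3), 4)
#>    epoch train_loss val_loss   sens   spec   dice    iou
#> 78    78     0.1501   0.0503 0.9695 0.9995 0.9408 0.8909
#> 79    79     0.1706   0.0471 0.9608 0.9994 0.9386 0.8865
#> 80    80     0.1874   0.0436 0.9571 0.9993 0.9483 0.9040

ev <- evaluateModel(fit$model, ds, batchSize = 8)
round(ev$mean, 4)     # mean of per-image metrics
#> sensitivity specificity        dice         iou
#>      0.9571      0.9993      0.9483      0.9040
round(ev$pooled, 4)   # counts pooled over the split first
#> sensitivity specificity        dice         iou
#>      0.9487      0.9993      0.9447      0.8952
```

After 80 full-batch steps the network has nearly memorised the eight
phantoms: per-image Dice 0.948 means the predicted lesions overlap the true
ones almost completely, and specificity ≈ 1 reflects the overwhelming
background class. The training loss still fluctuates epoch to epoch because
DropBlock is active; validation (run in evaluation mode) is smooth. By 300
steps the probe reaches Dice ≥ 0.95, which the test suite asserts.

The multi-scale claim is directly measurable:

```r
receptiveFieldReport(cfg)[1:4, ]
#>   level branch kernel dilation extent inputExtent
#> 1     1     b1      1        1      1           1
#> 2     1     b2      3        2      5           5
#> 3     1     b3      3        4      9           9
#> 4     1     b4      3        6     13          13
```

A command-line front end (`inst/cli/pdcnet.R`) wraps the same functions:
`synth`, `train`, `evaluate`, `predict`, `ablate`; see `?pdcnetMain`.

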