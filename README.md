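# nucmorph

Single-cell nuclear morphometry for DAPI-stained wide-field fluorescence
microscopy. `nucmorph` takes 512x512 12-bit frames (0.2150 um/px) and
produces, per nucleus: a quality-filtered segmentation, a chromatin
condensation statistic, a 104-dimensional shape/texture feature vector,
and class predictions from linear baselines and convolutional networks --
including a patch-scale classifier whose per-patch decisions form
interpretable heat-maps. It is aimed at groups quantifying early
chromatin-organisation changes (compression, cytokine stimulation,
transformation) in cultured cells or tissue slices.

## What it computes

**Segmentation.** Marker-based watershed: grayscale
opening-by-reconstruction, Sobel edges, filled edge regions shrunk to
interior seeds (foreground) plus the lowest 1% of frame values
(background), then seeded region growing. Filters remove nuclei larger
than 128x128 px or overexposed (>= 25% of pixels above 3700 counts), and
trim a 15-px band from nuclei on the frame border. A Shanbhag-threshold
variant handles crowded tissue-slice fields.

**Chromatin condensation.** Within each nucleus the heterochromatin
threshold is

```
t = min + 0.6 (max - min)
```

over nuclear pixel intensities; HC is the summed intensity at or above
`t`, EC the remainder, and HC/EC the condensation ratio (higher = more
condensed). Groups are compared with unpaired t-tests.

**Features.** area, eccentricity, major/minor axis length, roundness (5),
rotation-invariant uniform LBP at radii 2 and 3 (20), parameter-free
threshold adjacency statistics (54), and Zernike moment magnitudes to
degree 8 (25): 104 features per nucleus, 99 per patch (shape block
omitted).

**Classifiers.** Weighted ridge logistic regression, linear SVM, and a
100-tree depth-8 random forest, with feature-ablation tables; a VGG-style
CNN (10 conv layers, 4 max pools, filters 32 to 512, PReLU/ReLU, weighted
cross-entropy, Adam, patience early stopping); and a patch-level
classifier that averages per-patch probabilities into the image decision
and exports decision and filter heat-maps. Drift-blurred acquisition sets
are detected by pairwise machine-distinguishability above a 60% accuracy
threshold.

**Synthetic data.** A seeded generator produces DAPI-like fields with
ground-truth masks, class-conditional focus texture, and the three noise
modes (overexposure, drift blur, edge placement), so the whole pipeline is
testable without microscope data.

## A worked example

```r
library(nucmorph)

classes <- preset_classes()            # "open" and "condensed" chromatin
fs <- synth_field(classes, n_nuclei = 5, seed = 3)
nuclei <- segment_field(fs$field)
length(nuclei)
#> [1] 5

chromatin_table(nuclei)[, c("nucleus_id", "threshold", "hc", "ec", "ratio")]
#> # A tibble: 5 x 5
#>   nucleus_id threshold     hc      ec  ratio
#>        <int>     <dbl>  <int>   <int>  <dbl>
#> 1          1     2374  122745 3514930 0.0349
#> 2          2     2368   64057 2370127 0.0270
#> 3          3     2385. 320622 2420845 0.132
#> 4          4     2367   26568 2169707 0.0122
#> 5          5     2377. 301810 2245113 0.134
```

Two of the five planted nuclei came from the `condensed` spec; they
surface here as records 3 and 5, whose HC/EC ratios (0.132, 0.134) sit
several-fold above the `open` nuclei (0.01-0.03) -- a larger share of
their DAPI intensity lies above the heterochromatin threshold (~2370
counts for these nuclei). Feature extraction and a classifier on top:

```r
recs <- c(synth_nuclei(classes$open, 100, seed = 1),
          synth_nuclei(classes$condensed, 100, seed = 2))
y <- rep(c("open", "condensed"), each = 100)
feats <- assemble_features(recs)       # 200 x 104 feature tibble
split <- fair_split(y, seed = 7)       # equal per-class 15% validation
fit <- train_classifier(feats, y, linear_config("logistic_regression"), split)
glance(fit)
#> # A tibble: 1 x 5
#>   kind                train_accuracy val_accuracy n_train n_validation
#>   <chr>                        <dbl>        <dbl>   <int>        <int>
#> 1 logistic_regression              1            1     170           30
```

The synthetic classes are deliberately well separated; validation accuracy
of 1 means every held-out nucleus was assigned the correct condensation
class. `feature_ablation()` produces the ablation table,
`build_vgg()`/`train_cnn()` the convolutional classifier, and
`build_patchnet()`/`predict_image()` the patch-level decision heat-maps. A
thin command-line wrapper for the common steps lives at
`inst/cli/nucmorph`.

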