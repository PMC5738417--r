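---
title: "Nuclear morphometry and chromatin condensation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry and chromatin condensation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## The problem this package addresses

Chromatin reorganisation is among the earliest structural signatures of
cellular transformation: condensed (hetero-)chromatin redistributes, and
nuclear shape and texture shift in ways that precede gross morphological
change. In DAPI-stained wide-field fluorescence images the stain intensity
tracks local DNA density, so these changes are measurable at single-cell
resolution. `nucmorph` implements a complete measurement chain for 512x512
12-bit frames at 0.2150 um/px: nucleus segmentation with acquisition-noise
quality control, a scalar chromatin-condensation statistic, hand-crafted
shape/texture feature vectors, and two classifier families (linear baselines
with ablation tables, and convolutional networks including a patch-scale
interpretable variant).

Because raw microscope data are bulky and instrument-specific, the package
ships a seeded synthetic generator that produces DAPI-like fields with
ground-truth masks. Every stage of the pipeline is tested against that
generator; this vignette records the models, the defaults, and what those
tests do and do not establish about real data.

## The synthetic image model

A nucleus is an ellipse with area-equivalent radius drawn per class
(default 24 +/- 2.5 px, i.e. ~5 um at the package pixel size) and
eccentricity uniform on a class interval. Its interior carries a baseline
(euchromatin) intensity of 1500 counts with i.i.d. Gaussian noise (sd 40
counts), plus Poisson-many heterochromatin foci rendered as Gaussian bumps
(`sigma = foci_radius_px / 2`, truncated at 3 sigma) whose peak reaches
`base_intensity * foci_gain`. Fields are 512x512 frames over a Gaussian
background whose mean sits at ~1% of the 12-bit range, so the segmenter's
"lowest 1% of pixel values" background-marker rule has support. All draws
derive from one master seed through a counter-based stream: identical
`(spec, seed)` give bit-identical images.

Three modelling choices deserve explanation, because each was forced by the
behaviour of the condensation statistic (next section):

* **Outward-only boundary softening.** The mask edge is smoothed by a 1-px
  Gaussian applied outside the mask only. If boundary pixels inside the
  mask blended toward background, the within-nucleus intensity minimum
  would sit near zero and the condensation threshold (a fixed fraction of
  the min-to-max range) would drop below the euchromatin baseline,
  classifying essentially the whole nucleus as heterochromatin in weakly
  condensed cells.
* **Saturating focus overlap.** Overlapping foci combine by maximum, not by
  summation. Physically, focus brightness is bounded by local chromatin
  density; numerically, additive stacking would create isolated hotspots
  whose brightness grows with focus count, dragging the max-referenced
  threshold upward and paradoxically shrinking the measured heterochromatin
  segment as condensation increases.
* **Equal focus gain across the preset classes.** The built-in `open` and
  `condensed` presets share the focus model (radius 2.5 px, gain 2.0) and
  differ only in focus number (Poisson mean 5 vs 30). Heterochromatin
  puncta are the same physical objects in normal and transformed cells;
  condensation changes how many there are. This matters for the
  marker-conditioned patch analysis below, which asks whether the classifier
  treats individual foci as condensed-class evidence -- a question that only
  makes sense if a focus looks the same in both classes.

The generator also reproduces the three acquisition-noise modes the quality
control stages target: overexposure (a chosen fraction of a nucleus' pixels
forced above the 3700-count saturation line), drift blur (normalised linear
motion kernel convolved with the frame; total intensity is preserved up to
boundary truncation while high-frequency texture is destroyed), and edge
placement (a nucleus translated onto the frame border).

What the generator does *not* emulate: optics (no point-spread function or
photon-counting noise), intra-nucleus intensity gradients, nucleoli,
multi-channel stains, or the deconvolution artefacts of real wide-field
processing. Tests passing on synthetic data therefore establish the
*internal correctness* of each stage (the arithmetic, the filters, the
contracts) and the recoverability of planted structure; they do not certify
classification accuracy on any real cell line.

## Segmentation

Cultured-cell fields follow a four-step procedure:

1. grayscale opening-by-reconstruction (erosion by an approximate disk of
   radius 10 px, ~2 um, then geodesic reconstruction under the original;
   compiled Vincent hybrid algorithm) -- this flattens intra-nucleus
   texture so edges come from nucleus boundaries rather than foci;
2. Sobel gradient magnitude on the reconstructed image;
3. marker construction: edge pixels (Otsu-thresholded gradient) are filled
   into candidate regions; touching candidates are split by a watershed on
   the distance transform, and each candidate is shrunk to its interior
   (distance > 5 px) to form a foreground seed. Pixels within the lowest 1%
   of frame values (computed per frame) form the background marker;
4. marker-based watershed: seeded region growing on the reconstructed
   intensities (`EBImage::propagate`), with basins restricted to the
   candidate support.

Quality filters then run in a fixed order: nuclei whose bounding box
exceeds 128 px in either dimension are dropped (not shrunk); nuclei with at
least 25% of pixels strictly above 3700 counts are dropped as overexposed
(the fraction comparison is inclusive, the count comparison strict); nuclei
touching the frame border lose the 15 px of mask nearest each touched
border, and are dropped entirely if less than half the mask survives --
this keeps a usable nucleus interior while discarding the rim blur that
frame-edge deconvolution introduces. Surviving nuclei are centred in a
128x128 canvas with background zeroed outside the mask, the input
convention for all downstream stages. The 15-px band is removed from the
nucleus, not the frame; reading the rule as a frame crop would discard
interior nuclei that merely approach the border.

Tissue-slice fields use the alternative route: Shanbhag (dark-background)
entropy auto-threshold, Gaussian blur (sigma 2 px) of the selection,
re-binarisation at 0.5, and watershed on the distance transform. Entropy
thresholding assumes the object class carries non-negligible histogram
mass: on sparse fields over a narrow dim background its minimum sits at the
background mode (selecting half the frame) or deep inside the object tail
(selecting nothing). The tissue tests therefore use fixtures in the regime
the method is meant for -- crowded large nuclei (10-20% foreground) over a
broad background (280 +/- 110 counts, standing in for stromal/adipose
autofluorescence at high magnification).

## The condensation statistic (HC/EC)

Within a nucleus mask (given, or identified by Otsu thresholding with the
largest connected component kept), the heterochromatin threshold is

> t = min + 0.6 (max - min)

over mask pixels only. HC is the summed intensity of pixels >= t
(membership is inclusive; the coefficient 0.6 is a documented constant),
EC is the remaining intensity, and the condensation ratio is HC/EC. The
implementation guarantees exact conservation (HC + EC equals total mask
intensity in integer arithmetic), scale covariance (multiplying the image
by c > 0 leaves the ratio unchanged), and raises a degenerate-input error
when EC = 0 rather than returning infinity, so batch statistics stay
finite. Group comparisons use Welch's two-sided unpaired t-test.

One property worth knowing: when foci are absent or their gain approaches
1, the min-to-max range is set by noise alone and the threshold falls into
the noise tail, giving a focus-free nucleus a spurious noise-driven HC
segment. The expected ratio is therefore monotone in focus count and gain
only once foci dominate the intensity maximum; the property tests assert
monotonicity in that regime (gain >= 1.2, count >= 5) and the degenerate
end is documented here rather than asserted away.

## Morphometric features

The full per-nucleus vector has 104 entries; patches omit the shape block
and have 99. The decomposition is a documented package convention chosen to
match those totals:

| block | entries | definition |
|---|---|---|
| shape | 5 | area (px), eccentricity and axis lengths from the mask's second-moment ellipse (regionprops convention, axis = 4 sqrt(eigenvalue)), roundness 4 pi A / P^2 |
| LBP | 20 | rotation-invariant uniform local binary patterns, 8 neighbours at radii 2 and 3 (10 bins each), jointly normalised to sum 1 |
| PFTAS | 54 | parameter-free threshold adjacency statistics: 9-bin neighbour-count histograms at three automatic thresholds (Otsu-referenced mean +/- sd) on the image and its complement |
| Zernike | 25 | moment magnitudes to degree 8 over the mask's enclosing circle, intensity-normalised |

The perimeter in the roundness formula is estimated from the 4-neighbour
boundary crack count with the Cauchy-Crofton factor pi/4, which is exact
for disks averaged over orientations; roundness is capped at 1. LBP codes
compare interpolated neighbours to the centre with a small absolute
tolerance (1e-6 counts) so that exactly flat regions classify as the flat
uniform pattern instead of being scattered by interpolation rounding.
Grey-level run-length/co-occurrence and Gabor features are deliberately
absent from the feature set.

## Linear models and ablation

Three baselines run on the feature matrix: class-weighted L2-regularised
logistic regression (ridge, default lambda 0.01), a linear-kernel SVM at
library-default cost, and a random forest with 100 trees of maximum depth
8. Features are z-scored on the training split for the logistic and SVM
models; trees see raw features. Class weights are inverse-frequency
normalised to mean 1 -- the reading of "proportional" weighting that
up-weights rare classes, consistent with using weights to protect precision
and recall on the minority class. The ablation table retrains the model
once per named feature group with that group's columns removed, on the same
split throughout, with the all-features baseline as the first row; the
default groups mirror the structure of a published ablation analysis (all
texture, all shape, each texture block, each shape feature).

## The convolutional classifier

The network is a VGG-style stack: input batch normalisation (with learned
scale and shift), ten 3x3 convolutions in five blocks of two with PReLU
activations, 2x2/stride-2 max pooling after the first four blocks, filters
32 doubling to 512 after each pool, two 512-unit fully connected ReLU
layers with dropout 0.5, and a softmax output. The block grouping (2-2-2-2-2)
and FC widths are package conventions; the layer counts, kernel size,
filter progression and activation types are fixed contracts checkable
without training. Training is Adam on a class-weighted cross-entropy with
He initialisation; the reference protocol values (learning rate 8e-5,
batch 32 for full nuclei / 128 for patches, patience 20) are the config
defaults. Validation is evaluated every `eval_every` updates, one patience
step per evaluation, and the returned model is the parameter state of the
best validation loss, not the last step.

The engine itself is written in R over BLAS matrix products: convolutions
assemble their im2col matrix from nine contiguous slices of channels-first
arrays, and the backward pass scatters through the same slices, so no
per-pixel indexing happens in interpreted code. On one CPU core a
mini-batch update of the full 10-layer network on 32x32 inputs takes about
2-3 s. The desk-scale demonstrations therefore train on 32x32
block-averaged crops with a larger step size (1e-3) and a 60-update cap --
sizes chosen so the whole suite runs on a laptop core -- rather than on
128x128 crops at the reference learning rate; on the trivially separable
synthetic classes this reaches >95% validation accuracy. Determinism holds
per device under a fixed seed (single-threaded BLAS).

## The patch-scale interpretable classifier

A small CNN (three 3x3 convolutions with PReLU, 16 filters, global average
pooling, softmax; receptive field 7 px) is applied with shared weights to
every patch of a nucleus. Patch extraction enumerates the full stride
lattice and keeps patches that are at least 85% nucleus and pass the
overexposure rule applied at patch scale (same 25%/3700 definition, patch
area substituting nucleus area). The image-level prediction is the
arithmetic mean of the retained patches' probability vectors -- averaged on
probabilities, not logits -- which makes the identity between image
probability and patch-mean exactly testable and the per-patch decisions
directly interpretable as a spatial map. Training uses the
non-overlapping lattice (stride = patch size); inference heat-maps default
to stride 4 for granularity. Filter heat-maps apply the convolutional
stack (fully convolutional) to the whole 128x128 crop, one map per
last-layer filter; both the decision map and the filter maps are exposed,
since either rendering can be the relevant visualisation.

Marker-conditioned analysis: given per-nucleus marker coordinates (e.g.
centromeric foci from a second channel; in tests, the generator's planted
focus centres), 11x11 patches centred on markers are compared with the
non-overlapping complement of the lattice. Odd patch sizes centre exactly
on the coordinate; even sizes put it at index floor(s/2)+1. Complement
patches exclude any lattice patch that overlaps a marker patch at all. On
synthetic data the trained patch classifier assigns marker patches to the
condensed class far more often than complement patches, mirroring the
published observation that focus-bearing patches of normal cells are
systematically called as the more condensed class.

## Drift-blur quality control

Specimen drift destroys texture but leaves intensity histograms nearly
unchanged, so it cannot be caught per image. Instead, same-class
acquisition sets are tested pairwise for machine distinguishability: for
each unordered pair and each of 3 repeats (distinct fair-split seeds) a
binary classifier is trained and its validation accuracy recorded; a set is
flagged iff *every* comparison involving it exceeds the 60% threshold in
*every* repeat -- the package's operationalisation of "consistently"
distinguishable. Flagging is monotone in the threshold, and a threshold of
1 can never flag.

The default trainer is ridge logistic regression on the morphometric
features with a deliberately strong penalty (lambda 1): set comparisons run
at a few dozen nuclei per set, where the feature dimension rivals the
sample size and a weakly regularised model separates even identically
distributed sets by chance. A patch-scale CNN trainer is provided as an
alternative; any function satisfying the trainer contract is accepted.

## Splits, evaluation, embeddings

Validation sets are "fair": equal per-class counts of
floor(fraction * n / k) each (floor rounding), totalling at most 15% of the
data by default. Confusion matrices index reference classes on rows and
predictions on columns, with unseen predicted labels added as warned-about
extra columns; accuracy is trace over total. Two-dimensional embeddings
wrap Barnes-Hut t-SNE under a seed; for CNNs the embedded representation is
the penultimate-layer activation (the last hidden layer before the output),
for linear models the raw feature vector.

## Numerical and degenerate-input conventions

Constant images cannot be thresholded (error, not a guess); empty masks and
EC = 0 raise typed degenerate-input errors; single-pixel masks get area 1,
zero axes and roundness 1; glmnet's two-column minimum is met by a zero pad
column when a single feature survives ablation; non-finite training loss
aborts with a divergence error rather than continuing. Seeds are explicit
arguments everywhere randomness exists, and derived per-item seeds stay
below 2^31.

## Problem sizes used by the test suite

The packaged checks run at desk scale by design: 100 fields of 5 nuclei
for segmentation recovery; 3 acquisition sets of ~40 nuclei for drift QC
(validation fraction 0.3, so each comparison validates on 24 nuclei); 200
nuclei per class for classifier recovery (fair 15% split, 60 validation
nuclei); ~900 11x11 patches for the patch classifier with a 120-update
cap. These sizes are the package's documented study conditions, not tuned
quantities.

## Known limitations

* Synthetic realism is deliberately limited (see above); absolute HC/EC
  values depend on the generator's intensity model and should not be
  compared with values from real images.
* The condensation threshold is range-referenced and therefore
  sensitive to single extreme pixels; on real data, overexposure filtering
  upstream is what keeps it stable.
* Shanbhag thresholding is unreliable on sparse, low-background fields;
  the cultured-cell segmentation path is the right tool there.
* The CNN engine is single-core R: adequate for the packaged problem
  sizes, not for datasets of tens of thousands of full-resolution nuclei.
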