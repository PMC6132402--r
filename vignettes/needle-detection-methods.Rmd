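---
title: "Needle detection in 3D ultrasound: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Needle detection in 3D ultrasound: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During percutaneous interventions a clinician advances a thin needle
(17--22 G, 0.72--1.47 mm outer diameter) toward a target while watching an
ultrasound image. In 3D ultrasound the needle occupies roughly one voxel in
three thousand, its brightness overlaps that of bone, fascia and other
specular structures, and -- especially under steered (phased-array) beams --
parts of the shaft reflect no energy back and are simply invisible.
`needlefinder` localizes the needle in a static 3D volume in three stages:

1. **Voxel detection** by one of two learned detectors:
   a *triplanar patch classifier* or a *2.5D thick-slice fully
   convolutional segmenter*;
2. **Axis estimation** by RANSAC fitting of a fixed-diameter cylinder to
   the detected voxels;
3. **Visualization**: extraction of the plane that contains the whole
   needle axis and is perpendicular to the coronal planes -- the in-plane
   view a clinician would steer toward.

Axis convention used everywhere: array dimension 1 is *lateral*, dimension 2
is *axial* (the beam/depth direction), dimension 3 is *elevational*.
"Coronal" planes are lateral-elevational planes. Voxels are isotropic;
indices are 1-based in R and a voxel's physical center is
`origin + (index - 0.5) * voxel_size` so that all geometric errors can be
computed in millimetres.

## Detector 1: triplanar patch classification

Every voxel is described by three orthogonal 21 x 21 cross-sections
(4.2 x 4.2 mm at 0.2 mm voxels) centered on it. Two architectures are
provided: **ShareCNN** convolves all three planes with one shared bank of
filters, **IndepCNN** trains three independent banks. Both use four
convolutional layers of 32, 48, 64 and 96 filters with 3 x 3 kernels,
then concatenate the three feature maps into fully connected stages of
128, 64 and 2 units with a softmax output; ReLU activations throughout and
dropout 0.5 on the first two fully connected stages. Under the
bank-counting convention (filters x kernel area, summed over layers, times
banks; biases and input depth excluded) these architectures have 2160 and
6480 convolutional parameters; `count_conv_weights()` exposes the
conventional input-depth-dependent count as well.

Two design points deserve a note:

* **No pooling.** With valid (unpadded) 3 x 3 convolutions the spatial
  size walks 21 → 19 → 17 → 15 → 13 and the three 13 x 13 x 96 maps are
  flattened directly. Pooling would trade localization accuracy for
  context, which is the wrong trade for a structure one voxel thick.
* **Borders.** Patch centers near the volume boundary are zero-padded, so
  every voxel is classifiable; the evaluation should keep in mind that
  the outermost ~2 mm carry padded context.

**Imbalanced training.** A volume has ~1 needle voxel per 3000. Training
draws a *balanced* set: all-or-sampled needle patches plus an equal number
of uniformly drawn background patches, augmented by random 0/90/180/270
degree rotations around the axial axis. After the initial fit the model
scans background voxels and the false positives -- the "most aggressive"
non-needle voxels -- are harvested, ranked by predicted needle
probability, and swapped in for random negatives; the same weights are then
updated at a ten-fold lower learning rate. This bootstrap round is the
mechanism that buys precision: random negatives are overwhelmingly easy,
so the initial decision boundary sits too close to the needle class.

Optimization is stochastic gradient descent with RMSProp scaling and
categorical cross-entropy. The reference learning rates are 1e-4 for the
initial fit and 1e-5 for update rounds; these pair with the full-size
architecture and long training schedules. For the desk-scale configurations
used in the tests (filter banks of 4-12 filters, a few hundred patches,
minutes of CPU) we raise both by a factor of ten (1e-3 / 1e-4) -- RMSProp
step sizes are roughly the learning rate itself, so a handful of epochs at
1e-4 cannot move He-initialized weights appreciably. The 10:1 train:update
ratio is preserved. Early stopping monitors the loss on a 10% split of the
balanced set (patience 5, epoch cap 100 by default).

## Detector 2: thick-slice (2.5D) semantic segmentation

The segmenter decomposes the volume into 2D cross-sections perpendicular to
the lateral and the elevational axis, one per voxel step. Each processing
section is stacked with its two parallel neighbours at a gap of *d* mm into
a 3-channel "thick slice" -- enough 3D context to recognize a needle that
is invisible in the middle section, at a fraction of the cost of 3D
convolution. The default gap is *d* = 2.0 mm; `gap_sweep()` reruns the
sweep procedure (0.5 / 1.3 / 2.0 / 2.7 mm against the single-slice
condition) on phantoms. At phantom scale (12.8 mm volumes) the optimum
shifts toward smaller *d* than in full-size acquisitions -- the sweep
harness exists precisely to measure this on the data at hand.

One network (**ShareFCN**) serves both view directions. The encoder is a
VGG-19-style stack (stages of 2, 2, 4, 4, 4 convolutions with 64, 128,
256, 512, 512 filters, 3 x 3 kernels, five 2x max-pools that record their
argmax indices). The decoder unpools by 2 (pool-5 indices) into a
512-filter convolution, by 2 (pool-4 indices) into a 256-filter
convolution, and by 8 into the final 2-filter convolution and per-pixel
softmax. Skip connections tap the encoder before the 4th and 5th pools and
are added after a channel-matching 1 x 1 convolution, fusing coarse
semantics with local detail. Dropout (0.85) regularizes the two deepest
encoder convolution stages.

Decisions that were genuinely open:

* **The x8 unpooling.** Index unpooling requires the decoder map and the
  recorded pool to have equal channel counts. That holds for the first
  x2 of the x8 stage (pool-3 indices, 256 channels) but not for pools 2
  and 1 (128 / 64 channels). The implementation therefore unpools x2 with
  the pool-3 indices and finishes with nearest-neighbour x4; a plain
  nearest x8 is available as `final_upsample = "nearest"`.
* **Width scaling.** `width_scale` multiplies every channel count, so a
  quarter- or eighth-width network trains on a CPU in minutes while
  keeping the architecture's shape; `width_scale = 1` reproduces the
  reference design.
* **Input normalization.** Envelope ultrasound intensities are heavy-tailed
  (multiplicative speckle); each slice is log-compressed (`log1p`) and
  standardized before the first convolution (`normalize = "log"`), the
  usual display-side conditioning. Raw intensities are a config option.
* **Training windows.** Training uses fixed-size windows (default full
  slices; `crop_size` optionally crops 32-256 px windows centered near the
  needle for needle-containing sections and randomly for background ones).
  The network is fully convolutional, so inference always runs on full
  cross-sections; cropping only reduces the per-update cost and improves
  the pixel class balance at desk scale.
* **Learning rate.** Adam with the reference initial rate 1e-4 (batch size
  one). As with the patch network, the width-scaled desk configurations
  in the tests use 3e-4.

Training balances at the *section* level: needle-free cross-sections are
downsampled to match needle-containing ones (the pixel-level imbalance
within a needle slice is left to the loss). Volumes are augmented by
arbitrary-angle rotations around the axial axis before slice extraction
(10 by default; fewer in the desk-scale tests). A section's label map is
the ground-truth mask's intersection with the processing (middle) plane;
neighbour channels contribute context only.

At inference each direction yields a probability volume; the two are fused
voxelwise by the **geometric mean** `sqrt(p_lat * p_elev)` -- the
multiplicative analogue of averaging, threshold-equivalent to the raw
product (also available) -- and thresholded at 0.5. Fusion precedes
thresholding. The geometric mean is commutative, bounded, idempotent on
equal inputs and annihilated by a zero in either view: a detection must be
supported by both views, which is where the fusion's precision comes from.

## Axis estimation and the in-plane view

RANSAC fits a straight cylinder of fixed diameter (default 2 mm, covering
all experimented needles) to the detected voxel centers: 1000 iterations of
a minimal 2-point sample (a line determines the cylinder axis), consensus =
voxels within one radius of the infinite line, ties broken by first
occurrence, fully seeded. By default the winning line is refined as the
principal axis (total-least-squares) of its inliers and the consensus is
recounted; `refine = FALSE` gives plain RANSAC. The finite segment enters
only at tip designation: inlier centers are projected onto the axis, the
endpoints are the extreme projections, and the tip is the endpoint farther
from the entry face (chosen automatically as the lateral/elevational face
nearest either endpoint, or given as a hint). Fewer than `min_inliers`
supporting voxels yields an explicit "no needle found" result rather than
a garbage axis.

The needle plane is spanned by the axis direction and the axial unit
vector; its normal is their (normalized) cross product, so the plane
contains the whole axis and is perpendicular to every coronal plane. An
axis within 1e-6 rad of the axial direction makes this construction
degenerate; the lateral-axial plane through the axis point is returned,
flagged. `render_inplane_view()` resamples the volume on this plane
(trilinear, zero fill) and reports the axis endpoints as a sidecar overlay
-- never burned into the pixels.

## The synthetic phantom

No ex-vivo volumes ship with the package; every trainable and testable
behavior is exercised on a synthetic phantom whose defaults emulate a
motorized linear-array acquisition: 174 x 189 x 188 voxels at 0.2 mm, a
17 G (1.47 mm) needle up to 30 mm long entering through the lateral face at
a steepness angle of 10-30 degrees to the coronal plane.

* **Background**: a smooth low-frequency echogenicity field times
  Rayleigh-distributed multiplicative speckle, lightly Gaussian-blurred --
  the standard envelope-statistics approximation. The histogram is
  right-skewed and the texture decorrelates within ~10 voxels.
* **Distractors**: randomly oriented bright tubes and ellipsoids whose
  gains overlap the needle's, so intensity alone cannot separate the
  classes -- the reason a learned detector is needed at all.
* **Needle**: a voxelized cylinder (a voxel belongs to the mask iff its
  center is within one radius of the axis segment), brightened
  multiplicatively. `dropout_fraction` removes *contiguous runs* of the
  shaft from the image (not i.i.d. voxels), mimicking beam-angle-dependent
  invisibility under steered transducers; the ground-truth mask keeps the
  invisible voxels, exactly as a human annotator labels the whole needle,
  so recall genuinely penalizes invisibility. An optional acoustic shadow
  attenuates everything below the shaft along the axial direction.
* **Determinism**: generation is a pure function of the config's seed
  (Mersenne-Twister; the caller's RNG state is restored), so datasets,
  folds and training runs are exactly reproducible.

Steepness angles are reported as ranges per acquisition setting; their
distribution within a range is not known, so sweeps sample them uniformly.

What the phantom does *not* model: wave propagation and reverberation,
anisotropic point-spread functions, curved or deflected needles, tissue
deformation, or time series. Passing the phantom tests therefore shows
that the pipeline's machinery -- representation, optimization, fusion,
geometry -- works end to end under realistic statistics; it does not
certify clinical performance on real acquisitions.

## Evaluation

`voxel_metrics()` reports recall, precision, specificity and F1 (the
harmonic mean of recall and precision) from the voxel confusion counts.
Precision with zero predicted positives is *missing*, not zero; folds in
that state are excluded from precision/F1 averages and counted. Geometric
accuracy uses two measures: the **tip error** is the point-plane distance
from the ground-truth tip to the detected needle plane (the system
visualizes a plane, not a point, so this is the error a user experiences),
and the **orientation error** is the angle between detected and true axes,
computed on undirected axes (`acos` of the absolute dot product) since a
sign convention would be arbitrary. `length_stratified_errors()` sweeps the
inserted needle length over phantom replicates and reports means with
standard errors of the mean; `crossval()` runs the volume-disjoint k-fold
protocol (folds assigned round-robin at dataset creation, leakage is a hard
error) and reports fold metrics and their mean and standard deviation
across folds (fold-averaged, matching the mean-plus-minus-sd presentation).

## Desk-scale study sizes

The shipped tests exercise every learning behavior at sizes chosen for a
single CPU: phantoms of 32-96 voxels per side, eighth-width FCNs trained
for ~15 epochs on ~250-500 balanced samples, 1000-iteration RANSAC, three
to five seeds per stochastic claim. These are the package's own choices of
study size; the configurations scale up by changing `width_scale`, the
phantom shape, and the epoch counts. The learning smoke tests use the 17 G
(1.47 mm) needle: at eighth-width capacity the 22 G needle's out-of-plane
view (a ~4-voxel dot) is not reliably learnable in minutes of CPU, and the
tests are meant to verify mechanisms, not to benchmark the hard case.

## Known limitations

* The two detectors are trained per-dataset; no transfer or fine-tuning
  across voxel sizes is provided.
* The cylinder model assumes a straight needle; strongly deflected needles
  would need a curved model.
* The dense patch scan is O(voxels) network evaluations and is the slow
  path; the FCN route is the practical full-volume detector on a CPU.
* Index unpooling in the final x8 decoder stage is approximated beyond the
  pool-3 level (see above); a learned-deconvolution decoder is not
  implemented.
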