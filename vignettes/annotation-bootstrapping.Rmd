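---
title: "Bootstrapping seabed image annotation with background-model novelty detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrapping seabed image annotation with background-model novelty detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Benthic photo surveys from AUVs and ROVs produce tens of thousands of
seabed images per dive, and the organisms of interest (OOI — shells,
starfish, sponges, general megafauna) occupy a vanishing fraction of the
pixels. Manual annotation is dominated not by classification but by
*finding* objects. `benthoscan` implements a machine-learning-assisted
annotation workflow that automates the finding: unsupervised novelty
detection proposes candidate regions, humans only filter and refine them,
and the filtered set bootstraps a supervised instance-segmentation model
whose detections are in turn reviewed on a simple accept/reject basis.

The workflow has four stages:

1. **Novelty detection.** Images are clustered by global background
   appearance; one *data-driven background model* (DBM) — a shallow
   autoencoder — is trained per cluster on random background patches and
   applied convolutionally; thresholded reconstruction-error maps yield
   ranked square *training proposals*.
2. **Filtering and refinement.** A human accepts/labels proposals in
   descending novelty order (stopping at 600 per class) and adjusts a
   suggested circle to fit each object.
3. **Segmentation training and inference.** 500×500 crops around the
   refined circles (pixels inside a circle count as object) are augmented
   ("boosted") and used to train a pluggable instance-segmentation
   backend; at inference, images are zero-padded to multiples of 64,
   and connected "interesting" pixels of the output mask become
   minimum-enclosing-circle *annotation candidates*.
4. **Candidate review.** Humans keep the true positives.

The package implements stages 1, 2 and 4 completely, and everything
around stage 3 except the network itself: a `SegmentationBackend` is any
function from an image to a class-id mask, and trivial
threshold/oracle backends exercise the full plumbing. Training a deep
segmentation network is out of scope by design.

## The background model

Each cluster's DBM is a three-layer autoencoder on flattened RGB patches
$x \in \mathbb{R}^r$ with $r = 3 r_e^2$ for patch edge $r_e$:

$$l = \sigma(Wx + b), \qquad x' = \sigma(W'l + b'), \qquad
  \sigma(x) = \log(1 + e^x),$$

with latent size $s = [s_c\, r]$ for compression factor $s_c$. The
reconstruction error
$$F(x, x') = \lVert x - x' \rVert^2$$
is the **novelty score**: the model only learns to reconstruct common
background texture, so rare object patches reconstruct poorly. $F$ is
implemented as the *sum* of squared componentwise differences; a mean
would only rescale every score and threshold simultaneously, and the
percentile threshold below is invariant to that choice.

Defaults (all in `aen_config()` / `pipeline_config()`):

| parameter | default | meaning |
|---|---|---|
| `patch_edge` ($r_e$) | 39 px | patch edge; $r = 4563$ |
| `compression` ($s_c$) | 0.1 | latent fraction; $s = 456$ |
| `n_train_patches` | 10^4 | random training patches per cluster |
| `epochs` / `minibatch` | 100 / 128 | Adam, fixed learning rate 10^-3 |
| `K` | 5 | background clusters per survey |
| `stride` | 2 px | convolutional application stride |
| `percentile` | 0.99 | threshold percentile |
| `min_box_edge` | 30 px | minimum proposal edge |
| `per_class_limit` | 600 | review stop per class |
| `crop_size` | 500 px | training-sample crop edge |

Training uses Xavier (uniform Glorot) initialisation for both weight
matrices, zero biases, and minimises the minibatch mean of $F$. All
randomness — patch sampling, initialisation, epoch shuffling — is drawn
from R's RNG under a single seed, and the C++ training loop is
deterministic, so a seed reproduces a model bit-for-bit on one platform.

Pixels are normalised to $[0,1]$ (by the image dtype maximum). The
softplus output layer is strictly positive, so a $[0,1]$ target range
keeps perfect reconstruction feasible; an unscaled 0–255 range would not
materially change the method but would start training far from the
operating range.

### From error grid to proposals

Applying a DBM at stride 2 produces an error value per patch centre. The
stride-reduced grid is upscaled to image resolution by bilinear
interpolation, exact at the grid centres, with edge replication into the
$(r_e-1)/2$ margin where no complete patch fits, so the novelty map
covers the full image. Application is sliced over grid rows to bound
memory; the result is provably independent of slicing (each patch is an
independent column of a matrix product), which the tests assert.

The map is then convolved with an all-ones $r_e \times r_e$ kernel
(zero-padded, shape-preserving) — a dilation that merges nearby
responses. Dilation happens *before* thresholding, and the cluster
threshold
$$t_k = \frac{1}{|U_k|} \sum_{i \in U_k} P_{99}(N_i)$$
is computed on the dilated maps — the percentile is taken where it is
applied. Percentiles interpolate linearly between order statistics
(`stats::quantile()` type 7), and segmentation uses a strict `>`;
neither convention is forced by the method, both are pinned down for
determinism and checked against independent oracles in the tests.

Connected components are 8-connected (more forgiving of thin diagonal
structures), labelled deterministically in row-major discovery order.
Each region becomes a square box centred on its tight bounding box's
centre, expanded to at least 30 px, and *shifted inward* (never
truncated) at image borders so every proposal crops to an exact square.
The proposal score $\eta$ is the sum of the region's novelty values, and
proposals are ranked by descending $\eta$ with `(image_id, region_id)`
tie-breaks, so a ranking is reproducible byte-for-byte.

## The review data model

Human decisions are *inputs*, modelled as tables: filtering decisions
cover a prefix of the ranking and map each proposal to a label or a
rejection (`filter_proposals()` enforces the prefix and the 600-per-class
stop); refinement stores an adjusted circle, defaulting to the
proposal's inscribed circle; candidate review is an accept set keyed by
`(image_id, region_id)`. `decide_proposals_from_truth()` simulates a
reviewer from ground truth for end-to-end runs.

Training samples are 500×500 crops centred on each refined circle,
shifted inward at borders; every refined circle whose centre falls in
the crop is carried along. Boosting cycles the 8 axis-aligned
symmetries first, then combines them with ±10% scale jitter about the
crop centre; circles are transformed exactly with the pixels (the tests
verify pixel-level IoU ≥ 0.95 between a transformed circle and its
re-rendered object). The symmetry/jitter set is deliberately
conservative — label-preserving for textureless seabed backgrounds — and
configurable.

## Evaluation and the cost model

Detection is scored region-wise, the way grid review experiences it: an
OOI counts as found if its centre lies in some region (`tp_theta`,
recall side); a region counts as correct if it contains at least one OOI
centre (`tp_rho`, precision side). Centre containment is the strictest
simple reading of "contained" and is the default; an any-overlap rule is
available. The headline score is
$$F_2 = \frac{5 \cdot \text{recall} \cdot \text{precision}}
             {4 \cdot \text{precision} + \text{recall}},$$
recall-weighted because a missed organism is costlier than a false alarm
that one click dismisses.

Annotation economics are two lines:
$$\tau_\text{assisted}(n) = 18.34\,\text{s} \cdot n + 12327\,\text{s},
\qquad \tau_\text{manual}(n) = 89.27\,\text{s} \cdot n.$$
The rates are data, not constants: `fit_time_model()` recomputes them
from logged per-dataset session durations
(`published_annotation_sessions()` ships the reference sessions), and
the defaults equal that fit. The crossover
$n^* = 12327/(89.27 - 18.34) \approx 174$ images is exact;
`speedup_and_breakeven()` reports it together with the speed-up
function, whose value at 550 images rounds to 2.19.

`parameter_search()` re-runs stage 1 for each triplet of
$K \in \{1,5,10,50,100\}$, $r_e \in \{29,39\}$, $s_c \in \{0.1,0.2\}$
under one seed and tabulates recall/precision/F2 per triplet.

## The synthetic fixture generator

`generate_dataset()` renders seabed-like images so every stage is
testable without survey data: a per-sediment base colour plus
band-limited noise (blurred white noise — deterministic and
dependency-free, chosen over gradient noise), an optional smooth radial
illumination falloff, and rare planted objects (disks, ellipses,
three-lobed blobs) with exact ground-truth circles written in the same
circle-CSV dialect the review stages use. Three sediment presets
(`smooth_sand`, `gravel`, `dark_mud`) have well-separated base colours,
so two-type mixtures are linearly separable in the clustering feature
space. Object pixels are kept below a configurable rarity bound (2% by
default) because the novelty assumption — objects are rare — is exactly
what the generator must honour; generation warns when a spec violates
it.

What the generator does *not* emulate: real benthic texture statistics,
shadows and overlap between organisms, mosaicing artefacts, colour casts
of different cameras. Passing the fixture suite therefore demonstrates
that the machinery is correct and that the method behaves as designed
when its assumptions hold — not that any particular recall will be
reached on a real survey.

## Design choices made where the design was open

* **Clustering features.** The exact feature recipe behind the published
  clustering is not specified beyond "principal component projection
  coordinates and an entropy measure". This package uses 32×32 grayscale
  thumbnails, a dataset-level PCA keeping 8 components, and the Shannon
  entropy of the 256-bin histogram. PCA scores keep their natural,
  variance-ordered scale: z-scoring each component individually would
  inflate pure-noise directions to the same weight as the separating
  ones and demonstrably breaks k-means recovery of cleanly separable
  backgrounds. The entropy term is centred and scaled to the median
  component spread so it contributes without dominating. Everything is
  exposed in `cluster_images()` so alternatives can be swapped in.
* **k-means.** k-means++ seeding with 10 restarts and Lloyd refinement;
  a restart that empties a cluster is re-seeded from the point farthest
  from its assigned centre. Initialisation is not specified upstream;
  this is a standard, reproducible choice.
* **Patch sampling** is uniform over images, then uniform over valid
  positions, with replacement — "random" is read in the simplest way,
  unstratified.
* **Box placement.** When a region is expanded to the 30-px minimum, the
  square is centred on the tight box's centre (not the region centroid);
  for asymmetric regions the difference is at most a few pixels and the
  tight-box centre is cheaper and order-independent.
* **Candidate classes.** Regions of touching nonzero classes merge
  (class-agnostic "interesting" rule); the candidate keeps the modal
  class id as a convenience label. Automatic class merging below a
  sample-count threshold is left to the user.
* **K on fixtures.** For synthetic datasets the cluster count is set to
  the number of planted sediment types (K = 2 for the standard two-type
  mixture); K = 5 is a survey-scale default, not a property of the
  method.

## Numerical notes and problem sizes

* `softplus()` is evaluated as $x + \log(1+e^{-x})$ for $x>0$, so
  encode/decode never overflow.
* Dilation uses an exact integral-image box sum (clamped at 0 against
  cancellation), not an FFT, so impulse responses are exact.
* Minimum enclosing circles run Welzl's algorithm on the convex hull
  after a deterministic pseudo-shuffle; degenerate (collinear,
  duplicate) inputs fall back to the farthest pair. Radii are floored at
  0.5 px only when masks are converted to displayable candidates.
* Empty inputs are first-class: empty masks yield empty proposal tables,
  an evaluation without regions reports recall 0 and flags precision as
  undefined (reported as 0).

The shipped test-suite exercises the full pipeline on 20 synthetic
512×512 images (two sediment types, two planted objects each) with
reduced training effort — 20 epochs on 2000 patches per cluster — which
preserves the method's behaviour (loss curves flatten well before epoch
20 on these textures) while keeping a complete run on a single CPU core
in the minutes range. Unit tests use smaller patches (5–13 px) where
only the machinery, not the detection quality, is under test.

## Limitations

* The segmentation backend shipped here is deliberately trivial; real
  deployments plug in a trained network via the file-based backend
  contract (image in, class-id mask out).
* One DBM per cluster assumes backgrounds are homogeneous *within* an
  image; scenes mixing sediments inside one frame dilute the background
  model.
* The novelty threshold marks a fixed fraction (≈1%) of pixels per
  cluster, so on object-free images it still proposes something —
  by design (false proposals are cheap to reject), but worth knowing.
* Session-rate refits assume review time scales linearly with image
  count; the shipped reference rates come from three surveys and one
  annotation toolchain.
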