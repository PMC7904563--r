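---
title: "Methods: spatially resolved permeability analysis at tricellular junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially resolved permeability analysis at tricellular junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Macromolecules cross an endothelial monolayer mainly between cells, and the
points where three or more cells meet — tricellular junctions — are
candidate hot spots for this paracellular leak. A spatially resolved
permeability assay records *where* tracer crosses: a fluorescent tracer
(e.g. FITC-avidin) binds a biotinylated substrate immediately after
crossing, so bound fluorescence spots mark transport sites. A second
channel (a VE-cadherin immunostain) shows the cell borders. The analysis
task is:

1. find the tricellular junction centroids in the border channel,
2. find tracer-accumulation spots in the tracer channel,
3. call a junction *permeable* when the distance from its centroid to the
   nearest pixel of a spot is at most 2 px,
4. report per image: the fraction of junctions that are permeable, the
   total tracer accumulation (RFU), the junction-associated share of that
   accumulation, and the mean accumulation per permeable junction.

`tjperm` implements this pipeline together with a synthetic image
generator whose ground truth is exactly known, so every stage can be
validated by parameter recovery rather than by eye.

## Synthetic monolayer generator

**Geometry.** Confluent monolayer geometry is emulated by a Voronoi
tessellation of random seed points, optionally Lloyd-relaxed
(`relaxation_steps`, default 2) so cells become rounder and more uniform,
as in a confluent endothelium. The Delaunay triangulation is enumerated
exactly (all seed triples with an empty circumcircle); Voronoi vertices —
circumcentres of Delaunay triangles — are the ground-truth tricellular
junctions. Vertices closer than 2 px are merged into one junction
(degenerate meetings of four or more cells are biologically one junction
complex), and the merged degree counts the distinct incident cells.

**Border channel.** Edges are rasterised as ridges of configurable width
and intensity, Gaussian-blurred (a stand-in for the microscope PSF — no
physical optics are modelled) and overlaid with Gaussian noise.
Intensities live in [0, 1] internally and are quantised only on export,
decoupling the mathematics from the 8/16-bit container.

**Tracer channel.** `round(permeable_fraction * n_junctions)` junctions
are drawn without replacement and receive a Gaussian spot whose centre is
jittered by at most 1 px, which keeps every generated junction spot inside
the 2-px association radius by construction — ground truth is recoverable
in the noiseless limit. Off-junction spots (bicellular or transcellular
leak look-alikes) are placed on cell borders or interiors, always more
than 5 px from any junction centroid, so their ground-truth labels are
unambiguous. Amplitudes follow a lognormal law (mean 0.5, CV 0.3).

Two generator choices deserve explanation because they keep the ground
truth identifiable:

- *Spot size.* The default spot sigma is 1.2 px. At the assay's working
  pixel scale (~0.76 µm/px) this is a near-diffraction-limited
  accumulation punctum (~2 µm FWHM). The constraint behind the default is
  internal consistency: the thresholded footprint of a spot plus the 2-px
  association radius must stay inside the 5-px off-junction exclusion
  zone, otherwise off-junction spots would systematically flag nearby
  junctions and the generator's own labels would be ambiguous.
- *Off-junction population.* By default the generator chooses the
  *number* of off-junction spots so that they can follow the same
  amplitude law as junction spots while the junction-associated signal
  share hits its set-point (`tj_signal_share`). Fixing the count and
  rescaling amplitudes instead (still available by setting
  `n_offjunction_spots`) can push off-spot peaks far above junction-spot
  peaks — and, at extreme settings, past the valid intensity range.

The returned ground truth records what was *realised*: exact permeable
flags, per-spot provenance and pixel-summed integrals, and the realised
junction-associated signal share.

**Condition presets.** `condition_preset()` encodes five monolayer
conditions through their measured set-points: permeable fractions 38.1%
(untreated), 20.3% (S1P), 47.3% (thrombin), 40.7% (multidirectional
shear), 28.9% (uniaxial shear); junction-associated signal shares in the
measured 0.80–0.87 band; and per-junction amplitude scalings of x1.25
(thrombin) and x0.69 (uniaxial). Presets encode shear or agonist biology
*only* through these output statistics — no flow or signalling is
simulated.

**Time series.** Live-imaging dynamics are emulated by a per-frame
opening probability for designated junctions (opened junctions stay open)
and a per-frame spot-radius growth at fixed peak amplitude, so spot count
and every spot's integrated intensity are nondecreasing — the qualitative
signature seen in live imaging of this assay. `free_diffusion_radius()`
returns the 2-D RMS displacement sqrt(4 D t) as a documented sanity
bound: bound-tracer spots grow far more slowly than free diffusion would
spread them (tens of µm vs ~350 µm in 12 min for a 66-kDa-protein-like
D of 42 µm²/s). Neither D nor the formula constant is hard-coded into any
analysis step; both are arguments.

## Junction detection

**Trainable segmenter.** A multi-resolution residual encoder–decoder
assigns each pixel a junction probability: stacks of 3x3 convolutions
with ReLU and residual connections at `n_levels` resolutions (2x average
pooling between levels, 4 levels by default), fused back by upsampling
and addition with residual refinement, ending in a 1x1 convolution and
sigmoid. Because junction pixels are a tiny minority, the training
objective is overlap, not per-pixel cross-entropy: the loss is
`1 - soft_dice` with smoothing 1, the standard smooth form. Defaults
mirror the acquisition-scale recipe (256-px inputs, batch 32, learning
rate 1e-5, 128 channels, Adam, weight decay 0, 320 epochs ~ 12,000
updates); desk-scale runs reduce channel width, input crop and update
count. Augmentation is tiled crops x rotations (90/180/270) x horizontal
flip applied identically to image and mask, plus seeded colour jitter on
the image only.

Training logs train and held-out soft-Dice loss every `eval_interval`
updates (25 by default — fine enough to resolve a held-out minimum near
update 3,000 at acquisition scale and near 300 at desk scale) and
snapshots parameters at each evaluation. `select_checkpoint()` returns
the earliest update minimising the moving-average-smoothed held-out curve
(window 5 evaluations; the minimum of a noisy curve should not be read
off a single point). With deliberately tiny training sets the held-out
curve attains its minimum strictly before the final update while the
train curve still falls — the classic overfitting signature, which the
test suite reproduces. The held-out curve used for selection is a
validation split held out from training; test images stay untouched.

The convolution, pooling and upsampling kernels (and their adjoints) are
implemented in RcppArmadillo via im2col and BLAS gemm; analytic gradients
are verified against numerical differentiation in the test suite.
Training is seeded and bit-reproducible; divergence (non-finite loss)
aborts with a diagnostic.

**Geometric oracle.** Independently of the learned model, a deterministic
detector thresholds the border channel (Otsu by default), thins the
border network to a 1-px skeleton (Zhang–Suen) and reports skeleton
pixels where at least three branches meet. Candidates are merged within
3 px and verified by counting distinct skeleton arcs in a 4–6 px annulus
(at least 3 required) — thinning zigzag artifacts on a single border
otherwise masquerade as branch points. This detector involves no
training and serves as the oracle against which the learned model is
checked, and as the fast path for clean images.

**Post-processing.** `binarize_and_split()` thresholds the probability
map (default 0.5), splits merged blobs by the watershed transform on the
negated distance transform of the foreground (tolerance 0.5), takes
region centroids, merges centroids within 3 px, and emits the
uniform-size binary map (3-px disks) reflecting the uniform-junction-size
assumption. The watershed split and the uniform junction size are fixed
parts of the assay's recipe; the threshold, watershed tolerance, merge
radius and disk radius values are this package's documented defaults.

## Tracer quantification

Foreground is `value > local_mean * (1 + sensitivity)` with a
Gaussian-weighted local mean (sigma = neighbourhood/4, neighbourhood
defaulting to the nearest odd integer to image_size/8), strict
inequality, replicated borders — an exactly constant image yields an
empty foreground. Spots are 8-connected components at least
`min_spot_px = 5` pixels large (single-pixel noise excursions otherwise
flag junctions at random); each carries its pixel list, centroid and
integrated intensity summed from the *original* image (raw, not
background-subtracted — the convention adopted here). Total accumulation
is the sum of original pixel values over the retained foreground.

Association uses the 2-px rule with an inclusive threshold and continuous
centroid-to-pixel-centre distances. A spot near several junctions is
assigned to the nearest one only (ties to the lowest junction index), so
each spot contributes to the junction-associated accumulation exactly
once, while every junction within the threshold of some spot pixel is
flagged permeable. Images with zero detected junctions are rejected
rather than reported as zeros, avoiding silent division artefacts.

## Condition-level statistics

Images are averaged within replicate (donor) first; condition mean and
SEM are taken across replicate means (SEM = SD/sqrt(n)), making the donor
the unit of replication — with n = 3 donors, pooling images instead would
understate uncertainty. Conditions are compared with the classical
pooled-variance unpaired Student t test (two-sided), as named; Welch's
correction is deliberately not applied. Stars follow the strict
conventions `*` p < 0.05, `**` p < 0.01, `***` p < 0.001 (p = 0.05 is
"ns"). Zero pooled variance with equal means gives t = 0, p = 1; with
unequal means the result is flagged degenerate. No multiple-testing
correction is applied, matching the source analysis.

## Validation strategy and problem sizes

All empirical claims about the pipeline are established by the test suite
and the acceptance script at these desk-scale problem sizes, chosen so
the full suite runs on one CPU in minutes:

- *Detector-oracle equivalence*: 10 noiseless 512² renderings of
  ~100-cell monolayers; the geometric detector must reach recall and
  precision >= 0.95 at 3-px matching against generator ground truth.
- *Segmenter training*: ~220 augmented 256² pairs tiled from seven
  512² fields; 600 updates at channel width 8, 96-px crops, batch 8,
  learning rate 1e-3, 3 levels. The selected checkpoint must reach
  held-out soft Dice >= 0.6 and centroid F1 >= 0.90 at 5-px matching on
  two held-out fields; a 4-image training set must show the overfitting
  signature.
- *Parameter recovery*: permeable fraction in {0.2, 0.4, 0.6} crossed
  with signal share in {0.5, 0.85}; 10 images of 512²/100 cells per
  setting with ground-truth junctions supplied; the 10-image mean
  estimate must sit within 0.05 of the realised truth for both metrics
  (the per-setting mean is the comparison level, as the assay averages
  images per well before comparing conditions), and the mean estimated
  fraction must increase strictly across the three fraction settings.
- *Condition ordering*: 5 presets x 3 replicates x 9 images of 256²/60
  cells, junctions from the geometric detector; orderings, >0.8
  junction-associated shares, and significant total-accumulation
  contrasts must reproduce.
- *Statistical oracle*: 100 randomised small-sample cases against the
  closed-form pooled t formula at 1e-10.

## What the synthetic tests do and do not show

The generator reproduces the *structure* of the data — polygonal cell
borders with junction vertices, background plus compact bound-tracer
spots concentrated at a controllable fraction of junctions, growing spots
in time series — with fully known truth. It does not reproduce real
optics (only Gaussian blur), staining heterogeneity, uneven illumination,
annotation noise, 3-D structure, or flow; condition presets encode
treatment effects only through output statistics. Passing tests therefore
demonstrate that the pipeline's logic is correct and self-consistent and
that its estimators recover known truth under realistic geometry and
noise — not that any particular biological number would be reproduced on
new microscope data.

## Numerical conventions

- Coordinates are 0-based (x = column, y = row), origin top-left; a pixel
  belongs to a disk when its centre is within the radius.
- Spot connectivity is 8-connected; the watershed splits on the negated
  distance transform; matching of detected to true junctions is greedy
  nearest-pair within the stated radius with each truth junction matched
  at most once.
- All randomness flows from explicit integer seeds; every generator and
  the training loop are bit-reproducible for a fixed seed.
- Degenerate inputs have defined behaviour: blank images give empty
  junction sets, empty foregrounds give empty spot sets and zero totals,
  zero permeable junctions give an undefined (NA) mean per permeable
  junction, and zero detected junctions reject the image.
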