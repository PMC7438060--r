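---
title: "Fully affine invariant cross-session FOV registration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fully affine invariant cross-session FOV registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovalign)
```

## The problem

Chronic two-photon calcium imaging follows the same neuronal population
over days or weeks.  Identifying the same neurons across sessions requires
registering each session's field of view (FOV) to a template — by
convention the first recorded session.  Manual head re-fixation changes
not only the in-plane translation and rotation but the *viewing angle* of
the imaged plane, so the map between two sessions' mean images is well
modelled as a planar affine transform.  Registration is hardest exactly
when it matters: blurred sessions (dural regrowth), few common neurons
(population turnover), and uneven background brightness (different
acquisition gain, photobleaching).

## The camera model and view simulation

A positive-determinant affine map decomposes as

$$A \;=\; \lambda\, R(\psi)\, \begin{pmatrix} t & 0 \\ 0 & 1 \end{pmatrix} R(\phi),$$

with zoom $\lambda$, camera spin $\psi$, tilt $t \ge 1$ (latitude $\theta =
\arccos(1/t)$) and longitude $\phi$.  `compose_affine()` and
`decompose_affine()` implement the factorization by singular value
decomposition: $\lambda$ is the smaller singular value, $t$ the singular
value ratio.  One caveat worth stating: with $\phi$ canonicalized into
$[0, \pi)$, uniqueness requires $\psi \in [0, 2\pi)$ — the only equivalence
of the factorization is the joint flip $(\psi, \phi) \to (\psi + \pi,
\phi + \pi)$ — so that is the range the package documents and tests.
At $t = 1$ the longitude is degenerate and stored as $0$.

Ordinary keypoint pipelines are invariant to translation, rotation and
scale, i.e. to $\lambda$ and $\psi$, but not to $t$ and $\phi$.  The fully
affine invariant strategy recovers the missing invariance by brute force:
both images are warped to a grid of simulated camera poses, features are
detected on every simulated view, and their coordinates are mapped back to
the original frame before matching.  The grid (`sample_pose_grid()`)
follows the classical sampling: tilts in the geometric series
$t_k = \sqrt{2}^{\,k}$ and longitudes in steps of $\Delta\phi = 72^\circ/t$
up to $180^\circ$.  The longitude step shrinking with $t$ reflects the
growing anisotropy of a tilted view.  With the default
`max_tilt_index = 5` the grid has 43 poses (maximum tilt $4\sqrt2$,
latitude $\approx 79.8^\circ$).  Tilting a view is implemented as rotation
by $\phi$ (bounding box preserved, bilinear), an anti-alias Gaussian blur
of $\sigma = 0.8\sqrt{t^2 - 1}$ along the axis about to be compressed, and
subsampling by $t$ along that axis; `simulate_view()` records the exact
forward and inverse pixel maps, so backprojection is lossless.

Only $(t, \phi)$ are simulated.  Spin and zoom are left to the backends'
native rotation and scale invariance; simulating them would square the
view count for no benefit.

## Keypoint backends

Five interchangeable backends are implemented natively (in C++), one per
classical feature family.  They are in-package implementations *in the
style of* those families, not bit-compatible replicas of any reference
library:

* **SIFT-style** (float, Euclidean): difference-of-Gaussian extrema over a
  4-octave, 3-scales-per-octave pyramid with sub-pixel refinement, edge
  rejection at ratio 10, contrast threshold $0.04/3$ on unit-scaled
  intensities (the family's published default convention), and the
  128-dimensional $4{\times}4{\times}8$ gradient-orientation histogram
  descriptor with 0.2 clipping.
* **SURF-style** (float, Euclidean): scale-normalized Hessian-determinant
  maxima on a Gaussian scale space; 64-dimensional descriptor of
  Gaussian-weighted $(\sum d_x, \sum d_y, \sum|d_x|, \sum|d_y|)$ over a
  rotated $4{\times}4$ cell grid.
* **AKAZE-style** (binary, Hamming): Hessian-determinant detections with a
  486-bit LDB-style descriptor — pairwise comparisons of per-cell gradient
  statistics (gradient energy, mean $d_x$, mean $d_y$) over
  $2{\times}2$, $3{\times}3$ and $4{\times}4$ grids of a rotated patch.
  Two designs were tried and rejected here: a Perona–Malik nonlinear
  diffusion scale space, whose edge-preserving evolution diverges between
  a sharp and a blurred session so that detections stop corresponding
  (its per-image contrast constant makes this worse, and even a fixed
  constant does not repair it); and the classical intensity-mean channel,
  which session-specific illumination corrupts over patch-scale
  distances.  The shipped descriptor channels are illumination-robust by
  construction.
* **BRISK-style** (binary, Hamming): FAST-9/16 corners over a
  $\sqrt2$-factor pyramid with sub-pixel refinement of the score map;
  concentric-ring sampling pattern (60 points, ring-radius-proportional
  smoothing), long-distance pairs vote the orientation, the 512
  shortest-distance pairs form the descriptor.
* **ORB-style** (binary, Hamming): FAST corners over a 1.2-factor pyramid,
  response-ranked with a 500-feature budget, intensity-centroid
  orientation, and 256 steered random point-pair tests on a
  $\sigma = 2$-smoothed patch.  The test pattern is generated once from a
  fixed constant and is part of the method.

On a constant image every backend returns zero keypoints; all backends
are deterministic for a fixed input.

## Matching, robust estimation, and the reliability layer

Pooled descriptors are matched one-way by the nearest-neighbour distance
ratio (NNDR): a putative match is kept iff $d_1/d_2 < 0.75$.  Pooling
across overlapping simulated views creates near-duplicate keypoints whose
presence makes $d_1/d_2 \approx 1$ for *correct* matches; the pool is
therefore deduplicated first (`detect_features_affine()`): keypoints
closer than 1 px whose descriptors agree within a small tolerance
(default 2% of bits, or the equivalent Euclidean radius for float
descriptors) collapse to the first.  The tolerance matters in both
directions — zero makes the rule vacuous under resampling, while a large
one (8% was measured) destroys the multi-view descriptor diversity that
cross-tilt matching depends on.

The transform is estimated by RANSAC over minimal samples of 3 matches
(default 150,000 iterations, 99.9% confidence early exit, 3 px
reprojection threshold — about half a soma radius at the package's
working resolution), followed by a least-squares refit on the consensus
set.  Degenerate (collinear) samples are skipped; if no valid sample
exists the estimation fails with a diagnostic.

RANSAC is randomized, and with low inlier ratios different runs return
different transforms.  `align_fov()` therefore computes features **once**,
then repeats NNDR+RANSAC `n_repeats` times (default 100; repeat $i$ uses
seed $\texttt{seed} + i$) and keeps the transform minimizing the L1 norm
of the ROI-mask disagreement: the moving session's raw neuron mask is
warped (nearest-neighbour) onto the template frame and
$\sum |warped - template|$ is the score — for 0/255 masks, 255 times the
symmetric difference area of the two neuron supports.  Ties keep the
earliest repeat, making the whole result bit-reproducible from its seed.
The per-repeat scores, seeds and the winning index are all returned.

CLAHE preprocessing (`clahe_preprocess()`, 8×8 tiles, clip limit 1 in the
convention where the per-bin ceiling is $\text{clip} \cdot
\text{tile area}/256$, bilinear tile blending) is available for any
method but off by default: the affine pipeline does not require it.

## ROI metrics

* `binarize_and_filter()` drops connected components (8-connectivity)
  below 60 px — the dendritic-spine filter — and paints survivors at 255.
* `mask_correlation()` is the Pearson correlation of the flattened masks;
  it errors on constant masks rather than returning 0, and is invariant
  to the 0/255 vs 0/1 encoding.
* `sharpness()` counts spectrum magnitudes above $M/1000$, where $M$ is
  the maximum of the template's centred Fourier spectrum, divided by the
  pixel count.  Closed forms pin the scale: a constant image scores
  $1/(HW)$, an impulse scores 1, and the value decreases strictly with
  Gaussian blur.
* `count_common_neurons()` operationalizes common-neuron identification
  (a manual curation step in practice) as greedy one-to-one pairing of
  transform-mapped ROI centroids within 5 px.  The radius is a package
  definition, configurable, and reported as such.

## The synthetic benchmark: what it emulates and what it does not

`generate_scene()` draws soma-like anisotropic Gaussian blobs
($\sigma$ 2.1–4.0 px after eccentricity, amplitudes 120–220) with a
minimum spacing that keeps thresholded supports (amplitude/5, ≥ 60 px by
construction) disjoint under the session transforms, plus a fixed
multi-scale neuropil texture on an extended canvas.  The texture deserves
a note: real mean calcium images are never blobs on a flat field — the
neuropil and vasculature give them dense spatial structure, and without
it local descriptors cannot tell identical-looking somata apart (measured
on early blob-only fixtures, the distance ratio of even the *correct*
nearest neighbour hovered near 1, so every backend failed for want of
information, not for want of correctness).  `render_session()` renders a
neuron subset analytically through the session transform (no resampling
error in the ground truth), then applies a multiplicative low-frequency
brightness field, Gaussian blur, Gaussian noise, and 8-bit quantization;
the paired mask is rendered noiselessly.  Shot noise is deliberately
omitted.

`benchmark_suite()` renders 20 pairs at 256×256 with 30 neurons each, in
two strata: *easy* (latitude 5–15°, 80–90% shared neurons, no blur, mild
gradient and noise) and *stress* (latitude 35–42°, 25–30% shared, blur
$\sigma$ 2–2.5 on the moving session, ±35% gradient, noise $\sigma$ 4) —
the degraded regime the method exists for.  The 256×256 frame and the
30-neuron density were chosen to keep the full 20-pair × 5-backend × 2
method sweep around ten minutes on one CPU while preserving soma-scale
geometry; the evaluation uses `max_tilt_index = 3` (tilts to $2\sqrt2$,
ample for latitudes to ~42°, where the relative tilt between two
simulated views stays below the classical transition-tilt limit) and a
300-feature per-view budget.

Passing on these fixtures demonstrates geometric correctness, robustness
of the full pipeline to the modelled degradations, and exact
reproducibility.  It does not demonstrate performance on real data:
non-affine tissue deformation, activity-dependent appearance changes,
z-drift, and realistic noise statistics are all absent.

## Numerical choices and degenerate inputs

* Coordinates are zero-based, x along columns, y along rows, origin at
  the top-left pixel centre; transforms act on (x, y) points.
* Warping is inverse-mapped; masks use nearest-neighbour (values stay in
  {0, 255}), images bilinear; out-of-frame samples are 0.
* The decomposition rejects non-positive determinants with the
  determinant named; `simulate_view()` rejects views smaller than 8 px;
  `align_fov()` fails with counts in the message when fewer than 3
  matches exist, and `mask_correlation()` refuses zero-variance masks.
* RANSAC ties between equal consensus sizes break toward the smaller
  mean residual; L1 ties keep the earliest repeat.
* All randomness (RANSAC sampling, scene generation, session rendering)
  flows from explicit integer seeds; nothing draws from global entropy.

## Known limitations

The affine model cannot express non-rigid tissue deformation.  The
backends are native R/C++ implementations in the style of their families;
absolute keypoint counts are not comparable to any particular reference
library, which is why the package's claims are property-based (accuracy
against synthetic ground truth, affine-simulated vs plain contrast)
rather than count-based.  Online registration is out of scope; so are
within-session motion correction and neuron segmentation, which are
upstream of this package's inputs.
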