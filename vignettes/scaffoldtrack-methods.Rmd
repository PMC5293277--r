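---
title: "Methods: quantifying 3D cell migration and hydrogel microarchitecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying 3D cell migration and hydrogel microarchitecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldtrack)
```

## Scope and model of the data

`scaffoldtrack` implements the image-analysis side of a microfluidic 3D
migration study: GFP-expressing tumor cells embedded in collagen or
collagen–Matrigel hydrogels inside a microfluidic chamber, imaged in 2D
fluorescence time-lapse at low magnification (1.3 µm/px, one frame every
15 min over 12 h), with the hydrogel itself characterized separately by
confocal reflection microscopy (CRM, 0.099 µm/px), scanning electron
microscopy (SEM) of the dehydrated gel, and dextran diffusion time-lapse.
Because cells are fully embedded and the depth of field at 5× is large,
lateral (2D) motion is treated as a faithful proxy of 3D motility; no
attempt is made to recover axial displacement.

The package contains four analysis pipelines (cell tracking, fiber
networks, SEM morphometry, diffusion) and one first-class synthetic-data
generator that emulates each acquisition modality with known ground
truth. Every quantitative claim made by the tests is computed against that
generator or against closed-form geometry; no wet-lab values are baked in.

## Cell segmentation

Frames are first passed through contrast-limited adaptive histogram
equalization (CLAHE, `clahe_enhance()`; tile 64 px, clip limit 0.01 of the
tile histogram). The tile default keeps a full-size 1388×1040 frame at
roughly a 16×16 tile grid; both knobs are exposed.

Cells are then segmented by minimizing the two-phase piecewise-constant
(Chan–Vese) energy

$$E(S) = \lambda_1 \sum_{p \in S} (I_p - c_1)^2 +
  \lambda_2 \sum_{p \notin S} (I_p - c_2)^2 + \mu\,\mathrm{Per}(S),$$

where $S$ is the foreground, $c_1, c_2$ the region mean intensities, and
$\mathrm{Per}(S)$ the boundary length. The discretization uses the
8-neighbourhood cut metric with the standard Euclidean-length weights
($\pi/8$ per axial pair, $\pi/(8\sqrt2)$ per diagonal pair). For fixed
$(c_1, c_2)$ this energy is submodular, so the s–t minimum cut solves it
*exactly* — not approximately — which the test suite verifies by
exhaustive enumeration of all $2^9$ masks over every 3×3 image on a
three-level intensity grid. The cut is computed by a compiled Dinic
max-flow on the pixel lattice (`src/maxflow.cpp`); the lattice structure is
cached per image size so video segmentation only rebuilds capacities.

With free means the solver alternates cut and mean updates, initialized
from an Otsu split, and stops when the means move less than `tol` or the
mask repeats. Degenerate constant frames resolve to all-background by
convention. `segment_video()` estimates the means once on the first frame
and reuses them, since illumination is constant within one acquisition; a
`per_frame` mode re-estimates throughout. Detected components are labeled
with 8-connectivity and filtered at `min_area = 20` px² by default
(a 10–20 µm cell at 1.3 µm/px covers well over 20 px²; the synthetic tests
use 10 px² because their blobs are smaller).

## Tracking

Detections are linked frame to frame by gated, one-to-one, greedy
nearest-neighbour association: all candidate pairs within the gate are
sorted globally by distance and accepted greedily, ties broken by the
lexicographically smallest index pair so the result is deterministic and
independent of detection order. Whether the original constrained
nearest-neighbour tools resolve conflicts greedily or optimally is not
documented; greedy was chosen and the test suite only asserts equality
with the brute-force optimal assignment on instances where greedy is
provably optimal. The default gate of 40 µm per 15-min step is roughly
ten times the fastest observed cell speed, so it essentially only
suppresses teleporting associations. There is no gap closing and no
division handling: a missed detection ends the track, and a track must
span at least `min_track_len = 2` frames.

## Migration statistics

Per track, the accumulated distance is the summed Euclidean path length
in µm, and the average speed divides it by the elapsed time. The mean
accumulated distance (MAD) over an experiment is reported in two
conventions — pooled over all cells, and the unweighted mean of
per-replica means when replica labels are available — because figure-level
summaries commonly use the replica-pondered form while per-cell
distributions pool.

Polarity follows the velocity-SVD recipe: each track's per-step velocity
matrix is decomposed and the right singular vector of the largest
singular value is its primary migration direction (sign fixed so the mean
velocity projects non-negatively). All velocities are rotated so that
this axis maps to 0°, pooled across tracks, and binned by orientation
(16 bins by default); the profile is the mean speed magnitude per bin.
The anisotropy index is the mean speed within ±22.5° of the 0°/180° axis
divided by the mean within ±22.5° of 90°/270°, capped at 100 (and
flagged) when the orthogonal sector is empty, as for a perfectly straight
track. Note that aligning each track to its own SVD axis inflates the 0°
bin for short tracks; the isotropy checks therefore use long tracks
(10³ steps), where that selection bias vanishes.

## Synthetic generator: what it emulates, and what not

* `sample_track()` draws isotropic, persistent, or anisotropic random
  walks with fixed per-frame step length `speed × Δt`. Persistence is the
  expected cosine of the turning angle (wrapped-normal increments);
  anisotropy scales the step component along a unit axis by the ratio and
  renormalizes the expected step length (the normalization constant is
  the elliptic mean of the scaled direction). Walls reflect so tracks
  never leave the field.
* `render_video()` draws each cell as an isotropic Gaussian blob
  (2 px sd, a diffraction-blur proxy) over a constant background with
  additive Gaussian read noise, and warns when two truth positions come
  within 1 px.
* `sample_fiber_chain()` is a discrete 2D worm-like chain: tangent-angle
  increments of variance `step/Lp`, giving
  $E[\cos(\theta(s)-\theta(0))] = e^{-s/2L_p}$. The estimator in the
  fiber module fits the *same* 2D convention, so generator→estimator
  recovery is self-consistent; with data following the 3D convention the
  recovered $L_p$ would differ by a factor 2.
* `render_diffusion_series()` renders the half-infinite 1D solution
  $C(x,t) = \tfrac{C_0}{2}\,\mathrm{erfc}\!\big(x / 2\sqrt{Dt}\big)$
  along image columns.

The canonical tracking conditions (`synthetic_migration_video()`) are:
persistent walk (persistence 0.5) at the serum-stimulated speed of
4.37 µm/hr, 48 frames of 15 min, 1.3 µm/px, blob contrast 25:1 over the
noise, origins sampled with a 45 µm minimum spacing at a constant seeding
density (field side scales as $65\sqrt{n}$ µm). The spacing emulates
dilute single-cell embedding and keeps blob merging — which the renderer
does not model as biology — out of the detection-fidelity statistics.
Not simulated: photobleaching, division, death, shape dynamics (blebs,
lobopodia), Poisson shot noise, and axial drift. Passing tests therefore
demonstrate correctness of the measurement pipeline, not robustness to
every real-microscopy artifact.

## Fiber networks from confocal reflection stacks

The CRM pipeline operates slice-wise in 2D with per-slice aggregation:
at 0.099 µm laterally versus 0.42 µm axially, 3D tracing is
ill-conditioned, and the reported morphology panels are per-image
statistics anyway.

1. **Enhancement** (`enhance_fibers()`): second-order Gaussian-derivative
   steerable filter. The orientation-maximized ridge response is the
   negated smallest Hessian eigenvalue of the scale-space image,
   normalized by $\sigma^2$ — closed-form steerability, so the response
   is rotation-invariant up to discretization (≤ 2% spread across
   0°/45°/90° on smooth fixtures).
2. **Binarization** (`local_otsu_binarize()`): per-tile Otsu thresholds
   bilinearly interpolated between tile centres. A tile is accepted only
   when its class-mean separation exceeds 4× the pooled within-class
   standard deviation; an Otsu split of pure Gaussian noise separates
   means by only ≈1.6 sd, so noise-only neighbourhoods default to
   background instead of hallucinating foreground.
3. **Extraction** (`fire_extract()`): fiber-extraction in skeleton form.
   The mask is thinned to a medial axis by removing simple pixels in
   ascending distance-transform order while preserving centres of maximal
   disks, spurs shorter than 1.6× the local radius are pruned (blunt fiber
   ends otherwise sprout corner branches ≈0.7 width long), and chains are
   split at junction pixels (≥3 neighbours in the reduced skeleton
   graph, where a diagonal adjacency shortcut by an axial one does not
   count). The published branch-reconnection heuristic — rejoining chains
   whose end tangents are anti-collinear within 30° across a junction —
   is exposed as `reconnect = TRUE` because reported fiber lengths depend
   on that policy; the default splits.
4. **Metrics**: `fiber_length()` sums calibrated gaps.
   `fiber_persistence()` computes the tangent correlation $C(s)$ over
   pair separations up to `fit_range` (default `min(length, 10 µm)`) and
   least-squares fits $e^{-s/2L_p}$ by a 1D log-scale minimization,
   flagging effectively straight chains (capped at $10^4$ µm) and chains
   whose correlation never stays positive. Exponential-decay fits on
   40 µm chains are intrinsically noisy: the acceptance band for median
   recovery at 200 chains is a factor of two.
5. **Pore sizing** (`pore_sizes()`): the liquid phase is skeletonized the
   same way, and each medial-axis point receives its *covering radius* —
   the radius of the largest inscribed disk containing the point, found
   by scanning candidate disks in decreasing radius order. This
   deliberately differs from the plain distance transform: on a square
   pore the distance values along the diagonals are uniformly spread and
   have no meaningful mode, while the covering radius assigns the
   inscribed-disk radius to almost the whole medial axis, so the modal
   covering diameter reads off the pore size (exactly `spacing − width`
   on orthogonal grids). The image border acts as a virtual fiber wall
   and border-limited radii are flagged. Mean, median and mode of the
   diameter are all exported, since which of them a published "pore size
   diameter" denotes is generally unstated.

## SEM morphometry

SEM micrographs are binarized by statistical region merging (compiled
union-find over 4-neighbour pixel pairs sorted by intensity difference,
with the usual $b^2(R) = g^2 \ln(2/\delta) / (2Q|R|)$ predicate at
$g = 256$, $\delta = 1/(6N^2)$; `Q = 32` by default, config-exposed), then
reduced to two classes by an Otsu split of the region means. Porosity is
the black-pixel percentage; pores are 8-connected components of the black
phase, with border-touching pores counted (the reference tool's behavior
is not printed; the choice is explicit and exposed).

Mean fiber diameter uses the dual-centreline construction: the fiber area
is divided by the mean of two centreline lengths — Zhang–Suen axial
thinning, and the medial axis traced on the exact Euclidean distance
transform (a Voronoi-equivalent construction). Centreline length is the
sum over skeleton-graph edges (1 per axial step, √2 per diagonal, with
shortcut diagonals excluded); raw pixel counts would underestimate
diagonal runs. The intersection correction removes junction clusters
before the division: junction pixels dilated by the local radius are
subtracted from the area, and the length contributed by the junction
pixels themselves from the denominator. The centrelines of both crossing
fibers that traverse the zone stay in the denominator deliberately — both
fibers really do run through it, and removing their in-zone length would
re-attribute the singly-counted overlap area to half the centreline,
*inflating* the estimate rather than correcting it. On a crossing-ribbons
fixture the correction lowers the estimate toward the true width, which
the tests assert. SEM values characterize the dehydrated, sputter-coated
specimen; no shrinkage correction is attempted, and outputs carry both px
and calibrated units.

## Diffusion

ROI curves are per-frame means over declarative rectangular ROIs (a JSON
description replaces interactive selection for reproducibility),
normalized so the pre-loading baseline maps to 0 and the source-channel
plateau — the mean of the source ROI over the last 5% of frames — to 1.
The published normalization reference is not printed; this convention is
documented rather than asserted as the original. `half_rise_time()`
interpolates the first 0.5 crossing and right-censors curves that never
reach it. `fit_effective_D()` inverts the same erfc model the generator
renders, with start values from the analytic half-rise inversion
$D_0 = x^2 / (4 t_{1/2}\,\mathrm{erfc}^{-1}(0.5)^2)$ and a
Levenberg–Marquardt refinement; fits with RMS residual above 0.05 are
flagged unreliable, and $x = 0$ is rejected as degenerate. The 1D
half-infinite geometry is an idealization of the real chamber.

## Numerical choices and degenerate inputs

* Min-cut ties: constant images under free means return all-background.
* Histogram Otsu uses 256 bins; on two-valued data it recovers the split
  exactly.
* The SVD primary direction errors out on all-zero velocity tracks; an
  equal-amplitude zig-zag is a genuine SVD tie and is not asserted on.
* `anisotropy_ratio = 1` reproduces isotropic statistics exactly and
  `persistence ∈ {0, 1}` reproduce the uniform and straight-line limits,
  which the tests use as degenerate anchors.
* All generators consume one integer seed; fixed seeds reproduce every
  artifact bit-exactly, and the deterministic stages are byte-reproducible
  (asserted on CSV outputs).

## Problem sizes in the shipped checks

The test-suite and the acceptance script regenerate everything they
measure: 19,683 exhaustively enumerated 3×3 segmentations; 20 videos of
5–30 cells × 48 frames; 10³ tracks per speed; 10⁴ pooled steps per
polarity condition; 200 worm-like chains per persistence level; three
grid geometries for pore sizing; 50 noisy diffusion replicates. These
sizes were chosen so every Monte-Carlo band in the tests is comfortably
wider than its standard error at desk scale.

## Known limitations

* 2D only: no volumetric segmentation, 3D fiber tracing, or 3D pore
  volumes; z enters only as independent slices.
* The greedy linker has no probabilistic data association; dense fields
  of fast cells will fragment before they mislink, by construction of the
  gate.
* Persistence estimates on short chains are biased upward when
  `fit_range` exceeds the informative correlation range; the default
  10 µm range is a compromise for ≈10 µm-class fibers.
* SRM granularity `Q` and the CLAHE clip limit are exposed but their
  field-typical values are instrument-dependent; defaults are documented
  choices, not measurements.
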