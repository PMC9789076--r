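---
title: "Detecting lamina cribrosa defects in 3D OCT volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lamina cribrosa defects in 3D OCT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The lamina cribrosa (LC) is the sieve-like collagenous plate in the optic
nerve head through which retinal ganglion cell axons leave the eye. In
highly myopic eyes the LC can tear away from the surrounding peripapillary
sclera (PPS), leaving a lamina cribrosa defect (LCD): a full-thickness loss
of LC tissue, visible on swept-source OCT as a loss of high reflectivity
spanning the anterior-to-posterior extent of the plate. Reading LCDs from
individual B-scans is hard; a 3D reconstruction of the segmented LC and PPS
makes the gap and its position on the disc rim directly visible.

`lamcrib` implements that workflow as a reusable, tested pipeline:

1. slice a 3D volume into its 2D frame series along the axial, sagittal and
   coronal planes;
2. label a sparse subset of frames (every 3rd-5th frame), as a human reader
   would;
3. train one 2D segmenter per plane on those frames and predict dense
   labels for every frame;
4. fuse the three plane-wise label volumes voxel by voxel;
5. detect, localize and orient full-thickness LC-PPS gaps;
6. summarize a cohort and export meshes/overlay images.

Real clinical volumes of this kind are not publicly deposited, so the
package ships a synthetic optic-nerve-head phantom generator with exact
ground truth. All quantitative guarantees quoted below are statements about
the pipeline run on that phantom cohort; they demonstrate internal
correctness and recoverability, not clinical accuracy on patient scans.

## Conventions

A volume is an `(a, s, c)` array: `a` and `s` are the lateral axes, `c` is
depth (the OCT axial direction). Axial frames fix `a`, sagittal frames fix
`s`, coronal frames fix `c`; at the default acquisition grid - a 3 x 3 mm
field scanned as 256 x 222 x 190 voxels - the three planes therefore hold
256, 222 and 190 frames. The en-face plane is `(a, s)`. Frame indices are
1-based, and the TIFF page order equals the axial frame order with no
implicit flips, so extraction/stacking and file round trips are exact.

Rim angles are measured in the en-face plane with 0 degrees pointing
*temporally*, which is `+a` for right (OD) and `-a` for left (OS) eyes;
90 degrees is superior. Quadrants are fixed 90-degree sectors centered on
these axes. This makes "temporal" laterality-aware, as in clinical reading:
mirroring a volume left-right and flipping the recorded laterality leaves
every quadrant call unchanged (a tested invariant).

## The phantom

`phantom_spec()` describes one simulated eye. The LC is a bright plate of
radius ~0.65 mm bent posteriorly at the disc center (the optic cup) and
inserted into a darker, slightly thicker PPS shell that curves gently
anteriorly toward its outer edge; the whole sheet can be tilted temporally.
Confounders seen in real scans are modeled explicitly:

* **laminar pores** - small hyporeflective spheres inside the plate. They
  darken the intensity image only; their voxels remain LC-labeled, because
  a pore is not a defect. Detection must therefore ignore them.
* **vessel shadows** - hyporeflective columns running from the anterior
  volume face through the whole depth, multiplying the signal by ~0.35.
* **temporal edge attenuation** - a smooth multiplicative signal loss over
  the temporal LC edge (a logistic ramp), mimicking the shadowing by
  overlying tissue that makes that edge unclear in real scans.
* **speckle** - voxelwise multiplicative gamma noise with unit mean and
  standard deviation `noise_level` (default 0.25). Multiplicative unit-mean
  noise leaves class means fixed while inflating variances, so the
  LC/background contrast statistic decreases strictly with `noise_level`
  (a tested invariant). This is a deliberately simple stand-in; it does not
  reproduce the correlated speckle statistics of real OCT.

A defect, when requested, is a wedge carved through the full plate
thickness at the disc rim: all tissue voxels within `lcd_radial_vox / 2` of
the disc radius and within `lcd_arc_deg / 2` of the requested rim angle
become background. Because the wedge follows the rim, its en-face footprint is
elongated along the local tangent - at the temporal rim that tangent is
vertical, reproducing the vertically running temporal defects described
clinically. Defaults (40 degrees of arc, radial width ~90 um) are
plausible but uncalibrated: no published measurements of defect
dimensions exist to calibrate against, only presence and location. Pores (radius ~25 um) are far smaller than the
defect's radial width, so the two are separable by size. Every linear
default - disc and shell radii, plate thicknesses, pore and vessel radii,
defect width - is proportional to the grid, so a phantom simulated at
reduced resolution is the same physical object sampled more coarsely; at
the full protocol grid the defect's radial width is 8 voxels and a pore's
radius 2.

At the default grid the anatomy spans 210 consecutive axial frames, chosen
so that stride-3 to stride-5 sparse annotation yields between 42 and 70
labeled frames per plane - the range a manual reader produces.

`generate_cohort()` jitters nuisance parameters per eye (tilt 0-6 degrees,
pore count 20-40, +-15% noise, random laterality) and draws defect angles
uniformly within +-30 degrees of the temporal axis, matching the strongly
temporal clustering of clinical defects. Exactly `round(n * lcd_fraction)`
eyes carry a defect; per-eye seeds derive deterministically from the cohort
seed, so a cohort is a pure function of `(n, lcd_fraction, base_spec, seed)`.

## Annotation

`simulate_sparse_annotation()` finds the contiguous frame range containing
anatomy, starts at its first frame and steps by strides drawn uniformly
from `{3, 4, 5}` (the strides are randomized per gap rather than fixed per
eye, since a human reader is not metronomic). Each selected frame carries
the exact ground-truth labels - a perfect reader. Reader error is available
as an explicit `label_noise` hook but is off by default: manual LC
labeling of this kind is done by a single reader and no reader error
model exists to calibrate against. How a reader decides which frames
contain LC is likewise undocumented; the "non-background span" rule is
this package's operationalization.

## Segmentation

Two interchangeable per-plane segmenters sit behind the same interface
(`train_plane_segmenter()` / `predict_plane()`); everything downstream is
agnostic to the choice.

**Baseline (deterministic).** Frames are flat-field corrected - divided by
a broad (31 x 31) local mean - which cancels smooth multiplicative signal
loss such as the temporal attenuation ramp; without this step the
attenuated temporal PPS falls below any global threshold and produces a
false temporal "gap", which is precisely the clinical confounder. The
corrected frame is despeckled with a small Gaussian (sigma 1.5 px), because
a per-pixel threshold under sd-0.25 multiplicative noise misclassifies
~15% of PPS pixels and the resulting clustered holes would mimic defects;
the blur costs a ~1-voxel halo at tissue borders (an edge-preserving
median filter avoids the halo but leaves the clustered holes in place and
was rejected for that reason). A 3 x 3 morphological opening then removes
residual speckle islands. The tissue threshold is the histogram split that
misclassifies the fewest annotated pixels (the optimal decision stump on
corrected intensities); unlike a midpoint of class medians it lands at the
blurred edge crossing, so neither the dimmer PPS nor the background is
systematically eroded. Tissue
is split into LC versus PPS by en-face distance from the disc center, both
estimated from the annotated LC pixels (the radial split is the 99.9th
percentile of annotated LC radii plus half a voxel). The baseline has no
random state: re-running it bit-reproduces every prediction.

**CNN (learned).** A small 2D encoder-decoder written against the package's
own im2col convolution kernels (RcppArmadillo): two 3 x 3 conv+ReLU layers
at full resolution, a 2 x 2 max-pool bottleneck with one 3 x 3 conv,
nearest-neighbor upsampling, a skip concatenation, one 3 x 3 fusion conv
and a 1 x 1 three-class head - about 4,000 parameters at the default 8
channels. Training minimizes pixelwise softmax cross-entropy weighted by
inverse class frequency (capped at 25x) with Adam (lr 2e-3), one frame per
step, frames shuffled per epoch under the config seed; the backward pass is
verified against numerical differentiation in the test suite. The
coronal plane deserves a note: the plate spans only a few dozen depth
levels, so sparse annotation yields an order of magnitude fewer frames
there than in the lateral planes, and the learning-sanity checks train all
planes for 20 epochs so the coronal model sees a comparable number of
gradient steps. By default
frames are subsampled 2x for training and prediction and the predicted
labels upsampled back, which keeps a three-plane training run on a
full-protocol phantom in the minutes range on one CPU. No reference
architecture, loss, augmentation or stopping rule exists for this
per-eye-per-plane setting, so all of these are package choices and all are
visible in `segmenter_config()`. A pooled cross-eye model is deliberately
out of scope: the design is one model per plane per eye.

## Fusion

The combination rule for the three plane-wise predictions is not stated in
established practice; this package uses a per-voxel majority vote, isolated
behind `fuse_planes()` so alternatives can be swapped. A three-way tie
(all planes disagree) is broken by the fixed priority LC > PPS >
background - favoring anatomy avoids opening spurious gaps where planes
disagree. The confidence volume records votes-for-winner / 3. The
implementation is tested against a brute-force per-voxel oracle over all 27
vote patterns and on random volumes.

## Defect detection

`detect_lcd()` operates purely on a fused label volume.

Disc geometry is estimated from the labels themselves: center = LC
centroid, radius = 95th percentile of en-face LC radii, disc axis =
smallest-variance principal direction of the LC voxel cloud.

The search region is the rim annulus (0.72-1.38 times the disc radius)
clipped in depth to a band around the smoothed tissue-surface map (the
per-column mean depth of labeled tissue, with gap columns filled by
iterative neighbor averaging). The depth clip matters: a full-thickness gap
in a thin plate is open to the ambient background above and below, so an
unclipped annulus would merge every candidate into one component spanning
the whole volume. The band half-width defaults to 35% of the median
per-column tissue thickness (3 voxels at the protocol grid), which keeps
the band strictly inside the plate's depth range wherever tissue exists,
at any resolution. Whether the search region should be restricted
further - clinical defects are bordered by the PPS - is left permissive
here.

Candidates are 26-connected background components in that band. A
candidate is reported as a defect only if all of the following hold:

* **(a) full thickness** - at least 80% of its en-face columns contain no
  LC voxel at any depth (the gap interrupts the plate, not merely dents
  it), and LC tissue exists within 6 voxels of its footprint (the gap has
  a laminar border). The 80% rather than 100% tolerates stray mislabeled
  voxels in fused predictions.
* **(b) size** - at least `min_size` voxels (default 150 at the full
  grid). Clinical readings use no numeric size criterion; the default is
  set between the phantom's pore size (~30 voxels) and defect size
  (~1,900 voxels) at protocol resolution and is exposed as a parameter
  (reduced-resolution runs pass proportionally smaller values).
* **(c) not vessel-shadow-like** - the component does not extend to the
  anterior volume face.
* **(d) not pore-like** - en-face equivalent diameter at least
  `min_enface_diam` (default 8 voxels, above the vessel-shadow diameter of
  ~6 and the pore diameter of ~4).
* **(e) radially contained** - the 2nd-98th percentile radial spread of
  its footprint is at most 0.55 times the disc radius. A defect is a gap
  *between* the LC and the PPS, hugging the rim; a vessel-shadow tube that
  crosses the annulus spans its entire radial extent and is rejected by
  this rule even when its footprint is large. This rule is this package's
  addition, motivated by defects being bordered by PPS; it was designed by
  inspecting shadow-induced label gaps in fused phantom predictions.

Each reported region carries its centroid rim angle, arc extent, quadrant
(nearest 90-degree sector), en-face principal-axis orientation (vertical /
horizontal / oblique with +-30-degree bands; a single-voxel region is
flagged degenerate), and size. Regions are sorted by size; raising
`min_size` can only remove regions (tested monotonicity).

## Evaluation and reporting

`dice()` is the standard overlap coefficient, defined as 1 when a class is
absent from both volumes (this convention only matters in degenerate
tests). `detection_metrics()` aligns reports to phantom specs by volume id
and produces the 2 x 2 counts plus signed angle errors wrapped to
+-180 degrees for true positives. `prevalence_summary()` formats counts as
"k (p%)" with percentages rounded half away from zero - the rounding under
which 12/42 prints as 29% and 11/12 as 92%.

## Meshes and overlays

`labels_to_mesh()` extracts an iso-surface of a class mask at level 0.5 by
marching tetrahedra: each cell is split into 24 tetrahedra through its body
and face centers, which subdivides shared faces symmetrically and therefore
yields a watertight surface on solid masks without marching-cubes case
tables. Raw iso-surfaces of binary masks carry a staircase that inflates
area by ~10-15%, so the mesh is relaxed by 3 Laplacian iterations (step
0.6); each vertex moves toward the mean of its neighbors, keeping all
vertices inside the volume's bounding box. After relaxation a sphere mask's
area is within ~3% of the closed form and a cube mask's within ~9% -
corner rounding biases a cube low, curvature discretization biases a
sphere high. STL carries no color, so LC and PPS are exported as separate
per-class meshes; `enface_overlay()` writes the depth-projected LC (red) /
PPS (blue) map with defect footprints and centroid markers in yellow,
following the red/blue display convention of the clinical figures.

## Problem sizes and determinism

Full-protocol phantoms (256 x 222 x 190) are used where a property depends
on the protocol itself: the frame-count check, the 40-70 annotation-count
range and the learned-segmenter sanity check. Cohort-level recovery
experiments (the 20-eye suite check and the 42-eye acceptance cohort) run
at half lateral scale, 128 x 112 x 96, with `min_size = 60`; the
geometry, confounders and noise level are unchanged, and a 20-eye cohort
completes in about three minutes on one CPU. Every stochastic stage -
phantom rendering, cohort jitter, annotation strides, CNN initialization
and shuffling - consumes an explicit seed, and `run_pipeline()` records all
of them in its run log, so any run is exactly reproducible from its config.

## Known limitations

* The phantom is a geometric stand-in: no retina or choroid, no prelaminar
  tissue (the space anterior to the plate is empty background), uncorrelated
  speckle, and a single wedge defect per eye. In particular, because
  nothing sits above the plate, the anterior-face rule (c) rarely fires on
  phantom data; the radial-containment rule (e) does the work of rejecting
  shadow tubes.
* Segmentation accuracy against human readers is not evaluated (no such
  data exists in the package); the reported Dice values measure recovery of
  synthetic ground truth.
* The geometric LC/PPS split of the baseline assumes a roughly circular
  disc; strongly oval or peripapillary-atrophy-distorted discs would need
  the learned segmenter.
* Angle recovery is quoted for the defect centroid only; arc-extent and
  size estimates inherit segmentation blur at the defect edges.
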