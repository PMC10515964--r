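---
title: "Models and methods behind devatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind devatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`devatlas` implements the computational chain used to assemble
developmental brain common coordinate frameworks — tile stitching,
groupwise template construction, multimodal alignment, slice-to-volume
reconstruction, ontology management and regional quantification — at
desk scale, with every pipeline exercised end-to-end on seeded synthetic
phantoms. This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic tests do and do not establish
about behavior on real data.

## Coordinate conventions

Volumes are node-centered grids: the world coordinate (mm) of 0-based
voxel index $i$ is $o + i s$ with origin $o$ and spacing $s$. The
canonical internal orientation is RAS with the left–right axis first, so
the midsagittal plane is the grid's x-center plane and reflection is the
exact index map $(i,j,k) \mapsto (N{-}1{-}i, j, k)$. The internal unit is
mm; µm-tagged inputs are converted on load and written back in their
source unit. Because a bare array cannot reveal the handedness of its
acquisition, loaders take an `orientation` override rather than guessing.

Transforms use the pull-back convention: a transform $T$ with affine $A$
and displacement field $u$ maps reference points into the moving space,
$T(p) = A p + u(p)$, and applying $T$ to a volume samples it at $T(p)$
for every reference voxel. Composition therefore reads right-to-left
(`compose_transforms(list(t1, t2))` applies `t1` first and has point map
$T_1 \circ T_2$; for pure affines the composite matrix is
$A_1 A_2$, a convention pinned down by a sequential-application oracle in
the test suite). Inverses of dense fields come from the fixed-point
iteration $u^{-1}(p) = -u(p + u^{-1}(p))$, iterated until the update
stalls; it converges geometrically while $\lVert \nabla u \rVert < 1$,
which the elastic regularization of every field the engine produces
guarantees in practice. Displacement fields are sampled with
edge-clamped linear interpolation so they remain well defined at the
grid border.

## The registration engine

The built-in engine is a multiresolution affine stage followed by
Gaussian-regularized demons. The affine stage runs Nelder–Mead over
parameter blocks — translation, then rotation, then the full
12-parameter affine (translation, Euler rotations, log-scales, shears
about the volume center) — with the full affine fitted only at the
finest level, where noise cannot masquerade as rotation or shear; a
cross-correlation translation initializer seeds it. The demons stage
iterates, per pyramid level: warp the moving image through
$A p + u(p)$; compute Thirion forces
$v = \delta\, \nabla f / (\lVert \nabla f \rVert^2 + \kappa\,\delta^2)$
with $\delta$ the intensity difference, $\kappa = 1/\bar{s}^2$, and a
relative gradient floor ($\lVert\nabla f\rVert^2 > 0.0009 \max$) that
keeps background noise from exciting the field; clamp the step to one
voxel; smooth the update (fluid sigma) and the accumulated field
(elastic sigma). Multi-channel inputs contribute weighted force sums.

Key tunables (per `registration_spec()`): shrink factors `levels`
(default 4, 2, 1), `iterations` per level (default 50, 30, 15 — recovery
accuracy on the harness is insensitive between 15 and 30 fine-level
iterations, so the default favors the smaller budget), `sigma_fluid` (1
voxel) and `sigma_elastic` (1.5 voxels), and the mutual-information bin
count (32, with a light Parzen-style smoothing of the joint histogram).
The original pipeline this reimplements used an external registration
toolkit; here that toolkit's role is a pluggable backend behind the same
contract, and no convergence claims are inherited from it — iteration
counts are configuration, not assertions.

Cross-modality registration names mutual information as its metric. The
affine stage optimizes MI directly. For the demons stage the engine uses
the standard conditional-mean reduction: the moving image's intensities
are remapped through $E[f \mid \mathrm{bin}(m)]$ estimated from the
joint histogram (refreshed every 10 iterations), after which
least-squares forces apply. This handles monotone and non-monotone
intensity relationships (the test suite demonstrates recovery under full
intensity inversion) but, like all histogram reductions, it can stall
when one modality's tissue classes collapse into a single bin of the
other's.

Two engine-level guarantees are enforced rather than hoped for: the
returned transform never scores worse than the identity under the
requested metric (the engine falls back to identity otherwise), and
nonlinear results always carry a numerically verified inverse.

## Tile stitching

The stitcher follows the two-pass, edge-MIP design. Pass 1 reads each
tile once, chunk by chunk, retaining only the four outer edge strips
(10% of the tile extent by default) and their per-block maximum
intensity projections (32-slice blocks). All alignment then works on
this reduced representation: z offsets per tile column from normalized
cross-correlation of facing strip profiles along z; per-block (dx, dy)
from NCC of the strips that straddle each adjacency's overlap zone (for
horizontally adjacent tiles the top and bottom strips cover the full
overlap width, which is what makes x shifts measurable at all);
per-tile offsets from least squares over the tile adjacency graph with
the first tile anchored. Pass 2 reads each chunk once more and fuses
with linear feathering across overlap zones; single-coverage voxels
reproduce their unique source exactly. The chunked readers count every
access, so the two-read property is asserted, not assumed.

Several reconciliation choices are the package's own, since the
published description names no estimator: pairwise estimates are
trimmed by their residual against the graph solution (adjacent tiles can
be displaced beyond what their shared strip support can measure, and
such estimates are inconsistent with the rest of the graph); a second
correlation pass refines each adjacency in a narrow window around the
first solution; strips that are mostly background are dropped by a
relative-variance gate, because a MIP of noise decorrelates between
tiles once per-slice drift varies within a block. Per-slice offsets are
produced by fitting a smoothing spline (GCV; linear fallback below four
blocks) through the block offsets versus block-center z, and — when the
edge strips are available — snapped to integers by per-slice NCC within
±2 voxels of a continuity prior, solved per *world* slice (tiles enter
one solve at the slice indices that correspond to the same physical
plane) from the stack center outward, with estimates weighted by match
quality. The snap exists because tile placement is on the voxel grid:
a real-valued curve that rounds the wrong way near a half-voxel crossing
would break lossless fusion even though its error is far below a voxel.

Geometry constrains what is measurable: with 10% strips and 15% nominal
overlap, the strips of an adjacency share support only while the
relative displacement stays well inside the overlap width. The defaults
handle per-tile jitter up to about 5 voxels with drift up to 3; beyond
that, `edge_fraction` must grow with the expected misplacement.

## Symmetric template construction

`build_template()` starts from the voxel mean of the cohort and iterates
the three-step loop: (1) register every subject to the current template,
(2) voxel-average the warped subjects, (3) apply the inverse of the
average transform to the average image. Step (3) is interpreted in the
displacement domain — fields averaged voxel-wise, affines averaged in
the matrix-log domain — and its inverse warps the intensity average,
which is the update that removes the cohort-mean shape bias; the
published description says only that the average transform is applied,
so this interpretation is documented here as the package's reading.
After each update the per-subject transforms are composed with it, so
the returned transforms map into the returned template's space; a
consequence worth stating is that the voxel-wise mean of the final
displacement fields is zero by construction, and the returned template
is recomputed as the mean of the subjects warped by exactly those
transforms, which makes identity sibling-contrast propagation bitwise
consistent.

Intensity rescaling to the unit range happens only inside the
registration metric. Template intensities are averaged on the native
scale — otherwise a sibling contrast that is a scalar multiple of the
primary would not propagate to the same multiple of the template, and
linearity of contrast propagation is one of the properties the test
suite asserts exactly.

Convergence is a fixed iteration count (default 4) with an optional
early stop when the mean update drops below 0.1 voxel; the source
procedure iterated "until stable" without a stated criterion, so the
stopping rule is configuration. Symmetrization doubles the cohort with
midline reflections; because every operation in the loop commutes with
reflection up to interpolation error, the template's relative mirror
asymmetry stays well below 1% without any explicit symmetrization of
the result. Staged multiresolution construction (coarse spacing first,
each stage initializing the next) mirrors the 50/20/10 µm staging used
for large light-sheet templates; at desk scale its value is mainly
initialization quality, and the tests treat it as such.

## Landmark/mask-assisted multimodal alignment

The failure mode this addresses: two modalities agree on the outer brain
surface but an internal structure is misaligned, and the image metric
carries no usable signal there. Manually segmented region masks around
the misaligned structures are subtracted from the whole-brain masks,
producing "modified masks" whose carved boundaries localize the error.
Stage 1 registers the modified masks linearly — by default as smoothed
(distance-like) images under mean squared error, which gives the mask
alignment a capture range instead of a razor-thin edge gradient; a flag
selects raw-mask MI instead. Stage 2 runs nonlinear registration on two
equally weighted channels, the image (under mutual information, matching
the initial cross-modality registration this stage refines) and the
smoothed modified mask. "Equally weighted" is implemented as 0.5/0.5
channel weights; the source states equality without numbers.

The synthetic benefit fixture makes the displaced internal ellipsoid
visible in the fixed modality only — the cross-modality analogue of a
structure with no exploitable contrast — and gives the moving phantom a
mildly mismatched outer surface so whole-brain overlap is informative.
On this fixture mask assistance reduces the structure's centroid error
by an order of magnitude while whole-mask Dice does not decrease. The
fixture does not model the harder real-world case where the misaligned
region's boundary is itself ambiguous in both modalities.

Stereotaxic frames are built from bregma and lambda as a rigid transform
only: bregma at the origin, bregma-to-lambda along the negative
anterior-posterior axis, dorsoventral orthogonal in the sagittal plane.
Since the package operates on brain volumes rather than skulls, the
dorsoventral zero sits at the user-supplied bregma point.

## 2-D ISH to 3-D reconstruction

The seven-step chain: (1) intensity-invert and resize slices (default
512×512 as in the source pipeline; tests and the acceptance runs use the
phantom's native in-plane size, a problem-size choice, since nothing in
the chain depends on the absolute resolution); the intensity rescale
uses one range for the whole series, because per-slice rescaling blows
empty slices up to full contrast. (2) Stack present slices at their
nominal z and fill missing slices by fitting, per pixel column, a
natural cubic interpolating spline along z — the separable reading of
scattered-data spline infill for this sampling pattern, which is dense
in-plane and scattered only along z (a full N-D fit would add nothing
here but cost; cubic order reproduces any intensity profile linear in z
exactly, which the tests assert at 1%). Present slices are stored
verbatim: reconstruction never alters measured data before refinement.
(3) Linearly align the template to the reconstruction. (4) Refine each
measured slice in-plane against the aligned template slice — an integer
translation search maximizing the chosen metric (MI by default, as in
the source's slice-wise step), with border fill at the slice's own
background level. Interpolated slices are regenerated afterwards.
(5, 6) Register the template to the refined reconstruction nonlinearly
and carry the reconstruction onto the template grid through the inverse
transform. (7) Split the series by gene label, re-fill each single-gene
series, and warp each through the same transform; genes with fewer than
two slices are skipped with a warning.

Coronal versus sagittal series are a plane-axis parameter upstream of
this chain; a single reconstruction never mixes planes. The end-to-end
acceptance fixture uses a template that shares the reconstruction's
contrast and the mean-squared-error metric — the chain's geometry,
infill and slice refinement are what that test exercises; the
cross-modality (MI) path is exercised separately in the unit tests.

## Ontology and quantification

The ontology is a validated region table (16-bit id, optional original
32-bit id, name, acronym, parent, color, level) with construction-time
detection of duplicate ids, orphan parents and cycles; levels are
recomputed by breadth-first walk. The 32-bit-to-16-bit remap keeps ids
at or below 65535 unchanged and folds larger ids to
$20000 + (\mathrm{id} \bmod 10000)$ — the arithmetic form of taking the
last four decimal digits and prefixing a 2, preserving leading zeros.
Collisions raise an error listing the offenders rather than renumbering
silently: the source id set may never have collided, and silent
renumbering would corrupt cross-references. Newly added structures
allocate from 18000–19999 and the allocator refuses to exceed that
range.

Annotation volumes carry one label per voxel; the validator reports
in-mask zeros (exhaustiveness violations), labels missing from the
ontology, and labels outside the mask. Aggregation replaces labels by
their ancestor at a target depth and conserves labeled voxel counts
exactly; cross-atlas contingency tables are integer tallies whose
marginals equal region volumes identically, exported in long format for
Sankey-style rendering (log scaling belongs to the renderer).

Quantification: classified-voxel volumes are downsampled by exact block
sums, so each coarse voxel holds the count of positive fine voxels and
totals are conserved; per-region relative occupancy divides the summed
counts by region voxels times the per-bin capacity, so a ratio of 1
means fully occupied at classification resolution (the source ratio
mixes resolutions; this fixes the convention). Warping count volumes
uses linear interpolation scaled by the Jacobian determinant of the map
(mass conservation within ~2% on the tests), with a flag for the naive
behavior. Cell-to-region assignment floors world-to-index coordinates
(deterministic boundary rule); cells outside the annotation count in an
`unassigned` row so subclass proportions sum to exactly 1. The MTR map
is the closed form $1 - \mathrm{MT}/\mathrm{M0}$ with nonpositive M0
masked to NA.

## Synthetic data: what it emulates, and what it does not

The generators produce soft-edged ellipsoid phantoms with a smooth
mirror-symmetric intensity texture (amplitude 0.2, smoothing 2 voxels by
default — flat interiors would make displacement fields unrecoverable
for *any* intensity-driven method, which is an aperture problem, not an
engine property), iid Gaussian noise (default sd 0.02), cohorts deformed
by mean-centered smooth random fields (default maximum 3 voxels,
smoothing scale 8 voxels — chosen as a plausible anatomical-variability
scale relative to a 64-voxel brain), jittered tile grids (integer
per-tile jitter, per-column z offsets, optional linear per-slice drift,
all returned as ground truth; the anchor tile is left unperturbed so
recovered offsets are directly comparable), sparse jittered ISH series,
and nested Voronoi ontologies whose children tile their parents exactly.
Every generator is a pure function of its seed.

These fixtures establish correctness of the machinery: offsets are
recovered because the truth is recoverable, conservation laws hold
exactly, symmetry and centering emerge from the construction. They do
not establish robustness to the pathologies of real acquisitions —
illumination gradients and flat-field error across tiles, anisotropic
point-spread, staining variability between sections, tissue tears, or
true inter-subject anatomical topology changes. Tile content here is
cut from one volume, so overlap regions agree up to the placement
offsets; real tiles differ photometrically, and the stitcher's NCC-based
estimators tolerate but are not tested against such differences.

## Problem sizes and reproducibility

The reference problem sizes used by the acceptance checks are a 3×3 grid
of 128³ tiles (15% overlap, jitter ≤ 5 voxels, linear drift 0→3 voxels),
a 6-member 64³ cohort symmetrized to 12 with 4 template iterations, 48³
multimodal pairs, and a 64³ ISH phantom sampled every 2nd slice with 20%
of slices dropped and ±4 px jitter. All randomness flows through
explicit seeds; re-running any generator or pipeline with the same seed
is bit-identical, and the template convergence record is asserted to be
so. `scripts/acceptance.R --seed N` regenerates everything from scratch
and writes the measured quantities as JSON.

## Known limitations

* The demons engine is additive with elastic smoothing, not a
  diffeomorphic flow: large-deformation registration (beyond ~5 voxels
  of local displacement) degrades gracefully but is out of scope, as is
  any claim of symmetric-normalization fidelity.
* Mutual information uses a global joint histogram; spatially varying
  intensity relationships (bias fields) are not modeled.
* Strip-based stitching cannot measure relative displacements
  approaching the overlap width; the geometry section above gives the
  budget.
* The misaligned-region masks of landmark-assisted registration are
  inputs: identifying them is the expert's job, as in the source
  workflow, and no automatic discovery is attempted.
* Orientation handling trusts the stated axis codes; no header-based
  reorientation beyond the override flag is performed.
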