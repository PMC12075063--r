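---
title: "Methods: 3D motoneuron morphometry with mnmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D motoneuron morphometry with mnmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`mnmorph` quantifies spinal motoneuron (MN) morphology from 3D fluorescence
stacks of cleared tissue, in two chains:

1. **Soma chain** — instance segmentation of densely packed somata, volume
   measurement with clearing-expansion correction, a standard soma-size
   histogram, a two-component Gaussian curve fit whose intersection
   threshold splits putative γ (small) from putative α (large)
   motoneurons, and sphere/region tables for 3D rendering.
2. **Dendrite chain** — Hessian rod/ball structure enhancement of sparsely
   labelled neurons, thresholding and per-neuron labelling, topological
   thinning to a rooted SWC skeleton, and skeleton metrics: Sholl
   profiles, centrifugal branch order, per-order branch length, and
   tortuosity.

All computations are carried out in physical micrometres: distance
transforms, gradients and Hessians scale each axis by its voxel spacing, so
anisotropic stacks need no resampling before segmentation (isotropic
resampling happens only immediately before thinning, which assumes
isotropic connectivity).

Conventions: arrays are indexed (z, y, x) with z the slice axis; the voxel
at 0-based index *i* sits at physical coordinate *i*·spacing; multi-page
TIFF holds z outermost. SWC files store physical µm, type 1 = soma root,
3 = dendrite, 2 = axon candidate, root parent = −1.

# Soma segmentation

The chain is median filter → binary mask → gradient magnitude → seed
detection → marker-based watershed inside the mask → volume filtering.

**Median filter** (box, default half-size 2 voxels per axis) erases thin
neurites, which would otherwise bridge neighbouring somata in the mask,
while preserving large compact bodies. A box median erodes *convex*
boundaries slightly (the shift grows with window size and boundary
curvature, ~ρ²/2R); we measured an 8 % volume deficit on a 10 µm sphere.
The default pipeline therefore treats the median-image mask as a
localisation prior only and re-thresholds the **original** stack at the
same levels within a 2-voxel dilation of that prior (`refine_mask`),
restoring the unbiased half-peak boundary while keeping the eroded
neurites out.

**Mask provider.** The default mask is a hysteresis threshold
(26-connected) of the median-filtered stack. Thresholds are anchored on
the robust intensity range rather than on rank percentiles: with
background b = median intensity and peak p = 99.9th percentile, low =
b + 0.5 (p − b) and high = b + 0.75 (p − b). The half-range low threshold
coincides with the half-peak crossing of a blurred step edge, which is the
unbiased boundary estimate, and — unlike rank percentiles — does not move
when the fraction of the volume occupied by cells changes (a 50-soma field
fills only ~1–3 % of a stack; the 90th intensity percentile of such a
stack lies inside the noise). Any externally produced mask (for example
from a trained segmentation network) can be injected in its place; the
rest of the chain is unchanged.

**Seeds.** The Euclidean distance transform of the mask (in µm,
anisotropy-aware) is reduced to its h-maxima by grayscale reconstruction:
domes of prominence ≥ `h_um` (default 2 µm) survive; peaks closer together
than `min_seed_distance_um` (default 8 µm) are merged greedily, keeping the
deeper peak. The defaults sit between the scale of noise bumps on the
distance map and the radius of the smallest plausible motoneuron soma.

**Watershed** floods the Gaussian-gradient magnitude (σ default 1 µm) of
the filtered stack from the seed markers, restricted to the mask
(6-connected flood front, FIFO tie-break, deterministic). Every mask voxel
receives exactly one label; mask components that contain no seed adopt the
nearest seed's label, so the output is always a partition of the mask.

**Volume filter** removes instances outside [500, 60 000] µm³ — debris
below any plausible soma, and merged clumps above the histogram's ceiling
with margin, so nothing is silently discarded before quality control.

# Soma morphometry and expansion correction

Per instance: voxel count, raw volume (voxel count × voxel volume, in the
cleared/expanded imaging frame), corrected volume (raw divided by the cube
of the linear expansion factor; the default 1.2 gives 1.728), centroid and
bounding box. Both volume frames are always emitted, and downstream
statistics use the corrected one by default.

The size histogram uses left-closed right-open 1 000 µm³ bins from 0 to
38 000 µm³; values at or above the ceiling are tallied separately, never
silently dropped. The left-closed convention is a package choice (the
range and width are fixed, the edge convention was open).

As a consistency check mirroring 2D practice, `project_and_measure_diameters`
takes a ~100 µm slab, keeps only instances fully contained in it
(instances touching the slab faces are excluded), projects along z and
reports equivalent-circle diameters, flagging overlapping projections for
QC. On synthetic spheres the medians of these 2D diameters and of the
3D-derived diameters (6V/π)^{1/3} agree within 10 % — similar but not
identical, as projection geometry dictates.

# Subtype classification

The soma-size histogram is fitted by nonlinear least squares (Levenberg–
Marquardt) with one or two Gaussian curves A·exp(−(x−µ)²/2σ²) evaluated at
bin centres. Fitting histogram **counts** (not an EM fit of raw samples) is
deliberate: it reproduces the common curve-fitting practice for such
histograms; the bins are the data. Initialisation is deterministic — the
two largest local maxima of the 3-bin smoothed histogram at least 3 bins
apart (falling back to the 25th/75th percentile bins), σ₀ = 2 bins — so
there are no random restarts and fits are reproducible.

Modality is decided by refitting with one and two components and requiring
both a BIC improvement above a configurable margin (default 10, computed
from the Gaussian-error RSS over the 38 bins) and mean separation
µ₂ − µ₁ > σ₁ + σ₂. The margin is logged with every decision; by eye a
histogram turns "bimodal" gradually, so the evidence is always recorded.

With two components, the classification threshold is the x-coordinate
where the two fitted curves intersect, found by bisection between the
means (with a flagged fallback to the minimum of the summed curves when
heavy overlap leaves no crossing). Somata strictly below the threshold are
putative γMNs; ties go to α because only "smaller than the threshold" is
γ. These are size classes, not validated identities.

**What recovery means here.** When volumes are simulated from a
two-component mixture and pushed through bin → fit → intersect → classify,
the recovered small fraction carries a small upward bias (≈ +1.3 pp at the
package's default mixture): the intersection threshold is the mixture's
Bayes boundary, and the broad large-soma component leaks more mass below
it than the narrow small-soma component leaks above. The acceptance suite
requires the recovered fraction to stay within ±2 pp of the generating
weight at realistic sample sizes (889–3 553 somata, 20 replicates).

# Synthetic data: what it emulates, what it does not

`generate_soma_field` renders densely packed, axis-aligned ellipsoidal
somata whose volumes follow a configurable one- or two-component Gaussian
mixture (defaults: weight 0.3, means 4 000/15 000 µm³, SDs 1 200/4 000 µm³
— a well-separated, ~4 pooled-SD mixture of the kind the soma-size
histograms show after subtype differentiation), with ≥ 25 µm centroid
separation, a plateau intensity profile with a 1-voxel Gaussian-blurred
edge, and additive Gaussian noise (peak 200, background 20, noise SD 10).
Semi-axes vary within 0.8–1.25× the sphere-equivalent radius but are
normalised so each soma's analytic volume equals its sampled volume
exactly; the soma shape statistics are a modelling choice, not a
literature claim. The canonical test condition is 50 somata in a 256³
stack at 1.5 µm isotropic spacing.

`generate_neuron_stack` grows a rooted tree (primary dendrites spread over
the sphere, branches of ~N(18, 4) µm segments with per-step angular jitter
controlling tortuosity, bifurcation probability per order up to order ≥ 6),
renders constant-radius 1.5 µm tubes plus a soma ball, and sets dendrite
intensity to 1/3 of the soma's — matching the 2–3× soma/dendrite intensity
difference seen in retrogradely labelled cells. Branch directions reflect
at the volume walls so trees stay inside the grid.

One root seed drives everything; identical seeds give bit-identical
volumes and truth tables.

Not emulated: optical PSF anisotropy beyond voxel spacing, tiling or
stitching artefacts, photobleaching, intensity heterogeneity across
somata, spines, or diameter variation along dendrites. Passing tests on
these phantoms therefore demonstrate the correctness of the algorithms
under their stated assumptions — compact blobs, tubular neurites, additive
noise — not performance on any particular microscope's data.

# Dendrite tracing

Rod (Frangi vesselness; bright curvilinear: λ₂, λ₃ ≪ 0, λ₁ ≈ 0) and ball
(blobness; all eigenvalues ≪ 0) responses are computed from γ-normalised
(σ²-scaled) Gaussian Hessians at scales {1, 1.5, 2, 3} µm (rod) and
{4, 6, 8} µm (ball), maximum over scales. Discrete second-derivative
kernels are DC-corrected so a flat volume yields exactly zero response,
and an absolute Hessian-norm floor suppresses numerical residue. The two
responses are each normalised by their maximum and fused voxelwise by
maximum, so soma and dendrites enter one mask at a single threshold
(default 0.05 of the normalised response — the analogue of an interactive
thresholding step, chosen so that on the synthetic neuron the mask covers
≥ 95 % of soma and ≥ 80 % of dendrite voxels).

Hessian responses vanish exactly at soma–dendrite attachments and
branchpoints (the local geometry is neither rod nor ball), which can split
one neuron into several mask components; a 2-voxel morphological closing
bridges those gaps before the largest component is kept. Multi-neuron
stacks are separated by marker-based watershed of the inverted fused
response inside the mask, one soma seed per neuron.

The centerline is obtained by trilinear resampling to isotropic voxels at
the smallest spacing, sequential topological thinning (simple-point test
after Malandain–Bertrand: exactly one 26-connected foreground component
among the 26 neighbours and exactly one 6-connected background component
in the 18-neighbourhood; six directional subiterations; endpoints
protected, with the endpoint test evaluated on the pass snapshot so that
voxels isolated mid-pass do not freeze into radial spurs), then conversion
of the 26-adjacent skeleton voxels into a graph reduced to its geometric
minimum spanning tree — 26-adjacency alone produces spurious triangles at
junctions, and the MST guarantees the acyclic tree the SWC contract
requires. Terminal chains shorter than 4 µm (default) are pruned to a
fixpoint.

Rooting picks the skeleton node nearest the soma centroid (ties: lowest
id); an optional contraction radius collapses all skeleton nodes within
the soma ball into the root, because the thinning remnant of a soma would
otherwise masquerade as extra proximal branchpoints and inflate
centrifugal orders. Orders count outward: root-attached branches are
order 1, each child branch its parent's order + 1.

The reconstructions include the axon; since no algorithmic exclusion rule
is established, the package flags the order-1 stem with the greatest
root-to-tip path length as *axon candidate* when that length exceeds
500 µm (configurable) and excludes it from dendritic metrics only when
asked. Externally edited SWC files re-enter the metrics stage unchanged —
the SWC interface is the manual-correction channel.

# Skeleton metrics

Sholl spheres are 3D Euclidean, centred at the root, at multiples of
`r_step_um` (default 25 µm; recorded in output metadata). Edges are
densified to ≤ 1 µm sub-segments before counting sign changes of
d(node) − r, so a single long edge cannot hide a double crossing; an
endpoint exactly on a sphere is attributed to the sub-segment that ends
there, counting each true crossing once. Crossings are also attributed to
the order of the crossed branch; per-order totals partition the total
counts exactly. Branch length and tortuosity (path length / chord length,
≥ 1, = 1 only for straight branches) are summarised per order 1–6 with
SEM (n − 1 variance); deeper orders are reported in a separate row, never
dropped. All metrics are invariant under rigid motion of the skeleton.

# Numerical choices and degenerate inputs

* Histogram fits require ≥ 6 nonzero bins for two components; all-zero
  histograms are errors. Non-crossing fitted curves trigger the flagged
  minimum-of-sum fallback.
* Mixture sampling rejects and redraws non-positive volumes (truncation at
  zero); a zero-variance component is allowed and yields exact values.
* Empty masks give zero seeds (not an error); empty stacks give zero
  instances; empty label volumes give empty record tables; empty record
  lists give a missing (not zero) small fraction.
* Watershed determinism comes from a FIFO tie-break on equal elevations.
* Label TIFFs use 16-bit containers up to id 65 535 and 32-bit float pages
  beyond (exact for integer ids < 2²⁴); the widening is logged.
* The whole pipeline under a fixed seed is bit-reproducible; run manifests
  record md5 checksums of every written file.

# Problem sizes used by the test suite

The suite runs on one CPU in well under half an hour: the crowded-field
acceptance check uses 50 somata in a 256³ stack (1.5 µm spacing), the
mixture-recovery checks use 20 replicates at n = 889–3 553 (plus a
100-replicate property at n = 1 000), tracing checks use 128³–160³
single-neuron stacks, and the distribution-recovery (KS) property uses a
500-soma field. These sizes were chosen as the smallest at which the
tested statistics are stable, and they are stated here so that reported
tolerances are read against them.

# Known limitations

* Dendrite diameter, surface area and volume are out of scope; skeletons
  carry a nominal radius only.
* Recall on dim distal dendrites is characterised on synthetic phantoms
  only; real stacks resolve such branches by manual tracing, for which the
  SWC round-trip is the supported channel.
* The deep-learning mask of the original workflow is not re-implemented;
  the mask-provider interface accepts any external mask honouring the
  `binary_mask` contract.
* Group-level inference (ANOVA/Tukey across ages or motor pools) is
  deliberately downstream: the package emits tidy per-branch and
  per-soma tables.
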