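---
title: "Automated cartilage morphometry from contrast-enhanced microCT: models and design choices"
author: "cartct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated cartilage morphometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartct)
```

## The measurement problem

Articular cartilage (AC) in the mouse knee is a layer a few tens of
micrometres thick covering the tibial condyles. Soft tissue is essentially
invisible to conventional microCT, but after incubation in a
phosphotungstic-acid (PTA) contrast bath the cartilage layer becomes the
*brightest* structure in the scan — brighter than the subchondral
calcified plate (SCP) beneath it, which in turn is brighter than the
immersion fluid (background, BKG). That three-level contrast ordering is
the single physical assumption every stage of this package builds on.

`cartct` turns a reconstructed grey-level volume into per-condyle
structural readouts: segmented cartilage and mineralized masks, two
automatically placed condylar regions of interest (ROIs), voxel-count
volumes, maximal-inscribed-sphere local thickness, planar thickness maps
and profiles, contrast (SBR) and stain-uptake time courses, and paired
statistics for operated-versus-contralateral designs.

All coordinates follow one fixed axes convention: axis 1 iterates coronal
slices anterior to posterior (AP), axis 2 runs proximal to distal
(downward), axis 3 medial to lateral (ML). Re-slicing from axial or
sagittal stacks is a pure axis permutation — never a resampling — and
anisotropic voxels are rejected rather than resampled, because the
thickness estimator assumes an isotropic grid.

## Hounsfield calibration

Scanner output is calibrated by a two-point affine map,

$$\mathrm{HU}(x) = 1000\,\frac{x - w}{w - a},$$

where $w$ is the mean raw intensity of a user-drawn region in the
immersion fluid (the water-equivalent reference, mapped to 0 HU) and $a$
that of an air region (mapped to $-1000$ HU). Scans acquired inside the
staining solution make the immersion fluid the natural water-equivalent
reference. Every downstream operation is invariant to this affine map
(Otsu thresholds shift with it; thickness and volumes ignore intensity),
so calibration is a reporting convenience, not a correctness requirement.

## Segmentation

Thresholds minimise the weighted intra-class variance of the grey
histogram (Otsu's criterion). The package defaults to a **three-class**
variant: with PTA contrast the histogram carries three modes — background,
mineralized plate, stained cartilage — and the brightest class is the
cartilage. A two-class mode (`otsu2`) is retained: it first separates
foreground from background and then splits the foreground by a second
Otsu threshold, extracting the brightest layer hierarchically. Both are
exhaustive searches over histogram bin edges (integer bins for integer
volumes, 256 uniform bins for real-valued ones; histograms wider than
1024 bins are rebinned), and both are validated against an independent
brute-force minimiser (`otsuBruteForce`) that scores every candidate
partition directly from the counts.

Morphological cleanup removes connected components below 500 voxels
(26-connectivity; at 5 um voxels that is speckle far below any plausible
cartilage fragment), fills internal holes slice by slice, and keeps only
cartilage components that reach background within 3 voxels above — the
articular surface faces the bath from above, and the 3-voxel gap absorbs
the partial-volume band a blurred surface produces, in which mixed
voxels classify as plate.

Ties in the threshold search are broken towards the smaller threshold so
results are bit-reproducible. When grey classes are widely separated the
criterion can be flat over the empty valley between modes; the tie-break
then returns the smallest edge in that valley, which any downstream
masking is insensitive to.

## Automatic ROI placement

The joint surface is summarised by a *top-edge height map*: for every
(AP, ML) column, the first mask row from the top. The condylar symmetry
axis is the ML column about which this height map best matches its own
mirror image, by exhaustive integer scan refined to sub-voxel precision
with a 3-point parabola. Columns whose mirror partner is undefined (or
reflected outside the grid) are charged a full-scale mismatch penalty;
without that term the score can be maximised degenerately by centring the
mirror on a single condyle — a sphere matches itself — which is exactly
the failure mode asymmetric (thinned) joints would trigger.

Each condyle then receives one fixed-footprint box, 500 um (ML) by
800 um (AP) by default — 100 x 160 voxels at 5 um, converted once by
round-half-away-from-zero. The ML centre is the centroid of the
cartilage columns on that side of the symmetry axis (parameter-free, and
recovers programmed condyle centres on phantoms within 2 voxels); the AP
centre is the midpoint of the foreground AP extent; the box extends from
the highest top-edge row inside the footprint down 400 um, covering
cartilage, plate and trabecular bone. Cartilage metrics intersect the box
with the cartilage mask, so the depth only needs to cover the shell.

The condylar axis is not assumed to coincide with the ML direction: the
tilt estimator locates each condyle's thickness peak and reports the
signed angle between the peak-to-peak line and the ML axis. The peak is
the thickness-weighted centroid of the cells at or above half the side's
maximum. A narrower support (for instance the top decile) is unstable on
flat-topped thickness maps — on a uniform shell the top decile is a
noise-selected scatter and the centroid wanders by a couple of degrees —
while the half-max support is broad enough to average that selection
noise away and still tracks a programmed 12 degree rotation to within a
tenth of a degree.

## Local thickness

The thickness at a point $p$ of the cartilage mask is the diameter of the
largest sphere fully inscribed in the mask that contains $p$ — the
model-independent, orientation-free definition used throughout bone and
cartilage morphometry. The implementation is the classical three-step
algorithm: exact Euclidean distance transform (squared distances by the
parabolic lower-envelope method, exact in integer arithmetic); reduction
to non-redundant sphere centres, discarding any centre whose sphere lies
entirely inside a 26-neighbour's sphere ($r_q \ge r_p + \lVert pq\rVert$,
a pruning that provably never changes the maximum); and sphere painting.
Spheres must fit inside the mask proper — the volume outside the grid
counts as background, with no border clamping — and the mean thickness of
an ROI averages over *mask voxels* (volume-weighted), not over sphere
centres, after computing the field on the full mask so ROI edges never
truncate spheres.

An exhaustive reference (`localThicknessBruteForce`) recomputes the same
definition by scanning all centres and all background voxels; the ridge
implementation agrees with it exactly on every shape tested. On analytic
shapes the digital estimate carries the expected half-voxel quantisation:
digitised balls and slabs land within one voxel of their closed-form
values, and a uniform shell reads about 2 um (0.4 voxel) thick-biased at
5 um voxels. The bias is geometry-stable, so paired comparisons — the
scientific readout — cancel it: programmed thinning factors of
0.90/0.85/0.75 are recovered as percent differences within one point.

Thickness maps project the field per (AP, ML) column; the default
statistic is the column maximum, which highlights each condyle's peak
thickness, with the mean available. Profiles cut the map mediolaterally
through the mid-coronal plane or anteroposteriorly through either
condyle centre, and equal-length profiles average cell-wise across
samples.

## Contrast and uptake

Contrast is quantified as the signal-to-background ratio
$\mathrm{SBR} = 100\,(\mu_{sig} - \mu_{ref})/\mu_{ref}$, the relative
percent difference of region means — zero when the region matches its
reference, invariant to global intensity scaling. Reference regions
(background and plate) are supplied by the user as boxes or masks; the
package deliberately does not auto-place them, since nothing in the
measurement constrains where a "representative" reference should sit.

The synthetic uptake model is a saturating front: cartilage grey at depth
$d$ below the articular surface and time $t$ follows
$g_{bkg} + (g_{cart} - g_{bkg})\,\max(0,\, 1 - e^{-k\,(t - d\,\tau)})$,
with rate $k$ (1/h) and surface lag $\tau$ (h/um). It reproduces the
qualitative features of stain penetration — surface-first staining,
invisibility of unstained cartilage at $t = 0$, saturation to a plateau —
with two parameters; it is a phenomenological stand-in, not a diffusion
model. Plateau detection reports the earliest sampled time from which the
cartilage mean stays within a relative tolerance band of its final value;
if only the final sample qualifies, the series has not plateaued inside
the window and an error is raised rather than a guess returned.

## Surface export

Meshes for downstream finite-element tools are extracted by marching
tetrahedra on the Kuhn six-tetrahedron cube decomposition, which is
face-consistent across cells and therefore closed (watertight) by
construction, with outward-oriented triangles. The binary mask is
Gaussian-smoothed (sigma 1 voxel) before isosurfacing at level 0.5: a raw
binary isosurface places vertices at edge midpoints and overestimates a
sphere's area by tens of percent, while the smoothed surface lands within
a few percent of analytic areas and within 5% of voxel-count volumes.
Meshes are written as standard binary STL with coordinates in
micrometres.

## Statistics

Paired designs (operated versus contralateral) use the two-tailed paired
Student's t test with the 95% CI of the mean difference; identical
samples return t = 0, p = 1 by convention rather than an error, so
degenerate report rows stay interpretable. The unpaired test defaults to
pooled variance with Welch available by flag. The Wilcoxon signed-rank
test drops zero differences and uses the exact null distribution up to 25
untied differences (small-n group sizes make the exact tail essential:
five all-positive differences give the 1/16 two-sided floor), falling
back to the tie-corrected normal approximation otherwise. Near-normality
is checked by a one-sample Kolmogorov–Smirnov statistic against a normal
with the sample mean and SD; estimating the parameters from the same data
makes the check conservative, which is documented and accepted — it is a
screening step, not an inferential endpoint. Regression reports the
least-squares slope, the coefficient of determination (the squared
Pearson correlation) and the two-tailed slope p-value. Reproducibility is
summarised by the coefficient of variation (100 SD/mean, sample SD), and
group effects by the percent difference of treated over control means —
asymmetric in its arguments by construction. Report generation is a pure
function of its input table with deterministic row ordering.

## The phantom: what it does and does not emulate

Every test input is generated by `makeTibiaPhantom()`: a mineralized
plateau carrying two spherical-cap condyles coated by cartilage shells of
programmed per-side thickness, rendered as class greys, Gaussian-blurred,
and degraded with seeded additive Gaussian noise; ground-truth masks are
frozen before blur and noise. Spherical geometry makes the truth shell
thickness analytic (a 60 um shell at 5 um voxels is exactly 12 voxels
along the apex normal), which is what allows exact parameter-recovery
testing. Variants thin one side's shell by a factor (the focal cartilage
loss of destabilisation models), carve a scalpel slot of programmed
width and depth, or render a stain-uptake time series.

Default conditions: 5 um isotropic voxels; 180 x 96 x 280 voxel grid;
250 um condyles offset 325 um either side of the midline (the smallest
symmetric separation at which the shells stay disjoint); 60 um shells;
greys 100 (background), 185/1.35 (plate) and 185 (cartilage), fixing the
noise-free cartilage contrasts at exactly 85% versus background and 35%
versus plate — inside the plateau bands contrast-enhanced scans of this
kind exhibit; blur sigma of one voxel; and noise SD equal to 10% of the
plate-background separation, the hardest condition the recovery tests
are specified at.

What passing on phantoms does **not** show: real condyles are irregular,
cartilage thickness varies anatomically, menisci and other stained soft
tissues abut the cartilage (physically removing them is part of the
acquisition protocol precisely because they confound segmentation), and
scanner noise is neither Gaussian nor stationary (beam hardening, rings).
The pipeline is geometry-agnostic past segmentation, so the phantom
validates the measurement chain, not the biology.

## Numerical choices and degenerate inputs

* um-to-voxel conversions round half away from zero, once per quantity,
  so box footprints are bit-reproducible (500/5 -> exactly 100 voxels).
* All randomness is seeded through object fields (`PhantomSpec@seed`);
  generation restores the caller's RNG state.
* Empty masks, empty ROI intersections, all-zero difference vectors,
  constant regressors and unsaturated uptake series raise errors rather
  than returning sentinel values.
* ROI boxes are half-open, 0-based (the convention of the on-disk JSON
  interface); helpers convert to R's 1-based closed indexing in one
  place.
* Problem sizes in the shipped tests: the thickness oracle runs on
  blobs up to 32^3 voxels and analytic balls/slabs; recovery tests use
  the full 180 x 96 x 280 default phantom across 5 seeds and 3 thinning
  factors; the type-I-error calibration uses 10,000 null replicates of
  n = 6 pairs.

## A minimal worked run

```{r example, eval = FALSE}
spec <- phantomSpec(seed = 41)
ctrl <- makeTibiaPhantom(spec)
dmm <- applyThinning(spec, 0.852, "medial")   # ~ -14.8% medial loss

res <- runPipeline(pipelineConfig(), ctrl$volume)
res$morphometry
#>      side volume_mm3 mean_thickness_um n_voxels
#> 1  medial 0.02500875          59.05885   200070
#> 2 lateral 0.02501088          59.03579   200087
```

## Known limitations

* Calcified cartilage is not separable from the mineralized plate at this
  contrast; the tidemark is the lower cartilage boundary.
* The thickness estimator quantises at the half-voxel level; absolute
  values carry a geometry-dependent bias of up to one voxel, and only
  paired contrasts should be interpreted at finer resolution.
* The uptake model is phenomenological; rate constants fitted to it have
  no direct diffusion-coefficient interpretation.
* Segmentation assumes the menisci have been removed (physically or by
  virtual cropping); intact-joint scans will merge stained soft tissues
  into the cartilage class.
* The compositional insensitivity of the stain means no proteoglycan
  readout is available by design.
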