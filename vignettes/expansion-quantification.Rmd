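---
title: "Quantifying whole-animal expansion microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-animal expansion microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormExM)
```

Expansion microscopy (ExM) physically magnifies fixed tissue by embedding
it in a swellable hydrogel: after homogenization and dialysis in water a
specimen grows ~3–4× linearly, so a diffraction-limited microscope resolves
correspondingly finer biological detail. For intact, cuticle-enclosed
*C. elegans*, the quantitative questions this package addresses are:

* **Isotropy** — how faithfully did the animal expand? Measured as the
  root-mean-square (RMS) length-measurement error between pre- and
  post-expansion images over measurement lengths of 0–100 µm.
* **Resolution gains** — how many more synaptic puncta does a line
  profile resolve after expansion, and how many transcripts can be counted
  per neuron?
* **Staining quality** — the signal-to-background ratio (SBR) of an
  immunostain, from percentile-ranked pixel masks.
* **Expandability** — the worm's linear expansion factor normalized by
  its hydrogel's (nExF), the figure of merit for homogenization
  treatments.

Because no public image data accompany these procedures, every stage is
validated against a synthetic worm phantom with exact ground truth.

## Units and conventions

An `ImageField` carries its per-axis pixel size in **absolute**
(post-expansion) micrometres plus the specimen's linear expansion factor
E. Biological lengths divide absolute lengths by E
(`toBiologicalUnits()`). Arrays are `(y, x)` or `(z, y, x)`, coordinates
0-based and pixel-centred; ROI boxes include both corners. The expansion
factor is user-supplied metadata, never inferred silently from an image.

## The worm phantom

`phantomSpec()` + `generatePhantom()` render a parametric worm twice: in
the pre-expansion frame and after a global similarity (scale `eTrue`,
rotation, translation) composed with a smooth residual displacement
field. The scene contains the structures the downstream stages key on:

* a tapered tubular body (~90 µm midline, radius 6 µm) with two
  pharyngeal bulbs, posed in an asymmetric S so that registration has no
  spurious rotational self-similarity;
* a bright nerve-ring band with a plateau cross-profile whose core level
  is exactly `nerveRingBrightness` × body intensity (so mask means are
  analytically known);
* dark ellipsoidal nuclei with 1.6–3 µm length scales;
* synaptic puncta along a ventral cord, placed by sequential rejection
  sampling that enforces a minimum spacing;
* a multiplicative tissue texture (Gaussian random field, 25% relative
  sd, 5 µm correlation length) that deforms with the specimen —
  real worms are richly textured, and intensity-based registration is
  only informative where gradients exist;
* sCMOS-like noise: Poisson(gain·I)/gain plus Gaussian read noise,
  drawn from a noise stream separate from the geometry stream so noise
  can be varied at fixed geometry.

The post frame is rendered by evaluating the analytic pre-expansion scene
through the **exact inverse** of the forward map (a fixed-point inversion
of the displacement field), so every intensity feature — including object
edges — transforms by the ground-truth deformation, not just object
centres. The PSF stays absolute (optics do not expand), which gives the
post image its physically finer biological-scale detail. With zero noise,
zero residual field, and an identity similarity, pre and post frames are
bit-identical.

### The deformation model

The residual field is built by Gaussian-smoothing white noise on a coarse
grid (node spacing ℓ/2, kernel sd ℓ/2), giving autocorrelation
≈ exp(−r²/ℓ²), then rescaled to a per-component standard deviation σ_d.
Two identifiability conventions are imposed at generation: the field has
mean ≈ 0, and its best-fit global similarity (translation + scale +
rotation) **over the body support** is projected out. Without the second
step the decomposition into "rigid transform" and "residual distortion"
is ill-posed — a long-wavelength field over a finite worm contains a
large similarity component that any scaled-rotation registration rightly
absorbs into its scale estimate. The published percentile summaries of
tissue displacement give ranges, not a field model; the Gaussian random
field is our modelling choice and is flagged as such.

`expectedPairError()` is the Monte-Carlo oracle for the RMS-error
statistic: random point pairs at separation L inside the mask, each
endpoint displaced by the true field, RMS of |post length − L|. Its
limits are analytic: 0 for a zero field, ~linear growth for L ≪ ℓ, and a
plateau near √2·σ_d for L ≫ ℓ.

## Registration and the RMS error curve

`registerRigid()` estimates the scaled rotation by maximizing normalized
cross-correlation over foreground samples, initialized from intensity
moments (centroid, principal axes, second-moment trace); both principal
axis orientations are tried, with a 12-start angular sweep as a fallback
when neither converges confidently. The post image is pre-smoothed to the
pre image's biological scale before comparison. The recovered scale
estimates the raw expansion factor; on noiseless similarity-only phantoms
it is accurate to ~0.3%.

`registerNonrigid()` is a multi-resolution free-form deformation:
displacements live on a control mesh (bilinear interpolation), optimized
over three pyramid levels (mesh spacing 4×, 2×, 1× the target) by
L-BFGS with an analytic gradient of the masked, z-scored
sum-of-squared-differences plus a first-difference smoothness penalty λ
on the mesh. The foreground mask is Otsu's threshold of the σ = 2 px
smoothed pre image; images with < 1% foreground are rejected. Two
refinements matter in practice:

* **Symmetric estimation** (`symmetric = TRUE`): registering both ways
  and composing the backward field's inverse halves estimation noise at
  twice the cost.
* **Similarity refit**: after optimization, the residual's own best-fit
  similarity over the mask is folded into the rigid transform — the same
  identifiability convention the generator imposes on the truth. This is
  what makes "recovered rigid scale" and "residual field" well-defined
  quantities.

For validation studies the mesh spacing is `min(ℓ/2, 5 µm)` — the mesh
must resolve both the field and the worm's ~12 µm body width — and λ
follows a matched prior, λ = 7.5e-5·(ℓ/h)²/σ_d² clamped to
[0.002, 0.03]: smoother, lower-amplitude fields tolerate (and need)
stronger regularization because the data term carries less information
per node. On real data, where σ_d and ℓ are unknown, the defaults
(10 µm mesh, λ = 0.002) are a reasonable starting point and the
`metric` slot (NCC) diagnoses convergence.

`rmsErrorCurve()` samples point pairs inside the mask, applies the
recovered field to both endpoints, and reports RMS |Δlength| per 1 µm
separation bin, in biological units (the rigid scale is divided out
during alignment). Sampling is stratified per bin by default: uniform
endpoint pairs would leave short-separation bins nearly empty in a
~100 µm mask. Bins with fewer than 30 pairs are NA with a warning;
`aggregateRmsCurves()` averages curves across animals, as the published
per-age-group curves do. Fractional error curves (`rms/L`) are invariant
to the expansion factor, which we verify by rendering the same phantom
geometry at E = 1 and E = 3.3.

The validation surface (`isotropyStudy()`) compares the pipeline curve,
averaged over three animals, with the Monte-Carlo oracle per bin over
5–70 µm (the straight-line pair separations the worm geometry supports),
at σ_d ∈ {0.3, 1} µm, ℓ ∈ {10, 30} µm, E ∈ {3.3, 3.8}. Agreement is
within ±20% per bin with the rigid scale within 1% — note that at
σ_d = 0.3 µm the pipeline is recovering displacement differences of
fractions of a pixel, near the accuracy floor of intensity-based
registration; the residual positive deviations at short separations are
that floor.

`straightenImage()` resamples a worm along its fitted midline spline at
unit arc-length steps (normal offsets up to a half-width), the standard
body-posture normalization applied before registration when postures
differ grossly between imaging rounds.

## Puncta counting

Line profiles are extracted at 1 px arc-length steps (bilinear, with an
odd perpendicular averaging width, default 1), linearly normalized to
[0, 1] (a constant profile maps to zeros — a valid "no punctum"
observation), and smoothed with a centred 3-sample moving average that
shrinks to 2 samples at the ends rather than padding. Peaks are interior
plateau-aware local maxima; each peak's **topographic prominence** is its
height above the higher of the two minima separating it from the nearest
strictly-higher ground, with the signal ends acting as boundaries. Peaks
with prominence ≥ 0.01 are counted; the threshold is closed at 0.01
(ties are a measure-zero event on real data). The implementation is
checked exhaustively against an independent water-level oracle on
grid-valued profiles.

`foldChange()` reports the through-origin least-squares slope of post
versus pre counts as the primary statistic and the ratio of sums as the
secondary one, since a printed "x-fold more puncta" could be either.

`punctaResolutionStudy()` demonstrates the mechanism by which expansion
raises counts: when a fraction f of inter-punctum gaps lies below the
resolvable distance at the native scale but above it after 3.3×
expansion, the post/pre fold change grows monotonically with f and
exceeds 1 whenever f > 0. Sub-resolution gaps are drawn at 0.8–1.8 PSF σ
and resolvable ones at 5–12 σ, so the two populations sit clearly on
either side of the effective resolution limit (PSF plus the 3-sample
smoothing).

## 3D spot calling

`detectSpots()` band-passes the stack with an anisotropic
difference-of-Gaussians whose kernel is κ = 0.7× the expected spot σ —
slightly undersized, which keeps close pairs separable at a small
noise-suppression cost — normalized so an isolated unit-amplitude spot
filters to ≈ 1. Detections are 26-connected regional maxima above the
amplitude threshold, deduplicated only for exact plateau ties, and
refined by intensity-weighted centroids in a (3σ)³ window. Default spot
sigmas (0.2 µm lateral, 0.35 µm axial, absolute units) follow the
effective size of HCR amplicons at ~3.3× expansion (~150 nm lateral /
~250 nm axial in biological units) convolved with a confocal PSF.

The detection threshold corresponds to the manually-chosen per-stack
intensity cutoff of interactive workflows; `suggestThreshold()` automates
it by finding the flattest plateau of the count-vs-threshold curve,
which is equivalently the widest gap in the sorted candidate amplitudes
(the count is constant across a gap). A gap only qualifies as the
signal/noise separation if it leaves at least 3 and at most half of the
candidates above it — a noise-only stack offers gaps only in its own
distribution tails, which fail that condition, set the warning flag, and
fall back to the median-gradient threshold for manual review.

`countInRois()` assigns refined spot coordinates to axis-aligned,
inclusive 3D boxes, resolving overlaps by list order;
`fractionInMask()` reports the fraction of spots whose nearest voxel
falls in a mask (NA for an empty table — "no spots" is missing, not
zero).

The FISH phantom (`generateFishPhantom()`) places one spherical soma per
cell on a jittered grid, draws per-cell Poisson counts, and positions
transcripts uniformly in the perinuclear shell with a 10% nuclear
minority — the sub-cellular distribution observed for mRNA in these
animals (~80–90% perinuclear, ~5–20% nuclear). At 50 cells, SNR 5 and
λ ∈ {2, 5, 20}, recovery is essentially unbiased (|bias| ≤ 0.5 spots,
recall and precision ≥ 0.95). `transcriptCountStudy()` runs the same
workflow with per-neuron means set to published single-neuron
abundances (188.3 and 48.7 transcripts for a high- and a low-expressing
neuron) in 5 µm somata; at the implied density a few percent of
transcripts sit closer than the detector's resolution and merge, so
recovered means run ~2–4% low — the same physics a real measurement
faces.

## Signal-to-background ratio

`cropRegion()` cuts squares in biological units (default 50 µm, the
standardized nerve-ring/upper-body crop). `percentileMasks()` thresholds
by order statistics — signal pixels at or above the 98th percentile of
the signal crop, background pixels inside the interquartile band of the
background crop, ties included so integer images behave
deterministically. The published mask generation is "semi-automated"
without stated percentiles; 98 / [25, 75] are our defaults and both are
exposed. `sbr()` is the ratio of masked means (infinite, with a warning,
for a zero background mean). On two-level phantoms the recovered SBR is
within 10% of the configured contrast for c ∈ {2, 5, 10, 50} at
SNR ≥ 10; validation uses 10 µm crops so the interquartile band samples
only tissue (a 50 µm crop of a 12 µm-wide worm would mix canvas
background into the band).

## Expansion factors and nExF

`arcLength()` integrates a natural cubic spline through traced points
(chord-length parameterization, refined to a 1e-4 relative tolerance);
worm length is measured along the midline spline, the gel factor from
the mold-contour trace, both supplied as point lists since the original
measurements were manual traces. `normalizedExpansion()` divides the
worm factor by the gel factor; values above 1.05 are flagged, not
rejected, because tracing noise can push slightly past unity.
`simulateExpansionCohort()` draws gel factors from the measured hydrogel
variability (mean 3.53, sd 0.16), applies a fixed worm/gel ratio with
~1 µm tracing noise on every point, and shows the normalization removing
the gel variance: nExF sd ≤ 0.02 around the true ratio while the raw
worm factors vary with the gel.

## Pipeline driver

`readRunConfig()`/`runStage()` validate a YAML config up front (a bad
prominence threshold fails before any registration starts), execute one
stage (`simulate`, `distort`, `puncta`, `spots`, `sbr`, `expansion`),
write CSV/TIFF outputs plus a JSON manifest (stage, seed, package
version, parameters, output checksums), and remove partial outputs on
failure. Reruns with the same config and seed are bit-identical. A thin
command-line wrapper ships in `inst/scripts/exm-pipeline.R`.

## Problem sizes and limitations

Validation studies use 100 µm phantoms at 0.32 µm pixels (~313² pre,
~1100² post frames), three animals per registration condition, 50-cell
FISH stacks at (0.3, 0.15, 0.15) µm voxels, and 10⁵ profiles in the
prominence sweep; these sizes keep each study in the minutes range on a
single core while leaving per-bin sampling error well below the
tolerances being checked.

What passing these studies does **not** show: the phantom's texture is a
stationary Gaussian field, not real anatomy; its deformations are
smooth similarity-free Gaussian fields, whereas real distortion
concentrates at specific anatomical sites (vulva, mouth); FISH somata
are spheres with uniform shells; and no optical aberrations, bleaching,
tiling seams or cuticle scattering are modelled. Registration accuracy
on real images should be judged by the reported NCC metric and, where
possible, landmark checks, not extrapolated from phantom numbers.
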