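---
title: "Methods: cross-sectional geometry and porosity of growing long bones"
author: "boneCSG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-sectional geometry and porosity of growing long bones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneCSG)
```

## Scope and model

boneCSG measures how the cross-sectional structure of a growing long-bone
diaphysis changes with age. Its inputs are grayscale voxel volumes of
epiphysis-free femora (isotropic voxel size, mm) plus tabular cohort
metadata; its outputs are per-section geometry records, cohort trend
curves, stage summaries and femur-length-based age estimates. The section
model is deliberately simple and standard:

- the **periosteal border** is the traced outline of the largest
  thresholded bone component, holes filled;
- the **endocortical border** is approximated by an **ellipse** fitted to
  the medullary cavity — an explicit simplification that makes MA robust
  to endosteal resorption scalloping (a traced endosteal contour is *not*
  used for MA);
- second moments of area are computed on the **solid** cortical region
  between the two borders (pores filled), so the SMA quantifies the
  outline-level distribution of bone, not pore microstructure;
- porosity is everything sub-threshold between the two borders.

All areas are reported in mm², SMAs in mm⁴, and the four size-independent
ratios (Imax/Imin, Ix/Iy, MA/TA, CPA/CA) are dimensionless. The axis
convention is x = mediolateral, y = anteroposterior, z = long axis with
the distal end at low z; `Ix` (about the ML axis) measures bending
rigidity in the AP plane.

## Pipeline stages and numerical choices

**Thresholding.** The minimum (histogram-valley) threshold iteratively
smooths the 256-bin histogram with a 3-bin mean filter until exactly two
modes remain (run-compressed plateaus count once), then takes the
lowest-count bin strictly between the modes, ties broken toward the lower
intensity; pixels strictly above the threshold are bone. The iteration cap
is 10,000; histograms that never become bimodal are refused rather than
guessed at. Because a histogram-valley threshold is invariant to monotone
intensity rescaling, no brightness/contrast normalisation step is needed.

**Alignment.** The binary volume's principal axes come from the eigenvectors
of the voxel-coordinate covariance; the long (smallest-inertia) axis maps to
z, and the volume is resampled by nearest neighbour. Nearest-neighbour
resampling preserves the 8-bit/binary nature of the data; its voxelisation
error is the dominant noise term and is budgeted at ≤ 2 % for section
metrics at the voxel sizes used here. Rounding of resampling coordinates is
half-*up*, not banker's: with near-identity rotations the source grid lands
exactly on half-integer positions, where round-half-even would duplicate
every other pixel and visibly distort areas (~1 %) and second moments
(~4 %); half-up makes the identity transform exact. The distal end is
placed at low z either by caller flag or, by default, by comparing mean
foreground cross-section area in the two end slabs (the metaphyseal flare is
wider). Spherical blobs (principal variances within 5 %) are refused as
directionally ambiguous.

**In-plane orientation.** The manual landmark rotation of interactive
workflows is replaced by a deterministic rule: the major principal axis of
the distal-most 5 %-of-length slab's summed cross-section is rotated onto
x. An explicit angle overrides the rule, and a circular distal section
falls back to zero rotation with a warning. Left-side bones are mirrored
across x first so all specimens share one handedness; this mirroring
convention is ours, chosen so left/right twins yield identical metrics.

**Length and sectioning.** Intermetaphyseal length is the foreground
z-extent, (max − min + 1) × voxel size. Sections are taken at fractions of
that extent from the distal end, slice index = zmin + round(fraction ×
(n − 1)) with half-away-from-zero rounding, 0-based.

**Areas.** TA is the filled-outline pixel count × pixel area (pixel
counting, not the polygon shoelace, so hole handling is exact); the traced
polygon is carried for plotting only. MA is the fitted-ellipse area πab and
CA = TA − MA, so TA = CA + MA holds by arithmetic.

**Ellipse fit.** Direct least-squares conic fitting (the numerically stable
Halir–Flusser formulation) on the cavity's boundary pixel centres, with a
half-pixel outward correction (boundary pixel centres sit about half a
pixel inside the true border). Wild fits — centre outside the boundary
bounding box or area far from the cavity's pixel area — and degenerate fits
fall back to the cavity's moment-equivalent ellipse. Sections without an
enclosed cavity yield a zero-area ellipse (MA = 0) with a warning, not an
error. The exact objective used by interactive tools is not standardised;
least squares is this package's documented choice.

**Porosity.** CPA counts sub-threshold pixels between the two borders,
excluding pixels that belong to the medullary cavity's own connected
component: where the fitted ellipse slightly under-covers the cavity, that
spill-over is medullary space, not intracortical porosity. Without this
guard a pore-free section could never report CPA = 0 under an imperfect
ellipse fit. The porosity denominator is the outline-based CA (pore area
included); whether to exclude pore area from the denominator is genuinely
ambiguous in the field, and the alternative is a one-line change on the
returned record.

## Locomotor stages and trend analysis

Stages follow the five age bins of chimpanzee locomotor development
(carried; early independent locomotion dominated by climbing/suspension;
increasing terrestrial quadrupedalism; independent juvenile; near-adult).
The printed descriptions leave gaps ("2.9 / 3 years"); the bins are
implemented half-open — [0, 5/12), [5/12, 3), [3, 5), [5, 10), [10, 13)
years — so they are exhaustive and non-overlapping and reproduce the
reference sample's stage counts (2, 5, 2, 7, 4) exactly.

LOESS trends use tricube-weighted local regression over the span fraction
(default 0.7, matching the convention for these ontogenetic plots) of
nearest neighbours, evaluated on a 100-point grid with pointwise 95 %
intervals from the local fit's variance estimate
(`surface = "direct"` so linear data are reproduced exactly). The local
polynomial **degree defaults to 2**. A degree-1 fit was evaluated and
rejected on evidence: with span 0.7 over a 0–12.6-year range the one-sided
boundary windows of a local-linear smoother pin the fitted maximum to the
range edge even for *noise-free* rise-then-fall data, so an interior
infancy/juvenile peak (e.g. of the medullary index) can never be located;
a local quadratic tracks both the peak and the monotone segments, and is
also the default of R's `loess()`, the tool these plots are conventionally
made with. Peak location is read as the grid argmax
(`trendPeakAge()`); monotone decline is tested as "never rebounds above
the running minimum by more than the pointwise 95 % half-width"
(`trendNonIncreasingAfter()`), a tolerance anchored to the fit's own
uncertainty rather than an arbitrary constant.

Stage summaries use quartiles with linear interpolation (R type 7, the
common box-plot convention — the source material does not specify one),
Tukey whiskers at the most extreme values within 1.5 × IQR of the
quartiles, and outliers beyond them. No inter-stage hypothesis tests are
computed: with 2–7 individuals per stage they would be meaningless, so
trends are assessed by the LOESS curves and summaries only.

## Age model

Femur length is regressed on age with an OLS cubic, FL(a) = c0 + c1·a +
c2·a² + c3·a³, following the convention of plotting length against age;
age for an unknown individual is obtained by numerically inverting the
curve (bisection; the root is unique because monotonicity is verified on a
1000-point grid and non-monotone fits are flagged). Lengths outside the
calibrated range ± 5 % of its width are refused as extrapolation. The
bundled calibration table marks 16 individuals as known-age (11 with
documented birth/death dates or dental histology, 5 with birth year known
to the year only); the four individuals whose ages were themselves
estimated from femur length are excluded. The published description of the
calibration set is ambiguous (14 vs 16 individuals); the 16-point set is
the default and `growthCalibrationPairs(includeYearOnly = FALSE)` gives the
stricter subset. Reported ages are rounded to 2 decimals, matching the
reference table's precision.

## The synthetic generator

`makePhantomVolume()` rasterizes a tapered elliptical annulus: outer and
endocortical semi-axis profiles are piecewise linear in the length
fraction, with defaults giving a flared distal end (ML-dominant, so
automated orientation is well defined), a mid-shaft waist at 45 % of
length (so the 35/50/65 % sections differ measurably) and a moderate
proximal flare. Grayscale is 8-bit (background 20, bone 200) with additive
Gaussian noise clipped to [0, 255]. Circular pores are planted per slice,
non-overlapping and wholly interior to the cortex with a raster-safe
margin, until the planted area fraction is within 0.5 percentage points of
target; infeasible packings (pore diameter comparable to cortical
thickness, or attempt budget exhausted) raise errors rather than silently
under-planting. Ground truth comes from the continuous closed forms
(TA = πab, MA = πa_i b_i, Ix = π(ab³ − a_i b_i³)/4, Iy = π(a³b − a_i³ b_i)/4);
truth SMAs ignore pores, whose perturbation at ≤ 10 % porosity is below the
pipeline's tolerance. Every generator call uses one explicitly seeded RNG
stream; identical (spec, seed) gives identical output.

`makeCohort()` draws ages uniformly over 0.04–12.6 years, sets femur length
from a monotone default growth curve (coefficients rounded from a fit to
the bundled reference sample) plus 5 mm Gaussian noise, and evaluates three
index trajectories per individual:

- **medullary index**: adult level 0.28 + infant excess 0.08·exp(−age/4) +
  rise amplitude 0.30 · ((age/2.5)·e^(1−age/2.5))³ — rises from ~0.36 at
  birth to ~0.62 at 2.5 years and declines toward 0.28; the peak age sits
  in the later part of the early-independent locomotor stage, consistent
  with a rise between the first two stages and a decline thereafter.
  Individual scatter is additive (sd 0.02).
- **porosity index**: 0.02 + 0.23·exp(−0.9·age) — high neonatal porosity
  decaying to a 0.02 plateau, effectively flat past ~3.3 years
  (`porosityPlateauOnset()`, the age where the decaying excess reaches 5 %
  of its initial amplitude). Scatter is multiplicative lognormal (cv
  0.25): porosity scatter in real ontogenetic series is strongly
  heteroscedastic — large in infancy, near zero after stabilisation — and
  an additive model would put impossible mass below zero.
- **Ix/Iy**: 0.55 + 0.45·exp(−0.45·age), a monotone decline from circular
  toward mediolateral reinforcement; additive scatter sd 0.05.

Phantom geometry realises the indices exactly: with the endocortical
ellipse proportional to the periosteal one at scale s, MA/TA = s²; with
outer semi-axes (a, b), Ix/Iy = (b/a)² for the proportional annulus. So the
generated truth records are exact, and rendered volumes reproduce them up
to voxelisation.

What the generator does **not** emulate: trabecular bone, partially fused
epiphyses, scanner artefacts (beam hardening, rings), cortical-thickness
asymmetry, non-elliptical periosteal outlines, and pore networks (pores are
independent circles per slice). Passing tests therefore demonstrate
correctness of the measurement chain on idealised geometry, not robustness
to every property of real scans.

## Validation problem sizes

The test suite validates 2D sections at 0.05 mm pixels (0.025 mm for the
convergence checks) on annuli with 6–11 mm outer semi-axes; 3D phantoms are
60 mm long at 0.15 mm voxels for the tilt/mirroring invariance checks and
0.25 mm for general pipeline tests — sizes chosen so the full suite runs in
a couple of minutes on one CPU while keeping nearest-neighbour voxelisation
error within the stated 2 % budgets. Trend-recovery checks use 20 cohorts
of n = 40 (the spec-scale study design) on generator truth records, which
is what the trend statistics consume; rendering 20 × 40 voxel volumes would
add hours without touching any additional code path.

## Known limitations

- The endocortical ellipse understates MA for strongly non-elliptical
  cavities; the porosity guard then reassigns the mismatch band to the
  cavity, so CPA stays clean but MA inherits the ellipse bias.
- Principal-axis alignment assumes the diaphysis dominates the inertia
  tensor; volumes with attached epiphyses must be cropped first (the
  pipeline exposes a z-crop for partially fused ends).
- At 20° tilts and 0.25 mm voxels, double nearest-neighbour resampling
  leaves ~2–5 % noise on cavity-derived metrics of small sections; 0.15 mm
  brings all section metrics within 2 % of an untilted reference.
- LOESS peak location from n = 40 uniformly distributed ages carries ~±0.5
  year sampling noise plus ~+0.3 year smoothing bias at span 0.7; peak-age
  claims finer than that are not supported at this design size.
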