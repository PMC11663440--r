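# boneCSG

Cross-sectional geometry and intracortical porosity of growing long bones,
from micro-CT style voxel volumes.

## The problem

During ontogeny a long-bone diaphysis restructures at its periosteal,
endosteal and intracortical surfaces: the medullary cavity expands and then
contracts relative to the whole section, intracortical porosity drops as
primary bone consolidates, and the section drifts from circular toward an
elliptical, direction-reinforced shape as locomotion matures. Skeletal
biologists quantify this from CT scans with a small set of standard
measures taken on transverse sections of the shaft:

- **TA** — total subperiosteal area; **MA** — medullary area (an ellipse
  fitted to the endocortical border); **CA = TA − MA** — cortical area
  (mm²);
- **CPA** — cortical porosity area, the non-bone area between the two
  borders (mm²);
- second moments of area (mm⁴) about the centroidal mediolateral and
  anteroposterior axes, `Ix = Σ (y − ȳ)² A_px`, `Iy = Σ (x − x̄)² A_px`,
  and about the principal axes,
  `Imax, Imin = (Ix + Iy)/2 ± sqrt(((Ix − Iy)/2)² + Ixy²)`;
- the size-independent ratios **Imax/Imin**, **Ix/Iy**,
  **medullary index = MA/TA** and **porosity index = CPA/CA**.

boneCSG implements the full pipeline for epiphysis-free (juvenile) femora:
minimum-threshold binarization of the bimodal grayscale histogram,
principal-axis alignment of the volume, automated in-plane orientation,
intermetaphyseal length, section extraction at 35/50/65 % of length from
the distal end, per-section quantification, locomotor-stage binning, LOESS
ontogenetic trend curves with 95 % intervals, Tukey box-plot summaries per
stage, and age estimation from femur length via an invertible cubic growth
curve. A synthetic phantom generator (tapered elliptical annuli with
planted pores and closed-form ground truth) backs every stage with exact
oracles.

It is written for researchers in skeletal biology / biological anthropology
who want a scriptable, fully reproducible alternative to interactive
image-analysis workflows.

## Worked example

Quantify one synthetic cross-section with known truth — an elliptical
annulus with outer semi-axes 10 × 5 mm, endocortical semi-axes 6 × 3 mm and
10 % planted porosity, rasterized at 0.05 mm pixels:

```r
library(boneCSG)
ph <- makeSectionPhantom(outerSemiAxes = c(10, 5), innerSemiAxes = c(6, 3),
                         poreFraction = 0.10, pixelSize = 0.05,
                         noiseSd = 8, seed = 1)
sectionGeometry(ph$section)
#> SectionGeometry phantom2d_seed1
#>   TA 157.003  CA 100.475  MA 56.527  CPA 9.8825 (mm^2)
#>   Ix 853.567  Iy 3414.888  Imax 3414.888  Imin 853.567 (mm^4)  theta 0.0 deg
#>   Imax/Imin 4.001  Ix/Iy 0.250  medullary 0.360  porosity 0.0984
```

The closed forms give TA = π·10·5 = 157.08 mm², MA = π·6·3 = 56.55 mm²,
Ix = π(10·5³ − 6·3³)/4 = 854.51 mm⁴, Iy = 3417.96 mm⁴, medullary index
0.36, Imax/Imin = 4 — every measured value lands within a fraction of a
percent, and the planted 10 % porosity is recovered as 0.098.

Age estimation from femur length uses the bundled 20-individual reference
sample; the cubic is calibrated on the 16 known-age individuals and
inverted by bisection:

```r
curve <- fitGrowthCurve(growthCalibrationPairs())
curve
#> GrowthCurve: FL(a) = 67.748 + 34.576 a + -3.2116 a^2 + 0.13300 a^3
#>   ages [0.04, 12.57] y  lengths [63.1, 268.5] mm  monotone: TRUE
round(estimateAge(curve, c(163.1, 239.7)), 2)
#> [1]  3.99 11.26
```

For whole volumes, `readStack()` → `binarizeVolume()` →
`alignPrincipalAxes()` → `orientAboutLongAxis()` → `extractSection()` →
`sectionGeometry()`, or `runPipeline()` to do all of it per specimen and
write tidy CSVs plus a JSON manifest. `inst/scripts/bonecsg.R` wraps the
same functions as a command-line tool. The methods vignette
(`vignettes/bone-csg-methods.Rmd`) documents the model, the generator and
all numerical choices.

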