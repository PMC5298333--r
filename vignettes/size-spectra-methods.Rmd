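---
title: "Methods: plankton size spectra from mesocosm experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plankton size spectra from mesocosm experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesospectra)
```

## The analysis in one paragraph

`mesospectra` reconstructs the size distribution of a whole plankton
community — from picophytoplankton below 1 µm to mesozooplankton above
1 mm — by combining two instruments that each cover part of the size
range: a flow cytometer (events converted to cell size through a
scatter–size power law, trusted from ~0.5 to ~60 µm) and a flatbed
scanner imaging net-caught zooplankton (objects segmented and measured,
trusted above ~150 µm). All particles are reduced to a common currency —
equivalent spherical diameter (ESD), biovolume, wet-weight biomass and a
per-litre concentration weight — binned into logarithmically spaced size
classes, and summarised as a normalized particle size spectrum (PSS) and
a weighted biomass spectrum (WBS). Replicated mesocosms in two treatment
arms are then compared per size class or per taxon group with two-sample
t-tests. A seeded community simulator generates data with exactly the
structure the pipeline assumes, so every stage can be verified against
known ground truth.

## The two spectra

Let bin $i$ span $[s_i, s_{i+1})$ in ESD, with linear width
$\Delta s_i = s_{i+1} - s_i$ expressed in mm. With $N_i$ the summed
concentration (# L⁻¹) of particles in the bin,

$$\mathrm{PSS}_i = \frac{N_i}{\Delta s_i} \quad [\#\,\mathrm{L^{-1}\,mm^{-1}}]$$

The division by the linear width removes the distortion that logarithmic
binning introduces (class width grows in proportion to size). Aquatic
particle size spectra are near power laws on this scale, classically with
slopes around $-2$; steeper slopes mean relatively more small particles.

$$\mathrm{WBS}_i = \mathrm{PSS}_i \times \bar{m}_i \times \Delta s_i
  \quad [\mathrm{mg\,L^{-1}}]$$

where $\bar{m}_i$ is the mean individual wet weight in the bin. The WBS
is simply the absolute biomass concentration per log-spaced size class;
summed over bins it returns the community's total biomass concentration
exactly. `compute_spectrum()` computes the WBS as the direct per-particle
sum $\sum m_j w_j$ and asserts at run time (relative $10^{-12}$) that it
equals the product form above — the two are algebraically identical, and
the assertion guards the implementation.

Biomass comes from biovolume at a fixed tissue density of
1.060 g cm⁻³ (so 1 mm³ ↔ 1.060 mg wet weight). Flow-cytometry particles
use spherical biovolume $(\pi/6)\,\mathrm{ESD}^3$; measured scan objects
use the prolate-spheroid convention $(\pi/6)\,\mathrm{major}\times
\mathrm{minor}^2$ from the equivalent-ellipse axes, the common choice in
the zooplankton-scanner community. Simulated "imaged" objects are
spherical, so both conventions coincide there.

## Tunable parameters that matter

| parameter | default | unit | why this value |
|---|---|---|---|
| calibration `a`, `b` | 0.0064, 0.5262 | µm, – | scatter–size power law ESD = a·FSC^b from six-point size fractionation (0.2–8 µm pore filters) |
| FCM trusted range | 0.5–60 | µm | fluorescence-triggered acquisition resolves roughly this ESD range |
| net geometry | 0.17 m × 17 m | m | vertical tow ⇒ 385.9 L; 20 of 500 mL imaged ⇒ 15.4 L effective |
| scan resolution | 2400 | dpi | 10.58 µm pixels ("10.6 µm") |
| min object size | 150 | µm | below this, too few pixels for reliable classification |
| `min_area_px` | 64 | px | ≈ pixel count of a 150 µm disk at 10.6 µm/px |
| copepod classes | <600, 600–1000, >1000 | µm | S (copepodites), M, L (adults) |
| bins per decade | 12 | – | ~0.083-decade bins resolve the 100-µm-scale class bands where treatment effects are reported |
| instrument gap | 60–150 | µm | neither instrument is trusted here |
| density | 1.060 | g cm⁻³ | literature constant for organic tissue |
| α | 0.05 | – | per-class significance threshold |

## Numerical and statistical choices

**Half-open bins and class boundaries.** All intervals are half-open
`[lower, upper)`: a 2 µm cell is nanoplankton, a 20 µm cell is
microplankton, a 600 µm copepod is M, a 1000 µm copepod is L. The
published class descriptions ("2–20 µm", "> 1000 µm") leave the
boundary points ambiguous; half-open intervals make every assignment
deterministic and the classes an exact partition. Bin midpoints are
geometric means, the natural abscissa for log–log fits.

**Zero-count bins** are excluded from slope fits (log of zero); no
pseudo-counts are added.

**Partial-coverage bins.** A bin straddling an instrument-domain edge
(60 or 150 µm) is sampled over only part of its width, so its PSS is
biased low by construction. Such bins are flagged `partial_coverage`
(bins wholly inside the gap are `unobserved_gap`) and both are excluded
from slope fits. This exclusion noticeably improves the linearity of
merged spectra and involves no data-dependent tuning.

**Slope-fit weighting.** `fit_slope()` defaults to ordinary least
squares over usable bins — the convention under which published spectrum
slopes (including the canonical −2) are defined. The option
`weights = "count"` weights bins by raw particle count (inverse Poisson
sampling variance of log-PSS); it is the better estimator when one
instrument with uniform counting effort samples a power law and tail
bins hold single particles, and it is what the package's own
power-law-recovery tests use. It is *not* the default because in merged
spectra the flow cytometer counts orders of magnitude more particles per
litre sampled than the scanner, and count weights would concentrate all
leverage at the small-size end.

**Assumption-guarded t-tests.** Variance homogeneity is assessed with
Levene's test (Brown–Forsythe, median-centred, via `car`): homogeneous
arms get the pooled t-test, otherwise Welch. Shapiro–Wilk normality
results are attached as diagnostics but do not switch the test to a
non-parametric alternative — with n = 5 per arm those tests have little
power, and the analysis stays within the t-test framework it advertises.
Degenerate inputs (both arms constant) return p = 1 for equal means,
flagged. No multiple-testing correction is applied across size classes,
matching the per-class reporting convention of mesocosm studies; the
expected number of false positives per spectrum is attached to every
comparison table to keep that choice visible.

**Summary-statistic t-tests.** `ttest_from_summary()` reconstructs
t = (m₁−m₂)/√(SE₁²+SE₂²) from published mean ± SE tables, with pooled
(n₁+n₂−2) or Welch–Satterthwaite degrees of freedom. With equal group
sizes the pooled statistic is identical to the raw-data pooled t.

**Segmentation.** Objects are darker than background (transmissive
flatbed convention), so "below threshold" is object. Components are
8-connected — standard for blob extraction, and more robust for thin
appendages than 4-connectivity; the labelling is a run-length union-find
implemented in the package. Touching-object separation is deliberately
not implemented: the laboratory protocol separates organisms by hand
before scanning, and the synthetic plate renderer enforces the same
non-overlap guarantee (overlap is an error, not a silent merge).
Border-touching objects are flagged and retained by default, with the
flag exported. Axis estimates add the 1/12-pixel variance of the square
pixel footprint to the second-order moments, so a single-pixel object
has finite axes.

## What the simulator emulates — and what it does not

`default_populations()` encodes a 113-day winter-to-summer succession:
a picoplankton wave peaking around day 57–65 at 3–4× initial abundance;
a broad 5–40 µm phytoplankton background; nanophytoplankton blooms near
day 33 (2–15 µm) and day 57 (4–8 µm); a large centric diatom (200–500 µm)
blooming between days 40 and 65; copepods shifting from medium/large
adults (declining from day 1) to a copepodite-and-nauplii cohort peaking
near day 57; and sparse hydromedusae above 1 mm. Copepod and diatom
trajectories are anchored so that the *expected* control-arm biomass
reproduces a published mesocosm study's t1/t57 treatment-mean table
(total 5.26 → 12.74 mg L⁻¹; copepods 3.43 → 2.58 mg L⁻¹, a 25%
decline; diatom 0.05 → 6.02 mg L⁻¹); the high-CO₂ multipliers (1.6
picoeukaryotes, 1.3 diatom, 1.4 small/medium copepods and nauplii, 0.8
hydromedusae) encode that study's reported effect directions and
magnitudes, making them recoverable ground truth.

The statistical model is deliberately simple: abundances interpolate
linearly between knots (no autocorrelation or dynamical coupling),
counts are Poisson around a mean-one lognormal replicate factor drawn
per population × mesocosm × day, and sizes are lognormal with fixed
parameters per population. The replicate noise default is sd 0.15 on the
natural-log scale. Real mesocosm data differ in ways the simulator does
not attempt: between-mesocosm variability is larger (the published SEs
imply a CV near 0.35, under which the simulated treatment contrasts
would be, like the published ones, mostly non-significant for group
totals), sizes within a population drift over time as cohorts grow,
taxon labels carry classification error, and scan images contain
touching objects and artefacts. Passing tests therefore demonstrate
that the *pipeline machinery* is correct under its stated assumptions —
conservation, calibration inversion, segmentation geometry, test
calibration under the null — not that the simulator is a faithful
generative model of any particular sea.

Two consequences are worth noting explicitly. First, with noise sd 0.15
the simulated CO₂ contrasts on group totals are usually significant,
*more* decisive than the published p = 0.06–0.13; the published
p-values are nevertheless reproduced exactly by `ttest_from_summary()`
from the published table itself. Second, the simulated bloom-day (t57)
spectrum slope comes out near −3.5 to −3.6, somewhat steeper than the
published −3.43, while the initial-day slope lands on −3.29: the t57
slope is an emergent property of biomass-anchored populations plus the
pico wave, and the size range of the published fit is not stated, so no
attempt was made to tune it.

## Problem sizes used in the packaged checks

The default pipeline simulates the two comparison days only
(~2.7 million particles, a few seconds); repeated-simulation checks
(null false-positive rate, effect-direction recovery) use a compact
three-to-four-population experiment at 500 replicates; power-law slope
recovery uses 10⁵ particles per replicate. These sizes were chosen so
that Monte-Carlo error is small relative to the tolerances being
checked while a full run of the suite stays fast enough for routine
development.

## Known limitations

- No mixture/bimodal spectrum models, secondary-production or mortality
  estimation from slopes.
- No automatic taxon classification: category labels are inputs.
- No FCS parsing (events come as delimited text), no fluorescence
  gating, no flat-field correction.
- The unit discrepancy in published biomass tables (mg L⁻¹ vs mm³ L⁻¹
  headers for the same quantities, a 6% difference at density 1.060) is
  left unresolved: tables report both `biomass_mg_l` and
  `biovolume_mm3_l` columns and the reader chooses.
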