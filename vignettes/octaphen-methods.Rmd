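---
title: "Quantifying ischemia, neurodegeneration and subclinical edema in early diabetic retinopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ischemia, neurodegeneration and subclinical edema in early diabetic retinopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaphen)
```

## The problem

In nonproliferative diabetic retinopathy (NPDR), visual acuity loss is
driven by three partially independent disease pathways: **ischemia**
(capillary dropout, visible as reduced vessel density and an enlarged
foveal avascular zone on OCT angiography), **neurodegeneration** (thinning
of the retinal nerve fiber layer, RNFL, and the ganglion cell layer plus
inner plexiform layer, GCL-IPL, on structural OCT), and **subclinical
edema** (thickening of the inner nuclear layer, INL, outer plexiform
layer, OPL, or total retina without clinically evident macular edema).
`octaphen` implements the full quantification-and-analysis chain for these
phenotypes: image-level biomarker extraction, normative classification,
and clustered regression of best-corrected visual acuity (BCVA, logMAR).

Because raw clinical images and tables for this problem are generally not
redistributable, the package ships first-class synthetic generators for
all three input kinds (B-scans, en-face angiograms, eye-level cohort
tables) with exact ground truth, so every stage is testable end to end.

## Layer segmentation

A B-scan is segmented into six surfaces (ILM, RNFL/GCL, IPL/INL, INL/OPL,
OPL/ONL, outer retinal boundary) by gradient-weighted shortest-path
search. Pixels are graph nodes; edges connect 8-neighbours with
left-to-right progress; the edge weight between nodes $a$ and $b$ is

$$w_{ab} = 2 - (g_a + g_b) + \varepsilon,\qquad \varepsilon = 10^{-5},$$

where $g$ is the vertical intensity gradient under the boundary's
polarity (dark-to-light or light-to-dark), normalized to $[0,1]$ after
Gaussian pre-smoothing. Zero-cost virtual side columns make the entry and
exit rows free. Because admissible moves only advance one column, the
global minimum-cost path is found exactly by dynamic programming; ties
prefer the shallower row for determinism. The test suite verifies the
solver against exhaustive path enumeration on 6×6 images.

Surfaces are searched sequentially — the two highest-contrast surfaces
(ILM, outer boundary) first, then interior surfaces inside bands clipped
1–3 px inside previously found surfaces — which guarantees the
monotone-ordering invariant by construction. A violated ordering is a hard
error, never a silent reorder. A manual-override hook accepts
user-supplied replacements for any surface, mirroring the usual practice
of visual confirmation after automatic segmentation.

**Numerical choices.** The gradient pre-smoothing default is
$\sigma = 0.7$ px. This was chosen by phantom study: the OPL is only
~10 µm (≈3 px at 3 µm axial pitch), and with $\sigma \geq 1$ the
overlapping edge responses of the INL/OPL and OPL/ONL boundaries bias the
weaker boundary by >1 µm, while at $\sigma = 0.7$ all per-layer biases
stay below 0.35 µm and the path search still absorbs noise up to
`noise_sd` = 0.05 (per-layer thickness error < 0.6 µm averaged over 20
noisy phantoms). A parabolic sub-pixel refinement (shift clamped to
±0.5 px) removes the half-pixel quantization bias. Thickness averages
follow the ETDRS convention: RNFL and GCL-IPL over the central 6-mm
circle, INL/OPL/total over the central 1-mm circle. Eyes with a central
subfield thickness ≥ 275 µm are excluded as macular edema (the threshold
is inclusive).

## OCTA quantification

En-face angiograms (3 × 3 mm, 304 × 304 px) pass a signal-strength gate
(SSI < 40 fails; the comparison is strict, so SSI = 40 passes), are
upsampled to 1024 × 1024 by bicubic interpolation (Catmull–Rom kernel,
$a=-0.5$), binarized, and skeletonized (Zhang–Suen thinning with a
junction cleanup pass that enforces a strictly one-pixel-wide result).

**Density definition.** Printed capillary densities in the 0.05–0.07
range are only consistent with *skeleton* density — centerline-pixel
count over region pixel count — not with the area fraction of the binary
mask (~0.3–0.5). `vessel_density()` therefore counts skeleton pixels in
the measurement annulus (2.5-mm outer diameter, 0.6-mm central exclusion)
and this choice is deliberately prominent in the documentation.

**Binarization.** The exact binarization of the original instrument
software is not recoverable; the package uses Frangi-style
Hessian-eigenvalue vesselness, averaged with the range-normalized
intensity, followed by Otsu global thresholding. Pure vesselness
suppresses junctions and thins vessels (it measures ridge-likeness, not
vesselness of the full caliber); averaging with intensity restores the
caliber while the vesselness term still suppresses background noise. On
noise-free phantoms with resolvable (2-px) vessels this reaches Dice
≥ 0.9 against the drawn mask.

**FAZ.** The foveal avascular zone is the avascular 4-connected component
containing the fovea after morphological closing of the vessel mask (disc
radius 2 px at 1024 resolution, configurable); its area is the pixel
count times the pixel area. If the fovea lands on a vessel pixel the
search expands to the nearest avascular pixel within 0.1 mm, else fails.

## The synthetic world

`generate_bscan()` renders piecewise-constant axial profiles for the five
layers (defaults at the healthy-control mean thicknesses: 28.46, 72.40,
17.52, 10.15 µm and a 110.93-µm outer retina) with anti-aliased
boundaries, optional Gaussian foveal pit (off by default so segmentation
tests isolate boundary-finding accuracy), and truncated additive Gaussian
noise. `generate_angiogram()` draws smooth random-walk capillary strokes
on the 1024 measurement grid until the centerline density inside the
annulus reaches the target, then dilates to the vessel caliber,
block-averages to 304 px and adds noise. Two features matter:

* a **terminal capillary ring** is drawn at the FAZ margin, as in real
  retinas; without it the measured FAZ leaks through inter-capillary gaps
  into the general avascular background;
* new strokes keep ≥ 2 px clearance from existing centerlines, because
  two merged parallel capillaries yield a single skeleton line and would
  bias measured density low by ~10–20%. Crossings remain possible.

Ground-truth skeleton density is defined on the 1024 grid (skeleton pixel
density is resolution-dependent, so truth must live at measurement
resolution). The generator fails loudly if the target is unreachable
(saturation) or missed by more than 10%.

`generate_cohort()` draws eye-level records for three groups (healthy
control, DR with normal BCVA, DR with decreased BCVA) at the published
group means/SDs, with a single shared per-participant Gaussian factor
scaled per parameter: value = mean + σ·(λ·z_subject + √(1−λ²)·z_eye).
The marginal SD is exact and the inter-eye intraclass correlation is λ².
The default λ = √0.5 (ICC 0.5) is a realistic inter-eye correlation for
macular OCT/OCTA measures. BCVA is generated from the published
multivariate linear predictor (intercept 0.575; age +0.002/yr; DRCP
vessel density −6.194; GCL-IPL −0.004/µm) with an optional centered
interaction term (−0.083) and an eye-level residual.

**Free choices and caveats.**

* `residual_sd` = 0.03 logMAR is not published anywhere; it was chosen
  once so that the control-group BCVA SD implied by the linear predictor
  (≈0.041 from the covariate spread) plus residual reproduces the
  published group SDs (0.05–0.06 logMAR).
* The linear predictor evaluated at the *decreased-BCVA* group means
  gives ≈0.03 logMAR, whereas that group's published mean BCVA is 0.12 —
  an internal tension of the published tables themselves (the regression
  was fit across all DR eyes, not within groups). The generator follows
  the regression model; consequently a generated "decreased" eye can
  realize logMAR ≤ 0. Analyses that need the BCVA dichotomy therefore
  derive it from the realized value (`bcva_logmar > 0`), matching the
  clinical definition, while `group` records the generative label.
* What a green test establishes: recovery of known geometry and
  coefficients under Gaussian noise and simple phantom structure. The
  generators deliberately do not model OCT speckle, flow-signal physics,
  projection artifacts, motion, or pathology (cysts, detachments), so
  green tests do not certify performance on real instrument data.

## Phenotype classification

The healthy-control sample mean and SD of each of the eight parameters
form the normative reference. A component flag fires when a value lies
*strictly* beyond mean ± 1.96 SD in its abnormal direction (below for
vessel densities and the neurodegeneration thicknesses, above for FAZ
area and the edema thicknesses); the strictness at exactly 1.96 SD is a
measure-zero decision fixed for determinism. Composites are fixed
disjunctions: ischemia = VD decrease (either plexus) OR FAZ increase;
neurodegeneration = RNFL OR GCL-IPL thinning; subclinical edema = INL OR
OPL OR total thickening. On pure control data each one-sided flag rate is
the 1.96-SD Gaussian tail, ≈2.5%, which the acceptance suite checks on
100,000 synthetic eyes.

Prevalence is reported with the Wald interval
$p \pm 1.96\sqrt{p(1-p)/n}$, clipped to [0, 100]% and rounded
half-away-from-zero to one decimal — the only common interval that
reproduces every published table cell including clipped "(0–…)" lower
bounds. Between-group tests use the two-sided Fisher exact test for 2×2
tables, computed by direct hypergeometric enumeration (the published
sparse-cell p-values 0.109/0.011/0.004 match the exact test, not the
asymptotic χ², even though the methods text says χ²; both are available
and the discrepancy is documented here). 2×k tables use Pearson's χ².

Note on the single-factor cohort design: with inter-parameter correlation
equal to the ICC (0.5), the *any-phenotype* rate on control eyes is ~15%,
not the ≤10% a naive union-of-tails sketch might suggest — eight 2.5%
tails union to 18% under independence and only approach 5% under perfect
correlation. The fixture test bounds this rate by its simulated
distribution rather than an optimistic closed form.

## Clustered statistics

Many participants contribute both eyes, so all regressions are Gaussian
identity-link generalized estimating equations (GEE) with an exchangeable
working correlation within participant and robust sandwich standard
errors; confidence intervals are estimate ± 1.96 SE throughout, and with
singleton clusters the estimates coincide with ordinary least squares
exactly (a unit-tested identity). The engine is written in the package
(no GEE dependency) and is fully vectorized via the Sherman–Morrison form
of the exchangeable inverse, with moment estimators for the scale and the
working correlation.

The modelling chain mirrors standard practice: univariate screening of
each predictor against BCVA (eye coded OD = 0/OS = 1; severity bands
coded ordinally 1–3 — both codings are unstated upstream and documented
choices here); significant predictors enter a multivariate model;
backward elimination at α = 0.05 removes the least significant term until
all retained terms are significant (the exact upstream selection
procedure is ambiguous; elimination is implied by predictors present at
screening but absent from the final model). The GCL-IPL × DRCP-density
interaction is added as a product of mean-centered predictors (centering
is a conditioning/interpretability choice; the centering constants are
exposed because coefficient recovery against a known generator requires
using the generator's constants). ROC cutoffs for visual impairment
(logMAR > 0) use the empirical ROC, trapezoid AUC (equal to the
Mann–Whitney U statistic over $n_1 n_0$, a tested identity), and
Youden's J for the optimal cutoff — the original cutoff criterion is not
recoverable, and Youden is the standard default.

## Pipeline and reproducibility

`run_pipeline()` chains quality gate → segmentation/quantification →
eye-table assembly → DME exclusion → phenotyping → statistics, writing
CSV/JSON outputs plus a provenance record (config, hash, seed, versions).
A single global seed fans out to per-stage seeds through a documented
splitting rule; identical configs reproduce byte-identical outputs. By
default the image stages quantify a small demonstration subset of eyes
(full-cohort image quantification is configurable but slow in plain R),
with the remaining eye records carried by the validated cohort table.
File-boundary images use ASCII PGM or CSV matrices — plain-text formats
chosen so the package has no binary-image dependencies.

## Known limitations

* Segmentation assumes the standard layer-contrast pattern of healthy
  and early-NPDR maculae; it has no pathology model.
* The vesselness parameters are tuned for capillary-scale vessels at
  1024-grid resolution; large retinal arcades would need different scales.
* The GEE engine covers the Gaussian identity case used here, not other
  families.
* The normative reference is the plain control mean ± 1.96 SD without
  age adjustment, matching the upstream definition.
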