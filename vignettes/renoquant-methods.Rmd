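---
title: "Methods: quantitation models, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitation models, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renoquant)
```

renoquant implements the quantitative measurements used to characterise
renoprotection in rat models of subclinical chronic kidney disease (sCKD)
with superimposed ischaemia–reperfusion injury (IRI): immunofluorescence
marker scores, power-Doppler relative blood volume, kidney functional
reserve and urinary biomarkers, qPCR relative expression, and the group
discrimination statistics built on top of them. Animal data of this kind
are rarely deposited, so the package ships a first-class synthetic-data
module that generates every input with known ground truth; all validation
is parameter-recovery on those simulations. This vignette records the
models, the tunable parameters, and the design decisions that were
genuinely open.

## Image model and background correction

A micrograph is a triple of channels — DAPI (nuclei), pancytokeratin
(tubular epithelium, the tissue-content reference) and a marker of
interest (RECA1, PGC-1α or COX4) — acquired with per-channel exposures
and corrupted by the camera model

    raw = clean × illumination + dark + noise.

`background_correct()` inverts this with the standard dark-frame /
flat-field estimator

    corrected = (raw − dark) / (flat − dark) × mean(flat − dark),

clamping negatives to zero. The literature this correction follows
describes "minor modifications" without printing a formula, so the
modification-free baseline above is adopted deliberately: it is exactly
invertible on the simulator's camera model, and its flat-field identity
(`raw = flat` → constant output) is one of the conservation checks.
The correction aborts, naming the offending pixel fraction, if
`flat − dark ≤ 0` on more than `tol_fraction` (default 0.1%) of pixels;
isolated non-positive pixels within tolerance are clamped to the smallest
positive denominator.

Thresholding defaults to an **exact Otsu**: the between-class variance is
maximised over *every* observed split point via sorted cumulative sums,
not over a 256-bin histogram. The study's own per-section manual
thresholds are irreproducible by definition; `method = "manual"` is
retained for fidelity and every threshold is recorded in the mask for
audit. Whether the study thresholded before or after correction is not
stated; the pipeline corrects first by default and records the choice
(`correct_first`).

Nucleus counting uses 8-connected components with a minimum area of
5 px — enough to suppress single-pixel noise without splitting simulated
nuclei. Touching nuclei merge and count once; there is deliberately no
watershed splitting, so the DAPI count is a conservative cell count.

## Marker scores

Three per-section scores are computed:

* **Normalised RECA1** = (lumen-filled RECA1 area fraction) /
  (pancytokeratin area fraction). The plain endothelial area fraction
  underestimates vascular volume because capillary lumina are unstained;
  `fill_lumina()` re-implements the published filling macro as bounded
  hole-filling: background components fully enclosed by the mask and no
  larger than `max_hole_area` (default 2000 px ≈ capillary lumen scale at
  400×) are added. The operation is monotone and idempotent, and is
  tested against an analytic annulus oracle. The "macro-corrected
  vascular area" is interpreted as an area *fraction*, so the score is
  dimensionless.
* **Nuclear PGC-1α** = [(total − cytoplasmic)/total] ×
  [pancytokeratin / DAPI count]. The cytoplasmic component is the marker
  mask minus the DAPI mask. The printed equation multiplies an area
  fraction by the reciprocal of a raw count; it is implemented verbatim,
  and the dimensionally clean first factor is exposed separately as
  `nuclear_share` — that factor (the nuclear co-localised share, in
  [0, 1] and scale-invariant) is what parameter-recovery tests target.
* **Normalised COX4**: identical arithmetic on the COX4 channel.

Scores are never compared across markers (exposures differ per marker);
all downstream comparisons are within-marker fold changes against the
global average of the vehicle group's sections, which makes the
vehicle-group mean fold exactly 1 under balanced section counts — an
exact conservation check. Per-animal aggregation is mean/SD/n over
available sections; missing sections reduce n and are never imputed.
Fibrosis and EGTI damage grades are human visual scores: the package
ingests them as data and computes only percentages
(`fibrosis_percent()`) and aggregates.

## Synthetic micrographs

`generate_micrograph()` emulates the staining geometry, not tissue
optics: nuclei are non-overlapping disks placed by rejection sampling
(erroring after 10,000 attempts so impossible geometries fail loudly);
the epithelium is a smooth random field thresholded at an exact area
quantile; vessels are rings with hollow lumina; and the marker channel is
a pixel point process with `round(f·A)` of its `A` pixels inside nuclei —
so the realised nuclear share equals the request up to one pixel of
rounding. The illumination field is a tilted plane plus one Gaussian
bump, strictly positive, range `illumination_gradient_amplitude`
(default 0.3, i.e. ±15% shading). Defaults — 256×256 px, 80 nuclei of
radius 5, 50% epithelium, stain/background contrast 800/50, dark offset
100, read noise SD 25 — are conventional fluorescence scales; the assay
constrains none of them, only the *ratios* the scores compute.

What the simulator does **not** model: point-spread blur, chromatic
aberration, autofluorescence texture, and stain heterogeneity. Because
edges are not blurred, a well-chosen threshold can classify pixels
exactly, and recovery on clean seeds can be error-free; the ±0.05
recovery band therefore demonstrates robustness to shading, offset and
read noise — not to optical blur. Passing tests show the *equations and
their inversion* are right, not that segmentation of real tissue is
solved.

## Doppler relative blood volume

A study is a stack of power-Doppler frames with per-frame kidney
delineations. Volumes are voxel sums (pixel area × slice thickness) with
no inter-frame interpolation — simple, auditable, and consistent with
frame-wise manual delineation; the simulated ellipsoid's voxel volume
agrees with (4/3)πabc within 2%. The vascular volume counts voxels above
a threshold *inside* the delineation (extrarenal clutter is ignored by
construction, and the simulator plants some to prove it). The acquisition
threshold is not stated in the source protocol, so the default is Otsu on
the within-kidney intensities, recorded in the output and overridable.
rBV = 100 × vascular/kidney is aggregated at the volume level (ratio of
summed volumes); per-frame percentages and their mean are also emitted
because vendor "percent vascularity" may aggregate frame-wise. rBV is
bounded in [0, 100], invariant to uniform pixel-size rescaling, and
monotone in the threshold; recovery of 1/5/15% targets is within half a
percentage point at the default noise (signal 100, noise SD 8).

## Physiology

Kidney functional reserve is stimulated minus unstimulated GFR
(mL/min); negative values are retained and flagged, not clamped, since a
kidney without recruitable reserve is exactly the state of interest.
Creatinine clearance is the standard UV/P with explicitly declared units
(urinary creatinine mmol/L, serum µmol/L by default) — no silent unit
guessing; the timed-collection helper requires the interval with no
default. Urinary biomarkers (uKIM-1, clusterin) are normalised to
urinary creatinine.

## qPCR relative expression

`relative_expression()` implements 2^−ΔΔCt with dual housekeeping genes
(ACTB + PABPN1 for RNA; NDUFV1 + UBC for the mitochondrial DNA copy
assay). The geometric mean of housekeeping quantities is computed as the
arithmetic mean of their Cts — an exact identity under the 2^−Ct
transform, verified numerically to 1e−12 in the tests. Reference-group
centring uses the arithmetic mean of reference ΔCts (the common
convention), which forces the reference group's fold changes to have
geometric mean exactly 1. Amplification efficiency is fixed at 2.0
(assays verified in the 90–110% band use the plain 2^−ΔΔCt form) and
replicates are averaged with no outlier rejection. Samples missing a
housekeeping Ct are excluded with a logged reason, never imputed. The
simulator adds a per-sample Ct shift shared by all genes (loading/RT
efficiency) that housekeeping normalisation must cancel exactly — which
it does, making noiseless recovery exact to machine precision.

## Discrimination statistics

`pearson_screen()` applies the screening rule r > 0.2 and p < 0.05
verbatim — note it is one-sided in r, so perfect negative correlations
are *not* flagged; this asymmetry is preserved intentionally.

`fit_logistic()` is maximum-likelihood logistic regression on
internally standardised features. With group effects as large as this
design produces, complete separation is the expected regime; rather than
reporting divergent coefficients the fit rescales the slope vector to a
bounded L2 norm (default 10 on the standardised scale) and flags
`separable` — score rankings, and hence AUC, are unaffected.

`fit_lasso_logistic()` (via glmnet) fits the L1 path over a log-spaced
penalty grid and selects the penalty by leave-one-out cross-validated
binomial deviance — the selection rule is not stated in the source
protocol, and LOO is the defensible choice at n = 24; the selected
penalty is reported. The unpenalised limit agrees with the plain fit to
1e−4 on non-separable data, and the infinite-penalty limit collapses to
AUC 0.5 (both tested).

AUC is the Mann–Whitney ranking probability with ties counted ½,
verified against an exhaustive pair-count oracle; the 95% CI is a
class-stratified percentile bootstrap with a fixed seed (the CI method in
the source protocol is unstated). Univariable AUCs computed from fitted
probabilities equal those from the raw feature, since a monotone 1-D
model preserves ranking. Mixed-model/Tukey group testing is routine
statistics outside this package's scope.

## Synthetic cohort and the discrimination benchmark

`generate_cohort()` draws per-animal values from group × timepoint
normal distributions covering the five-arm design (sham + vehicle,
IRI + vehicle, IRI + NR, IRI + SkQR1, IRI + both; n = 6 per arm; days 0,
56, 57, 63, 98). The default effect table encodes the qualitative course:
all arms share an sCKD baseline at day 56; IRI arms crash acutely at day
57; vehicle animals retain a chronic deficit at day 98 (KFR ≈ 0.08 vs
0.35–0.40 mL/min treated, rBV ≈ 13% vs 23–25%, uKIM-1 ≈ 7 vs
1.6–2 ng/mL) while treated arms largely recover. Those gaps are 2.5–5
within-group SDs — deliberately large, matching a design whose reported
discrimination was essentially perfect; the discrimination benchmark
(vehicle vs treated at day 98, n = 6 vs 18, features uKIM-1/uCr,
uCLU/uCr, KFR, rBV) asks the LASSO model to reach AUC ≥ 0.95, a
qualitative reproduction of that pattern, not of any printed number.

## Determinism and the pipeline

Every generator is a pure function of (params, seed): randomness is
scoped with a save/restore of the caller's RNG state, so generation
never perturbs the session stream. `run_pipeline()` executes stages in
dependency order, derives stage seeds from the run seed, echoes every
applied default into `manifest.json` alongside md5 hashes of all
outputs, and is byte-identical across reruns — tested by hashing two
complete runs. The default pipeline configuration is demonstration-
scaled (2 animals × 2 markers × 2 sections of 128×128 px, an 8-frame
Doppler stack); recovery validation uses the full 256×256 defaults, and
the vignette-stated sizes are the package's own choices for a
desk-reproducible analysis.

## Known limitations

* The simulators validate equations and inversion, not segmentation of
  real histology (no blur, no texture, no stain variability).
* The nuclear score's mixed units (fraction ÷ count) follow the printed
  equation; cross-study comparability rests on the `nuclear_share`
  factor, which is the clean quantity.
* Only two-class discrimination is supported; the multi-arm design is
  analysed as vehicle vs treated.
* Doppler rBV is threshold-based; no velocity estimation, gating or
  attenuation correction is attempted.
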