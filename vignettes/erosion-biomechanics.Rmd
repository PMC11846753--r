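---
title: "Plaque-erosion biomechanics: models, surrogates and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plaque-erosion biomechanics: models, surrogates and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemech)
```

## The problem

Plaque erosion is an acute-coronary-syndrome mechanism in which the fibrous
cap stays intact but the endothelium is lost and a (typically white,
platelet-rich) thrombus forms on the plaque surface. Unlike plaque rupture
it tends to occur over less stenotic lesions, and its biomechanical
signature — the combination of flow shear stress on the lumen, wall stress
and strain in the plaque, and morphology (cap thickness, plaque burden,
stenosis) — is poorly characterized. `plaquemech` implements a desk-scale
version of the comparison-and-prediction analysis for cohorts of eroded and
non-eroded plaques: contour processing from segmented intravascular imaging
frames, biomechanical surrogates for the wall and the flow, group and
erosion-site statistics, and a logistic-regression prediction framework
evaluated by leave-one-out cross-validation inside a bootstrap.

The package ships a transcription of a 16-patient cohort (eight eroded,
eight non-eroded plaques) as per-patient fixture tables
(`load_fixture()`), and a synthetic-cohort generator so that every stage is
testable without patient data.

## Geometry processing

Cross-sections are closed planar polygons in mm (`contour_slice()`):
lumen, outer boundary (external elastic membrane), and optional lipid,
calcification and thrombus contours, stacked at 0.2 cm spacing along the
vessel (`vessel_geometry()`).

* **Thrombus removal** (`remove_thrombus()`): erosion analysis needs the
  pre-erosion lumen, so white thrombi are deleted and the lumen line is
  recovered as the union of the segmented lumen and the thrombus footprint
  (per-angle maximum radius about the lumen centroid), followed by a
  5-point circumferential moving-average smoothing restricted to the
  recovered arc. The operation never shrinks the lumen.
* **Lipid trailing edge** (`complete_lipid_trailing_edge()`): imaging
  signal attenuates behind the lipid leading edge; the core is closed by
  assuming lipid occupies two-thirds of the wall space behind the leading
  edge along each outward ray.
* **Outer-boundary completion** (`interpolate_outer_boundary()`): missing
  angular arcs are filled by per-angle linear interpolation of radius
  between the nearest flanking slices (copied from the single neighbor at
  the stack ends), on the assumption that the outer boundary varies
  continuously along the vessel.
* **Four-quarter-even-spacing** (`resample_four_quarter()`): each lumen is
  reduced to 100 points — the boundary is cut where it crosses the four
  axis rays from a reference center and each quarter receives 25 points
  evenly spaced by arc length. The center defaults to the polygon's area
  centroid and is cached on the result, which makes repeated resampling an
  exact no-op. Contours are assumed star-shaped about the center, which
  also makes ray-based wall and cap thickness well defined.

Morphology metrics are area stenosis (`1 - min lumen area / reference
lumen area`, the reference being the largest lumen area proximal to the
minimum-area slice, falling back to the first slice when the minimum is
proximal-most), plaque burden (`1 - lumen area / wall area`), and cap
thickness (lumen point to lipid leading edge along the outward ray).
Patient-level cap statistics pool all cap points across slices rather than
averaging per-slice summaries; with near-uniform point counts per slice
the two conventions differ little, and pooling keeps thin-cap points from
being diluted on slices with small lipid arcs.

## Materials

Tissue behavior is modified Mooney-Rivlin hyperelasticity. The vessel wall
uses the anisotropic form with an exponential fiber term along the
circumferential direction,

$$W = c_1(I_1-3) + c_2(I_2-3) + D_1[e^{D_2(I_1-3)}-1] +
\frac{K_1}{K_2}\{e^{K_2(I_4-1)^2}-1\},$$

with $I_4 = n_c^T C\, n_c$; lipid and calcification are isotropic
($K_1 = 0$). Defaults (kPa): vessel $(-515.6,\ 45.05,\ 247.3,\ 2.0,\
14.1,\ 23.5)$, lipid $(0.5, 0, 0.5, 1.5)$, calcification
$(920, 0, 360, 2.0)$ — literature values for coronary tissue; the negative
vessel $c_1$ is dominated by the exponential isotropic term so the
stress–stretch response is monotone stiffening (`plot_stress_stretch()`).
Parameter sets are loadable from YAML (`read_material_config()`); the
shipped config records the parsing assumptions alongside the numbers.

Incompressibility is handled exactly through a pressure multiplier fixed
by a traction-free direction (homogeneous states) or the radial boundary
condition (tube solver) rather than a penalty formulation; this keeps the
closed-form test oracles (neo-Hookean uniaxial stress, Laplace limit)
valid. Stresses are in kPa; shear stresses are reported in dyn/cm²
(1 dyn/cm² = 0.1 Pa); pressures convert at 1 mmHg = 0.1333 kPa.

## The structural surrogate

The full 3D fluid–structure interaction problem is out of scope; the wall
stress/strain fields are produced by a documented quasi-static surrogate:
each lumen point is treated as belonging to an equivalent incompressible
hyperelastic thick-walled tube with that point's local zero-load radius
and wall thickness. `inflate_tube()` solves the inflation–extension
problem by root bracketing on the equilibrium pressure integral
$p = \int_{r_i}^{r_o} (\sigma_{\theta\theta}-\sigma_{rr})/r\,dr$ (48-point
Gauss–Legendre inside the root solve; the converged state's residual is
re-verified with adaptive quadrature against a 1e-6 kPa tolerance). The
lumen-surface maximum principal Cauchy stress and Green–Lagrange strain
become PWS and PWSn. Points backed by a lipid core use a two-layer
composite collapsed to one equivalent material with thickness-weighted
parameters (cap = vessel, core = lipid). This surrogate preserves the
metrics' dependence on pressure, radius, thickness and material — the
properties the acceptance suite checks (Laplace thin-wall limit,
monotonicity in pressure and thickness) — but not 3D bending, axial
tapering or stress concentrations at component boundaries.

The **preshrink** step (`apply_preshrink()`) recovers a zero-load state
from in vivo contours: 5% axial shrink for every slice, and a per-slice
circumferential shrink found by root bracketing in $s \in [0, 0.3]$ so
that re-pressurizing the shrunken slice recovers the in vivo lumen area
within 0.5% (the tolerance is the package's choice; the procedure itself
only requires "iterative matching"). Surface values are extracted at the
lumen; through-thickness maxima would differ only for the radial-stress
dominated regime that thin coronary walls do not reach.

**Time points.** Fields are evaluated quasi-statically at the times of
maximum and minimum inlet pressure of the waveform; a transient
multi-cycle solve is out of scope. ΔFSS is the pointwise FSS difference
between the two time points, aggregated per patient after the pointwise
difference (the per-location definition), not as a difference of
aggregates.

## The flow surrogate

`slice_fss()` uses the Poiseuille base shear on the equivalent circle,
$\bar\tau = 4\mu q/(\pi r_{eq}^3)$ with $r_{eq} = \sqrt{A/\pi}$, modulated
per lumen point by $(r_{eq}/\rho_i)$ where $\rho_i$ is the local
centroid-to-point radius, so stenotic slices and locally narrow sectors
see elevated shear. Blood is treated as laminar and Newtonian with the
standard values $\mu = 0.035$ dyn·s/cm² (3.5 cP) and
$\rho = 1.05$ g/cm³. The
minimum-pressure FSS is evaluated at the time of minimum inlet pressure
(not minimum flow). No recirculation, oscillatory shear index or branch
effects are represented.

Waveforms (`make_waveform()`) rescale a smooth pulse shape to the
patient's arm-cuff systolic/diastolic values exactly, with a
diastolic-dominant nonnegative coronary flow profile; extrema times are
found by dense sampling plus local refinement.

## Statistics

Group comparisons (`group_summary()`) report per-group mean ± SD (n−1)
and the relative difference `(eroded − non-eroded)/non-eroded × 100%`.
Normality screening uses a one-sample Kolmogorov–Smirnov test against a
moment-fitted normal; group differences use the Wilcoxon rank-sum test
and the paired site comparisons the signed-rank test, both with exactly
enumerated small-sample null distributions (`wilcoxon_test()`): all
$2^n$ sign patterns (paired) or all $\binom{n_1+n_2}{n_1}$ labelings
(unpaired), midranks for ties, two-sided p doubling the smaller tail.
For eight paired patients with a uniform sign this yields
$p = 2/2^8 = 0.0078125$. `summarize_site_table()` reports the paired
exact test as primary — it is the test whose value the printed site
tables carry — with the unpaired rank-sum alongside.

Table reproduction uses half-away-from-zero rounding to the printed
decimals.

## Prediction framework

Thirteen predictors (max/mean PWS, max/mean PWSn, max/mean FSS, max/mean
ΔFSS, mean plaque burden, area stenosis, min/mean cap thickness, mean
lumen area) feed 1–3-predictor logistic models: 13 + 78 + 286 = 377
subsets (`enumerate_models()`), with an optional conservative screen that
drops any multi-predictor model containing a pair with Pearson
correlation p < 0.05, computed once on the full table.

The fit (`fit_logistic()`) standardizes predictors by the training fold's
mean/SD and runs iteratively reweighted least squares with a ridge term
$\lambda = 10^{-4}$ on the standardized coefficients — at 16 patients
complete separation is routine, and the small ridge guarantees a unique,
deterministic optimum while leaving the ranking of predicted scores
essentially untouched.

Evaluation couples leave-one-out cross-validation with the bootstrap:
each of the (default 100) replicates resamples n patients with
replacement (redrawn if single-class, count logged), runs LOO inside the
replicate, and scores the replicate by AUC; the report is the AUC
average, the 5th–95th percentile (90%) interval, and the ROC of the
cumulated score/label pairs (`bootstrap_evaluate()`, `rank_models()`).
Percentile intervals were chosen over basic/BCa for transparency at 100
replicates.

**Score comparability across folds.** Raw out-of-fold probabilities are
not rank-comparable across LOO folds: removing a positive patient lowers
that fold's training prevalence, which systematically depresses the
held-out positive's probability. At n = 16 this intercept shift dominates
weak predictors and drags cross-validated AUC far below 0.5 even under
label permutation. `loo_predict()` therefore also returns
prevalence-centered logit scores,
$\mathrm{logit}(p_i) - \mathrm{logit}(\bar y_{-i})$, and the
bootstrap/ranking machinery computes AUC from these. The centering is
strictly out-of-sample, leaves single-model rankings unchanged, and
restores null calibration (permutation AUC ≈ 0.5). Probabilities are
still reported for interpretation.

## The synthetic cohort

`generate_predictor_cohort()` draws per-patient predictor vectors from
per-group truncated normals; the defaults for the eleven predictors with
published group statistics are those groups' mean ± SD, truncated at
physical floors (nonnegative stresses, shear and thicknesses; fractions
and strains in (0, 1)). Only marginal summaries are published, so
predictors are independent by default; a Gaussian-copula correlation
matrix is exposed for testing the correlation screen. Two quantities have
no published per-patient values and carry package-chosen defaults, sized
relative to their parent FSS distributions and to the reported ordering
of predictive strength: max ΔFSS 90 ± 30 vs 40 ± 25 dyn/cm², mean ΔFSS
35 ± 15 vs 17 ± 12 dyn/cm², and mean lumen area 4.5 ± 1.5 vs
5.5 ± 1.8 mm² (eroded lesions being the more stenotic group). The
`effect_scale` knob scales the between-group mean differences about the
pooled mean; 0 gives a null cohort.

`generate_contour_patient()` builds slice stacks of perturbed ellipses
sharing one angular shape, so lumen areas scale exactly with the squared
per-slice radius factor and the focal narrowing hits the requested area
stenosis by construction; the wall thickens and a lipid pool (optional)
appears under the lesion; eroded patients get a thrombus overlying a
contiguous ~60° sector of the narrowest slice, and exactly those lumen
points are erosion-labeled. What the generator does *not* emulate: raw
imaging speckle, segmentation error, red-thrombus shadowing,
inter-predictor correlation structure, and any real covariance between
morphology and mechanics — so passing tests demonstrate the pipeline's
internal consistency, not clinical validity on real cohorts.

## Problem sizes and numerical choices

Routine runs use what a laptop handles in seconds to minutes: 100 lumen
points per slice, 5–10 slices per synthetic patient, 100 bootstrap
replicates, 20–50 seeds for calibration experiments. The parameter-
recovery experiment uses 24 patients per group: at the configured
standardized effect (~1.3, population AUC ≈ 0.82) the Hanley–McNeil AUC
standard error at 24 + 24 is ≈ 0.06, so recovery above 0.7 reflects the
generator rather than cohort sampling noise — at 8 + 8 the cohort-level
AUC itself fluctuates with SD ≈ 0.11 and no estimator can recover the
effect reliably. Null calibration, by contrast, is run at the study's own
8 + 8 size.

Other numerical choices: tube root solve bracketed in deformed inner
radius with expansion up to 1.5^12 × the zero-load radius before
reporting non-convergence; exponential overflow guarded at $e^{700}$ with
an error naming the stretch; degenerate polygons (area ≈ 0) rejected;
ties in the exact tests midranked; bisection/`uniroot` tolerances 1e-6
(preshrink shrink fraction) and 1e-12 (tube radius).

## Limitations

The structural and flow surrogates are one-dimensional equilibrium
models; they preserve parameter dependence, not field structure. No
residual circumferential stress or opening angle, no cyclic bending, no
adventitia, no patient-specific material parameters, no side branches.
The fixture cohort is 16 patients; every AUC is specific to it and the
bootstrap intervals say nothing about population-level accuracy. The
synthetic defaults cannot reproduce the published multi-predictor AUC
ranking exactly because inter-predictor correlations were never
published.
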