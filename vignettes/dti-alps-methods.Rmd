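---
title: "DTI-ALPS: model, phantoms and reliability statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTI-ALPS: model, phantoms and reliability statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtialps)
```

## The ALPS model

Diffusion tensor image analysis along the perivascular space (DTI-ALPS)
proxies glymphatic transport from a standard diffusion MRI scan. At the
level of the lateral-ventricle body, perivascular spaces follow the
medullary veins and run right–left (the anatomical x axis). In the same
axial plane, projection fibers (superior corona radiata) run
inferior–superior (z) and association fibers (superior longitudinal
fasciculus) run anterior–posterior (y) — both orthogonal to the
perivascular direction. Water mobility *along x* inside those two fiber
regions therefore isolates the perivascular contribution: diffusion along
the fibers' own axes is dominated by axonal geometry, but x-axis diffusion
within them has no axonal pathway and is attributed to the perivascular
compartment.

With `Dxx`, `Dyy`, `Dzz` the *diagonal elements of the diffusion tensor in
the anatomical frame* (not eigenvalues), averaged over a projection-fiber
ROI (`proj`) and an association-fiber ROI (`assoc`):

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx}^{proj}, D_{xx}^{assoc})}
                       {\mathrm{mean}(D_{yy}^{proj}, D_{zz}^{assoc})}$$

Each hemisphere is computed independently and the reported ALPS index is
the average of the two. An index near 1 means no preferential perivascular
diffusion; larger values indicate freer transport. The model assumes
single-fiber voxels with axes aligned to the anatomical grid — which is why
volumes are reoriented to RAS before fitting and why the diagonal elements
must not be replaced by eigenvalues.

## Tensor estimation

`fit_tensor()` solves the log-linear model
$\ln(S_i/S_0) = -b_i\, g_i^\top D\, g_i$ per voxel in the standard
6-element design ($[g_x^2, g_y^2, g_z^2, 2g_xg_y, 2g_xg_z, 2g_yg_z]\,b$).
Choices that matter:

* **S0** is the geometric mean of the b=0 volumes.
* **OLS vs WLS.** Both estimators are available. The published pipelines do
  not state which estimator their tools used, so this package defaults to
  one-pass weighted least squares (weights = squared OLS-predicted
  signals), the common `dtifit`-style choice; on noise-free data both are
  identical to machine precision (asserted in the tests).
* **Clamping.** Signals are clamped at $10^{-6} S_0$ before the log;
  affected voxels are flagged. This keeps the fit defined under noise
  without biasing bright voxels.
* **Degenerate fits.** Voxels with negative eigenvalues are retained but
  flagged; ROI extraction reports the flagged fraction and warns above
  50%.
* No brain masking is applied beyond an S0 threshold; the ROI analysis
  does its own spatial selection.

## ROI presets and geometry

Two published ROI sets are built in, with printed centers stored verbatim:

* `DSI_DEFAULT`: projection (53,47,40)/(25,47,40), association
  (59,47,40)/(19,47,40); spheres of 12-voxel diameter.
* `FSL_DEFAULT`: SCR (116,110,99)/(64,110,99), SLF (128,110,99)/(51,110,99)
  on the 182×218×182 1 mm atlas grid; 5 mm diameter spheres.

Open conventions were resolved as follows, with switches where users may
disagree:

* Printed coordinates are **0-based voxel indices** by default
  (`index_base = 1` converts from 1-based).
* The "12 pixel" diameter is taken as the operational definition (the GUI
  procedure counts pixels); its physical size follows from the grid's
  voxel size. The phantom template for this preset uses 2 mm isotropic
  voxels on a 78³ grid covering the printed coordinates.
* Sphere membership is **center-in-sphere** (voxel center within
  diameter/2 in physical mm), with no partial-volume weighting — the
  simplest deterministic rule and the one typical ROI tooling applies.
  Mask cardinalities are verified against brute-force enumeration (a 5 mm
  sphere on a 1 mm grid contains exactly 81 voxels).

## The phantom

`phantom_spec()`/`build_tensor_field()` generate a diagonal tensor field on
the analysis grid directly (inputs are assumed pre-registered, so no
registration stage exists to simulate): an isotropic background
(0.7×10⁻³ mm²/s), axis-aligned fiber slabs mirrored across the midline,
and a multiplicative **perivascular gain g** on the x-diffusivity inside
the slabs. Projection slabs carry diag(gλ⊥, λ⊥, λ∥), association slabs
diag(gλ⊥, λ∥, λ⊥). The analytic ALPS index of the noise-free phantom is
exactly *g*, which anchors the package's strongest test: the full
simulate → fit → ALPS chain must return *g* to 1 part in 10⁹.

Parameter defaults are realistic white-matter values chosen once:
λ∥ = 1.7×10⁻³ mm²/s, λ⊥ = 0.4×10⁻³ mm²/s, gains in [1, 2]. The published
protocol fixes the acquisition: 6 b=0 volumes plus 40 directions at
b = 1000 s/mm², 2 mm isotropic; directions are spread deterministically on
the sphere with a Fibonacci lattice. Noise is **Rician** in the
magnitude-signal convention, σ = s0/SNR, and every draw is
seed-deterministic.

Two geometric details are deliberate:

* On the 2 mm DSI grid, 12-voxel spheres at the printed projection and
  association centers (6 voxels apart) overlap each other's slab. Overlap
  voxels take the element-wise minimum of the two prescriptions,
  diag(gλ⊥, λ⊥, λ⊥) — a perivascular-core tensor. Both numerator
  (Dxx = gλ⊥ everywhere in the slab union) and denominator (λ⊥) stay pure,
  so the analytic index remains exactly g.
* The FSL preset's 1 mm template is cropped to a 17-slice slab around the
  ROI plane (z = 99, recorded as a grid `origin` offset); everything
  outside is background and would only add runtime.

What the phantom does **not** emulate: susceptibility distortion, eddy
currents, motion, Gibbs ringing, spatially correlated noise, fiber
crossing or dispersion, and partial-volume anatomy. Passing phantom tests
therefore demonstrates correctness of the estimator and the index
arithmetic under the ALPS model's own assumptions — not robustness to
acquisition artifacts, which the upstream corrections (TOPUP/EDDY,
denoising) are responsible for.

## Cohort simulation

`simulate_cohort()` injects scanner/session structure **on the ALPS
scale**: subject i draws a latent gain $g_i \sim N(g_0, \sigma_s)$, and
measurement j realizes $g_i + b_j + \varepsilon_{ij}$,
$\varepsilon \sim N(0, \sigma_e)$ with fixed per-measurement offsets
$b_j$. Implementing scanner effects as gain adjustments (rather than
image-domain artifacts) keeps the implied agreement ICC analytic,

$$\rho = \frac{\sigma_s^2}{\sigma_s^2 + \mathrm{var}(b) + \sigma_e^2},$$

where $\mathrm{var}(b)$ uses the (k−1) denominator — the quantity the
column mean square estimates under fixed offsets. Draws below a floor
(default 0.05) are clipped and counted. Image synthesis (one phantom per
cell whose analytic ALPS equals the target) is opt-in, since the
reliability statistics only need the table.

## Reliability statistics

`anova_decompose()` computes the two-way mean squares; both ICC forms are
single-measure, two-way random effects:

* consistency: $(MS_R - MS_E) / (MS_R + (k-1) MS_E)$ — used for
  inter-scanner reproducibility;
* absolute agreement:
  $(MS_R - MS_E) / (MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$ — used
  for inter-rater reliability and test-retest repeatability.

Confidence intervals follow McGraw & Wong (1996): exact F-based bounds for
the consistency form; the Satterthwaite-df procedure for agreement. The
p-value is the one-sided test of ICC > 0 via $F = MS_R/MS_E$ on
$(n-1), (n-1)(k-1)$ df, matching conventional "P < 0.001" reporting. The
implementation is cross-checked in the tests against brute-force
sum-of-squares computation, base R's `aov()`, and frozen values from an
independent reference implementation.

Edge cases: constant matrices are reported as degenerate (ICC undefined);
`MS_E = 0` with subject variance yields ICC 1 with interval [1, 1];
incomplete rows are removed listwise with a logged count, never imputed.

Interpretation bands use half-open intervals — poor < 0.5 ≤ moderate
< 0.75 ≤ good < 0.9 ≤ excellent — because the conventional "between"
phrasing is ambiguous at the boundaries; 0.9 itself maps to excellent.
Bland–Altman analysis uses the sample (n−1) SD and the 1.96 multiplier
with no repeated-measures correction.

`validation_report()` binds these together per study design: consistency
ICC for `inter_scanner`, absolute agreement for `inter_rater` and
`test_retest`, with overall and pairwise estimates, bands and
Bland–Altman statistics per measurement pair. Whether inter-rater ICCs are
computed pooled across scanners or per scanner is up to the caller — the
function takes whatever long-format slice it is given.

## Numerical verification sizes

The test suite exercises: full-grid closure phantoms (78³ DSI, 182×218×17
FSL slab) at gains {1, 1.25, 1.5, 2}; 1000 random positive-definite
tensors for exact inversion (< 10⁻¹² relative) and the trace identity;
20 SNR-20 phantoms on a 40×40×13 grid (ALPS within 5% of truth in ≥ 90%);
ICC recovery at n = 200, k = 4 over 50 seeds for designed ρ ∈
{0.5, 0.75, 0.9} (median within ±0.03) and 95% CI coverage at n = 15,
k = 4, ρ = 0.9 over 1000 cohorts (93–97%). Cohort sizes for the ICC
simulations use a total ALPS SD of 0.2, a realistic between-plus-within
spread for this index.

## Known limitations

* ROI placement is template-based only; no SWI-guided vein localization,
  no per-subject warping, no manual adjustment.
* Single-shell tensor model only; no multi-shell or non-Gaussian models.
* The phantom's fiber slabs are axis-aligned boxes — adequate for
  validating the index arithmetic, not a realistic anatomy simulator.
* Preprocessing (distortion/eddy/motion correction, denoising) is out of
  scope; inputs are assumed corrected and registered.
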