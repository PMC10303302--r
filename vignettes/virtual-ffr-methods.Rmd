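---
title: "Methods: virtual FFR from lumen geometry and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual FFR from lumen geometry and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vffr)
```

## Scope and assumptions

`vffr` estimates fractional flow reserve — the ratio of mean distal
coronary pressure to mean aortic pressure under maximal hyperemia — from a
one-dimensional description of the vessel: the lumen cross-sectional area
A(s) along the centerline arc-length s. Everything upstream of that profile
(polar-image segmentation, ECG gating, pullback mapping) and everything
downstream (pressure-drop modelling, FFR, diagnostic evaluation) is
implemented here; full 3D reconstruction and 3D CFD are out of scope by
design. The physical assumptions are the standard ones of reduced-order
coronary hemodynamics:

* steady flow at a fixed hyperemic rate Q, conserved along the segment
  (side branches are ignored — the model applies to a main epicardial
  vessel between branch points);
* circular-equivalent cross-sections, d = 2√(A/π), since IVUS areas are
  the primitive measurement;
* fully developed Poiseuille friction locally, plus irreversible
  Borda–Carnot losses where the lumen expands;
* rigid walls, Newtonian blood (μ = 0.0035 Pa·s, ρ = 1060 kg/m³ by
  default).

## Geometry

The reference ("healthy") vessel dimension is a straight line fitted by
ordinary least squares through the diameters of the non-diseased samples;
the lesion is excluded from the fit via an interval argument, and
`detect_lesion()` delimits that interval as the maximal contiguous run of
samples whose pointwise diameter stenosis against the current reference
exceeds a threshold (default 20%), seeded at the deepest relative
narrowing. Seeding at maximum pointwise DS% rather than minimum absolute
diameter makes the choice correct for tapered vessels, where the distal
lumen is smallest even when healthy. Over which proximal segment the
reference slope should be fitted is genuinely open; it is exposed as
configuration (`lesion_exclusion`) rather than hard-coded.

From the profile, the reference line and the lesion interval,
`stenosis_metrics()` reports MLA, MLD, RVD/RVA at the MLA position, DS%,
AS%, and plaque burden when EEM areas are present. For circular
cross-sections AS% = 100·(1 − (1 − DS%/100)²) holds exactly and is used as
a consistency test. If the fitted reference falls at or below the minimum
lumen diameter — a symptom of a bad fit, not of disease — DS% is clamped
at zero with a warning rather than reported negative.

All hemodynamic computations resample the profile to a uniform 0.1 mm
grid. That resolution was chosen once for the whole package: it is finer
than any clinical pullback spacing, and halving it changes FFR by less
than 0.005 on smooth moderate lesions (see "Numerical behaviour").

## Segmentation stand-in

The lumen boundary on a polar cross-section image (rows = angle bins,
columns = radius bins, dark lumen / bright wall) is traced as a
minimum-cost closed path visiting one radius per angle. The node cost is
the negative outward radial intensity gradient, so strong dark-to-bright
edges are cheap; a small curvature penalty (1% of the maximum gradient per
bin of radial jump) discourages jagged paths; radial jumps between
adjacent angles are limited to ±2 bins including the wrap-around pair.
Because the graph is ordered by angle, the path is solved exactly by
dynamic programming — the deterministic equivalent of running Dijkstra on
this DAG. Closure is enforced by solving once per candidate start radius
(every 2 bins) and keeping the cheapest closed path, ties broken toward
the smaller radius. A frame with no gradient structure (flat image) raises
a typed "unsegmentable" error instead of returning an arbitrary contour.

Contour area uses the polar rule A = ½·Σ r_i²·Δθ, exact for constant
radius. ECG gating picks, for each R wave, the frame nearest to the R-wave
time minus an end-diastole offset (default 0: the R-wave frame is the
end-diastolic proxy); frame indices are 0-based, and uniform motorized
pullback maps frame k to arc-length k·speed/rate, re-zeroed at the first
gated frame.

## Hemodynamics

Hyperemic velocity follows the diameter-squared law v = k·d_ref². The law
fixes only the exponent; the constant is physiological calibration, and
the default k = 0.0389 m s⁻¹ mm⁻² makes a 3.0 mm reference vessel run at
0.35 m/s, a typical adenosine-hyperemia velocity. A frame-count transit
mode (v = length / transit time) and a fixed-Q mode are provided; in all
modes Q = v·A_ref with A_ref the reference area at the proximal end.

The reduced-order pressure drop accumulates two non-negative terms per
0.1 mm interval:

* viscous: dP_v = 8πμQ/A² · ds (trapezoid rule on 1/A²);
* expansion: dP_e = k_e·(ρ/2)·Q²·(1/A_in − 1/A_out)² on every interval
  where the area increases, with k_e = 1 (full Borda–Carnot) by default.

Contractions are loss-free apart from viscosity — the standard
reduced-order convention, since converging flow stays attached.
All arithmetic is SI internally; conversion to mmHg (÷ 133.322) happens
only at the field boundary. FFR(s) = (Pa − ΔP(s))/Pa with Pa = 90 mmHg by
default (mean aortic pressure is patient-specific in practice and is a
parameter here). If the drop at the measurement point reaches Pa, the
constant-flow assumption has left its validity region and a typed
"non-physical" error is raised rather than a clamped value.

The 1D finite-volume solver discretizes the steady area-averaged momentum
balance over uniform cells: the same Poiseuille friction, plus the
convective term ρQ²·d(1/A)/ds integrated exactly across each face, with
pressure recovery on expanding faces limited by the same energy-loss
coefficient. The two engines therefore share one physical contract and
differ only in whether the reversible kinetic-energy exchange is carried:
the solver's field shows the physical throat dip and partial distal
recovery, while the reduced-order field is monotone by construction. At a
matched distal area the convective contribution telescopes away, which is
why the engines agree to ~0.001 FFR on the 20-lesion fixture library
(DS 30–80%, lengths 5–25 mm) used in the tests.

### Numerical behaviour

Applying the Borda–Carnot increment per grid interval makes the expansion
loss of a *smooth* taper vanish as the grid is refined (the sum of squared
increments is O(ds)), which is physically right — a gradual diffuser
recovers pressure almost fully — and makes an *abrupt* step carry the full
loss in its single interval. The consequence is that the expansion term is
grid-dependent in the regime between those limits: severe smooth lesions
at coarse grids attribute more loss to expansion than at fine grids. At
the package's fixed 0.1 mm resolution this effect is below 0.005 FFR for
lesions up to ~60% DS, which is where the grid-invariance property is
asserted; both engines are run at matched resolution so their interface
losses coincide. The finite-volume solver's observed convergence order on
smooth stenoses is ≈1, dominated by exactly this first-order expansion
term (friction converges at second order and the convective term
telescopes exactly).

## Diagnostic evaluation layer

Positivity is defined on the invasive side as FFR ≤ 0.80, and an index
calls disease when its value is ≤ the cutoff (lower index ⇒ more severe).
From a confusion matrix, `diagnostic_indices()` reports accuracy,
sensitivity, specificity, PPV, NPV, likelihood ratios, the Youden index
(sens + spec − 1 on fractions), false discovery/omission rates and the
misclassification percentage. The confidence-interval families are chosen
deliberately and differ by statistic, matching the conventions of clinical
diagnostic-performance tables:

* exact Clopper–Pearson beta-quantile intervals for accuracy, sensitivity
  and specificity — exact coverage at small n (here often n = 7 negatives);
* standard-logit (Mercaldo) intervals for the predictive values, using the
  prevalence-form variance
  Var(logit PPV) = (1−sens)/(n₁·sens) + spec/(n₀·(1−spec));
* the Simel log method for likelihood ratios,
  Var(ln LR⁺) = (1−sens)/TP + spec/FP.

Indices with empty denominators are reported as `NA`, never fabricated.
Report formatting rounds half-up to 1 decimal for percentages, 2 for
ratios, 3 for AUC; full precision is retained internally.

AUC is the Mann–Whitney concordance probability with ties counted ½,
oriented so that a lower index predicts positivity; a property test
confirms on hundreds of random cohorts that it equals the trapezoid area
under the empirical ROC from the cutoff sweep. The reported optimal cutoff
maximizes Youden over the union of observed values and a 0.01 grid on
[0.50, 0.95]; exact ties are broken toward the cutoff nearest 0.80 (the
clinical decision threshold), then toward the larger cutoff. Bland–Altman
limits use the sample SD of the *signed* differences, mean ± 1.96·SD — the
standard construction. No multiple-testing correction is applied to the
reported p-values.

## Synthetic data: what it does and does not emulate

The generators provide every pipeline input with known ground truth:

* **Vessels** — a tapered healthy line times unit-peak cosine or Gaussian
  narrowings, so the generated peak DS% is exact by construction; severity
  is capped at 95% and overlapping lesions are rejected.
* **Polar stacks** — per-frame circular (optionally elliptic) lumens with
  a one-bin smooth edge and additive Gaussian noise, bit-reproducible per
  seed. They emulate edge contrast and noise, *not* speckle texture,
  catheter ring-down, guide-wire shadows or non-circular lumens — so
  tracer performance here bounds the algorithmic error, not the clinical
  one.
* **ECG trains** — R waves at 60/HR spacing with truncated Gaussian
  jitter on the half-open recording window.
* **Cohorts** — trivariate Gaussian draws (Cholesky) at the emulated
  study's moments (means 0.72/0.74/0.73, SDs 0.10/0.09/0.09) and pairwise
  correlations (0.7913, 0.6296, 0.7323), truncated to (0.2, 1.0] by
  rejection rather than clipping so the realized correlations stay
  interpretable; 0.2 covers the plausible FFR range. At n = 10⁵ the
  sample moments recover the parameters within 0.01 (means) and 0.02
  (correlations), the residual bias being the small truncation effect.

The cohort simulator reproduces first and second moments only. Real
per-vessel data are not multivariate Gaussian, and summary AUCs of a real
cohort depend on higher-order structure; cohort-level AUCs from the
simulator are therefore distributional quantities (checked as ranges over
many seeds), not point targets. A 36-vessel draw at these parameters
yields sensitivity/specificity at the 0.80 cutoff scattered around the
high-sensitivity, moderate-specificity regime expected from the
correlation structure.

Problem sizes used by the checks (chosen as the smallest that make the
statistics stable): 20-lesion engine-agreement library; 64×48 polar grids
with ~40 gated frames for the end-to-end pullback; 200 random cohorts for
the AUC identity; 10⁴ replicates for binomial coverage; 10⁵ vessels for
moment recovery.

## Known limitations

* The velocity–diameter-squared closure carries no patient-specific
  microvascular information; k, Pa and blood properties are configuration,
  and reported FFR values inherit their uncertainty.
* One unbranched segment: no side-branch flow loss, no serial-lesion
  interaction beyond what the 1D profile encodes.
* The expansion-loss discretization is grid-tied for severe smooth
  lesions (above); comparisons across resolutions should hold the grid
  fixed.
* The tracer assumes a star-convex lumen about the catheter center (one
  radius per angle).
* Pulsatility, wall compliance and non-Newtonian rheology are not
  modelled; steady hyperemic means are the target quantity.
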