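---
title: "Modelling postprandial hepatic and systemic glucose fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling postprandial hepatic and systemic glucose fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaflux)
```

## The measurement problem

A single oral dose of dideuterated glucose (D-Glc) lets one experiment
observe both sides of postprandial glucose control. In venous blood, the
D-Glc/tracee molar ratio separates meal-derived (exogenous) from
liver-derived (endogenous) glucose; in the liver itself, deuterium
metabolic imaging tracks the tracer arriving in hepatic tissue while
natural-abundance carbon-13 spectroscopy follows glycogen. `hepaflux`
implements the full analysis chain for such a study — quantification,
tracer partition, insulin exposure modelling, glucose–insulin parameter
estimation, and cohort statistics — together with a mechanistic synthetic
cohort generator used to validate every stage.

## Tracer partition

The measured molar ratio is corrected for the pre-dose background ratio
(taken from the subject's own T−60/T0 samples rather than a theoretical
isotopic-abundance constant, which remains available through the
configuration) and for tracer purity (default 0.99):
$r' = \max(0, (r - r_0)/\mathrm{purity})$. Under the tracer-to-tracee
convention the exogenous concentration is
$G_{exo} = G_{tot}\, r'/(1+r')$ and the endogenous series is the
remainder, so the two sources sum to the measured total by construction.
Whether the enrichment is expressed as tracer-to-tracee ratio or mole
percent excess is a convention choice; both are implemented
(`convention = "ttr"` (default) or `"mpe"`), since the saturating
transform only differs at large enrichments. Corrected ratios that fall
below zero from early-time noise are clipped to zero with a warning.

## Quantification of the imaging channels

Hepatic D-Glc concentration is obtained voxel by voxel as the
per-deuteron amplitude ratio against that subject's initial
(pre-ingestion) natural-abundance semi-heavy-water signal, scaled by the
assumed hepatic water reference of 8.94 mmol/l, and then averaged over the
six central voxels. Deuteron multiplicities (two for the tracer, one for
water) are explicit configuration values rather than hard-coded constants,
since published workflows differ on whether the glucose peak is corrected
for multiplicity. The concentration is "mmol D-Glc per selected volume":
no attempt is made to separate vascular from hepatocellular signal, which
is beyond what the measurement can support.

Glycogen uses phantom-replacement quantification with a multiplicative
correction chain — coil-to-liver distance, coil loading, T~1~ relaxation
and nuclear Overhauser enhancement — each factor a positive calibration
input.

## Insulin as a known input

The glucose model treats insulin as a measured forcing, not a state. For
healthy subjects the measured plasma insulin is interpolated linearly
between samples (constant before the first sample). For insulin-treated
subjects, whose fast-acting analogue is still being absorbed at dose
time, a two-compartment subcutaneous depot model

$$q_1' = -(k_{a1}+k_d)q_1 + \text{boluses},\qquad
  q_2' = k_d q_1 - k_{a2} q_2,$$
$$I' = -k_e (I - I_b) + F\,(k_{a1} q_1 + k_{a2} q_2)/(V_I\,BW)$$

is fitted to the measured fast-acting concentrations with known bolus
timing and dosing (1 U = 6000 pmol). Only the four rate constants are
estimated; $V_I$ and $F$ are fixed because concentration data identify
only their ratio. The composite active insulin adds the free-active
fraction of the circulating long-acting analogue: 100% for glargine, 25%
for detemir, 2.85% for degludec. Proportional (constant-CV) weighting is
the default, with constant weighting available, since assay error in
insulin is close to multiplicative.

## The oral minimal model

With composite active insulin $I(t)$ as input, the model integrates two
remote insulin compartments and two glucose sources:

$$X' = -p_2\,(X - SI_D\,(I-I_b)), \qquad
  X_P' = -p_{2P}\,(X_P - SI_P\,(I-I_b)),$$
$$G_{exo}' = -(GEZI_D + X)\,G_{exo} + Ra(t)/V,$$
$$EGP = EGP_b \max(0,\, 1 - GE_P (G - G_b) - X_P), \qquad
  G_{endo}' = -(GEZI_D + X)\,G_{endo} + EGP/V,$$

with disposal $R_d = (GEZI_D + X)\,G\,V$ and the basal balance
$EGP_b = GEZI_D\,G_b\,V$ enforced throughout. The multiplicative
suppression form was chosen so that $SI_P$ and $GE_P$ read directly as
fractional-suppression sensitivities and the diabetes rule "$GE_P = 0$"
removes one term cleanly. $GE_P$ deliberately lumps glucose's own effect
on production with the direct (portal) insulin effect; that is why it is
substantial in health — where portal insulin leads peripheral insulin —
and fixed to zero under subcutaneous insulin delivery, which abolishes
the porto-systemic gradient. Production is floored at zero; it can never
be negative.

The meal enters through a gastrointestinal sub-model: a single liquid
stomach compartment (the dose is a drink, so no solid-phase grinding
compartment is needed) emptying at a rate that depends on the remaining
content through the two-tanh profile with break points $b$ and $c$,
followed by first-order intestinal absorption $k_{abs}$ and
bioavailability $f_{bio}$. Gastric retention $GR(t) = q_{sto}/D$ is
summarised by its half-time $T_{50}$, located by linear interpolation on
the dense half-minute solver grid so the value does not depend on the
reporting schedule.

### Estimation

Parameters are estimated by weighted least squares jointly over the
exogenous and endogenous channels (proportional weighting with a floor at
5% of each channel's maximum, so the pre-dose zeros of the exogenous
channel do not receive unbounded weight). Fixing rules: $GEZI_D$ is fixed
at a population value (0.02 min⁻¹ by default, proportionally scaled by
0.5 for the diabetes group — the scaling is a configuration input, not an
asserted truth); $V$, $f_{bio}$, $b$, $c$ are fixed; free by default are
$SI_D$, $p_2$, $SI_P$, $p_{2P}$, $k_{max}$, $k_{min}$, $k_{abs}$, plus
$GE_P$ for healthy fits. Whether $f_{bio}$ is estimated is exposed as an
option but off by default.

Because the exogenous channel depends only on absorption and disposal,
the optimiser is staged: disposal/GI parameters are first fitted to the
exogenous channel, production parameters to the endogenous channel, and a
joint Levenberg–Marquardt polish over all free parameters defines the
reported objective. Finite-difference Jacobians use a relative step of
about 10⁻³ — well above the 10⁻⁸ integration tolerance — because steps
inside the solver tolerance produce noise gradients and premature stalls.
Estimates within 1% of a box bound are flagged as near-boundary, which is
how an unidentifiable $GE_P$ left free on diabetes-like data announces
itself. Asymptotic fractional standard errors come from the Jacobian at
the optimum and are reported only for free parameters.

Numerical settings: `lsoda` with absolute and relative tolerances of
10⁻⁸, dense output every 0.5 min, the dose added to the stomach as an
event at t = 0 (the retention curve is pinned to 1 at the ingestion
instant, where the solver reports the pre-event state).

## The synthetic cohort

The generator forward-simulates the same equations (one shared forward
core), so noise-free datasets are exactly reproducible by the estimator.
Three documented profiles define the study conditions: one healthy and
two diabetes subgroups in the 10 / 6 + 4 mixture of `study_mixture()`.
Profile constants were calibrated once against the study's printed
summaries and frozen:

* healthy — basal/peak total glucose 5.2/7.5 mmol/l, endogenous nadir
  1.2 mmol/l, 63% average EGP suppression over 0–180 min, hepatic D-Glc
  peak 3.0 mmol/l, glycogen iAUC +2.4 mol/l·min, insulin 43.4 → 366
  pmol/l peaking at 81.2 min (a log-Gaussian bump; no β-cell model is
  implemented because the analysis uses insulin as a known input);
* diabetes subgroup 1 — T₅₀GR 65.3 min, first-hour suppression 0.26,
  hepatic peak 6.1 mmol/l, glycogen +2.5 mol/l·min, an 8.2 U bolus at
  −45 min and constant detemir exposure (pump replacement);
* diabetes subgroup 2 — T₅₀GR 110.7 min, first-hour suppression 0.11,
  hepatic peak 2.7 mmol/l, glycogen −3.0 mol/l·min (net depletion).

Two observational channels are calibrated by construction rather than by
stored rate constants. The hepatic channel is a first-order exchange with
plasma D-Glc, $L' = k_{in}G_{exo} - k_{out}L$; since $L$ is linear in
$k_{in}$, the inflow rate is solved exactly so the noise-free peak equals
the profile's target. This lumped compartment is the honest limit of the
measurement: the composite vascular-plus-hepatocellular nature of the
signal is represented only through the exchange, not decomposed. The
glycogen trajectory is the parametric ramp
$baseline + A\,\Phi((t-t_{on})/w)$ with $\Phi$ the standard normal CDF and
$A$ solved so the trapezoidal incremental AUC over 0–180 min on the
reporting grid equals the target — the study reports concentration
trajectories and iAUCs, not a glycogen flux model, so none is invented.
Glucagon is generated as a descriptive decline-then-rise curve and never
used by the fitted model.

Sampling follows the protocol grids: venous samples at T−60, 0, 10, 20,
30, 60, 90, 120, 150, 180 min; glucagon on its sparser subset; MR
channels every 10 min. The MR grid extends to 180 min (the acquisition
window of the emulated protocol ends at 150) so that the reported 0–180
incremental AUCs of the imaging channels are computable on-grid; the
10-min spacing is a stand-in for the interleaved acquisition, not a claim
about its exact schedule.

Measurement noise is multiplicative Gaussian truncated at zero with
per-channel CVs (glucose and ratio 2%, insulin 6%, glucagon 10%, DMI
amplitudes 8%, glycogen 10% — typical assay/MRS precisions, all
configurable). Between-subject variability enters as unit-mean lognormal
multipliers on the kinetic parameters (15% CV), with the observational
anchors inheriting the relative spread of the printed cohort summaries
(e.g. 27% for the hepatic peak); the emptying bounds share one multiplier
so the nonlinearity keeps its shape.

### Design choices made under genuine freedom

* **Time convention**: minutes relative to dose ingestion; negative times
  are pre-dose (the bolus sits at ≈ −45 min). Dose conversion uses
  180.156 g/mol; the isotope mass difference (<1.2%) is ignored.
* **Missing values** are absent rows, never sentinels — glucagon's sparser
  grid is by design and is not a validation finding.
* **Healthy subjects skip the subcutaneous model entirely**; their
  measured insulin, linearly interpolated, is the model input. The
  generator therefore also drives the healthy forward simulation with the
  piecewise-linear interpolation of the venous-grid insulin samples —
  exactly the representation the downstream fit uses.
* **Population GEZI_D = 0.02 min⁻¹** (upper end of published
  glucose-effectiveness estimates). The choice is load-bearing: the late
  quasi-steady endogenous level is approximately
  $G_b\,rel\cdot GEZI_D/(GEZI_D+X)$, and smaller values cannot hold a
  1.2 mmol/l nadir against 63% average suppression.
* **Per-subgroup intestinal absorption defaults** (0.035 vs 0.012 min⁻¹)
  encode the reported subgroup contrast in meal-glucose appearance; they
  leave half-emptying (a property of gastric emptying alone) and diabetes
  EGP suppression (insulin-driven only, since $GE_P=0$) untouched.
* **Statistics**: pooled-variance Student t by default (Welch via
  configuration), 95% CIs from the t distribution, **no multiple-testing
  correction** — comparisons are descriptive, mirroring the two-sided
  α = 0.05 convention of the emulated design. Clustering z-scores the two
  iAUC features, uses Euclidean distance and Ward linkage (the linkage is
  an argument so stability can be probed), cuts at k = 2 and renames
  cluster 1 to the higher-plasma-iAUC phenotype.

## What the synthetic validation does and does not show

Passing the pipeline on generated cohorts demonstrates internal
consistency: the estimator recovers the generating parameters (to ≲1%
noise-free across all three profiles), quantification inverts the
generator's amplitude model exactly, partition is conservative, and the
subgroup structure is rediscovered by clustering under realistic noise.
It does not demonstrate that the model family is adequate for real data:
the generator has no model mismatch, no occlusions or motion in the
imaging channels, no assay drift, and its between-subject variation is
lognormal by fiat. Two known shape limitations of the calibrated defaults
are documented rather than hidden: the exogenous-glucose peak of the
healthy profile (≈4.4 mmol/l) sits below the printed cohort mean
(5.2 ± 1.2), and the diabetes profiles' exogenous peaks are compressed
relative to the printed 12.6/6.7 means, because cohort means of
individually-timed peaks need not lie on any single consistent
trajectory, and the suppression/nadir/total-peak anchors take precedence.
Orderings and ratios between groups are preserved.

Problem sizes used by the validation suite — single subjects for the
calibrated round trips, a 20-subject cohort for parameter recovery, 200
replicates for the noise-unbiasedness check, a 6 + 4 noisy cohort for the
clustering check — are the package's chosen defaults and scale linearly
if enlarged.

## Known limitations

* Point weighted-least-squares estimation only; no Bayesian machinery.
* The vascular/hepatocellular decomposition of the hepatic D-Glc signal
  is out of scope (a lumped exchange stands in for it).
* Gastric emptying is inferred through the model, not validated against
  scintigraphy or breath tests.
* The healthy endogenous insulin curve is descriptive; simulating
  secretion dynamics would be needed to study insulin itself.
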