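# hepaflux

Postprandial hepatic and systemic glucose flux analysis from a single oral
stable-isotope tracer combined with liver magnetic resonance readouts.

After drinking a dose of [6,6′-²H₂]-glucose (D-Glc), three things can be
measured simultaneously: total plasma glucose and the D-Glc/tracee molar
ratio in venous blood, plasma insulin (fast- and long-acting analogues
separately, by LC-MS), hepatic D-Glc by deuterium metabolic imaging (DMI),
and liver glycogen by natural-abundance ¹³C spectroscopy. `hepaflux` turns
those raw channels into physiology:

- **Tracer partition** — the measured molar ratio `r`, corrected for the
  pre-dose background and tracer purity (`r' = (r − r₀)/purity`), splits
  total glucose into exogenous (meal) and endogenous sources:
  `G_exo = G_tot · r'/(1 + r')`.
- **Spectroscopy quantification** — hepatic D-Glc from per-voxel,
  per-deuteron amplitude ratios against the initial semi-heavy-water signal
  (assumed 8.94 mmol/l), averaged over six voxels; glycogen from a phantom
  reference with corrections for coil distance, loading, T₁ and NOE.
- **Insulin exposure** — for insulin-treated subjects, a two-compartment
  subcutaneous absorption model fitted to the measured fast-acting insulin,
  plus the free-active fraction of the circulating basal analogue
  (glargine 100%, detemir 25%, degludec 2.85%), gives the composite active
  insulin input.
- **Oral minimal model** — with insulin as a known input, the single-tracer
  oral minimal model with a gastrointestinal absorption sub-model is fitted
  jointly to the exogenous and endogenous glucose series:

  ```
  X'     = −p₂ (X − SI_D (I − I_b))            remote insulin, disposal
  X_P'   = −p₂P (X_P − SI_P (I − I_b))         remote insulin, production
  G_exo' = −(GEZI_D + X) G_exo + Ra(t)/V
  EGP    = EGP_b · max(0, 1 − GE_P (G − G_b) − X_P)
  G_endo'= −(GEZI_D + X) G_endo + EGP/V
  ```

  yielding the meal rate of appearance `R_aMeal`, gastric retention GR(t)
  and its half-time T₅₀GR, endogenous glucose production (EGP) and glucose
  disposal (R_d), with the usual fixing rules (`GEZI_D` fixed to a
  population value; `GE_P = 0` in type 1 diabetes).
- **Cohort analytics** — incremental AUCs, peaks/nadirs (excluding the
  T−60 sample), pooled two-sample t tests, and Ward hierarchical
  clustering of per-subject plasma and hepatic D-Glc iAUCs that separates
  the diabetes arm into its two phenotypic subgroups.

Because no subject-level data are public, the package ships a mechanistic
**synthetic cohort generator** (`generate_subject()`, `generate_cohort()`)
whose calibrated default profiles — one healthy, two diabetes subgroups —
reproduce the study's headline readouts when pushed through the full
pipeline. Generator and estimator share one forward core, so every stage is
testable end to end.

## Worked example

```r
library(hepaflux)

sub <- generate_subject(default_profile("healthy"), seed = 1, noise = FALSE)
res <- analyze_subject(sub$dataset)
round(res$metrics[c("egp_suppression_0_180", "endo_nadir",
                    "hepatic_dglc_peak", "glycogen_iauc_0_180",
                    "t50_gr", "peak_glucose")], 3)
#> egp_suppression_0_180            endo_nadir     hepatic_dglc_peak
#>                  0.630                 1.200                 3.000
#>   glycogen_iauc_0_180                t50_gr          peak_glucose
#>              2400.000                71.136                 7.500
```

Read: fitting the minimal model to this virtual healthy subject shows EGP
suppressed by 63% on average over three hours; endogenous glucose bottoms
out at 1.2 mmol/l; the liver D-Glc signal peaks at 3.0 mmol/l; glycogen
accumulates 2.4 mol/l × min above its fasting level by 180 min; half the
drink has left the stomach by ~71 min; total glucose peaks at 7.5 mmol/l.

A study-sized cohort with measurement noise and between-subject
variability, analysed and summarised:

```r
cohort   <- generate_cohort(study_mixture(), seed = 1)
datasets <- lapply(cohort, `[[`, "dataset")
analyses <- lapply(datasets, analyze_subject)
report   <- build_cohort_report(analyses, datasets)
report$cluster$labels      # the discovered 6 + 4 diabetes subgroups
```

A thin command-line wrapper covering simulation, per-subject analysis and
cohort reports is installed at `inst/cli/hepaflux.R`.

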