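# iolmc

Monte Carlo propagation of intraocular-lens (IOL) manufacturing power
tolerance into postoperative refractive prediction error.

After cataract surgery the eye's refraction is predicted from preoperative
optical biometry — mean keratometry *K* (D), anterior chamber depth *ACD*
(mm), and axial length *AL* (mm) — by a vergence formula. The lens actually
implanted, however, carries a labelled power that may differ from its true
power: 0.50 D-interval lenses are manufactured to a tolerance of about
±0.40 D, while 0.25 D-interval lenses reach about ±0.11 D. `iolmc` is for
researchers in cataract refractive outcomes who want to quantify how much of
the postoperative prediction error this dioptric labelling error alone can
explain.

The package provides:

* **Formula engines.** Deterministic SRK/T and Haigis implementations.
  SRK/T estimates the effective lens position (ELP) from corneal geometry
  and an A-constant; Haigis uses the linear predictor
  *d = a₀ + a₁·ACD + a₂·AL*. Both predict the spectacle-plane spherical
  equivalent *R(P)* at any IOL power *P* through a thin-lens vergence chain
  (12 mm vertex), and both are invertible: `power_for_target()` finds the
  continuous power with *R(P) = target*.
* **Zero-error power construction.** With the target set to the *observed*
  postoperative spherical equivalent, the inversion yields the IOL power at
  which prediction error is exactly zero — absorbing every other error
  source (biometry, ELP estimation) so that a subsequent power perturbation
  is the only error source left.
* **Monte Carlo study.** `run_mc_study()` perturbs each eye's zero-error
  power with Gaussian manufacturing error (SD 0.40 or 0.11 D) and propagates
  it to refractive error, 10 replicates per formula per lens group, with
  median absolute error (MedAE), mean absolute error (MAE), and
  within-threshold percentages per replicate.
* **Lens-constant optimization.** `optimize_a_constant()` and
  `optimize_haigis_constants()` reproduce the "data-adjusted constant"
  procedure: per-eye ELP back-solving, ordinary least squares for a₁/a₂,
  and an a₀ (or A) shift giving exactly zero mean prediction error.
* **Synthetic paired-eye cohorts.** `generate_cohort()` emulates a
  40-patient bilateral-cataract population: shared patient latents give the
  observed interocular correlations (R² ≈ 0.93 for K, 0.89 for ACD, 0.93
  for AL), one 0.25 D- and one 0.50 D-interval lens per patient, powers
  restricted to 15.5–25.0 D, and correlated clinical-scale refraction noise.
* **Outcome statistics.** MedAE/MAE summaries, Mann–Whitney U (exact or
  tie-corrected normal), 2×2 chi-square, pooled-variance t, Pearson R².

## Worked example

Power selection for a single average eye:

```r
library(iolmc)
lens <- default_lens_registry()$akreos_ao      # 0.50 D grid, SD 0.40 D
eye  <- data.frame(K_D = 44.41, ACD_mm = 3.14, AL_mm = 23.42)
p <- power_for_target("haigis", eye, lens, target_refraction = -0.25)
round(p, 4)                                    # 20.0392  (continuous)
round_to_grid(p, lens)                         # 20.0     (on the 0.50 D grid)
predict_refraction("haigis", eye, lens, 20.0)  # -0.2215 D
```

The eye needs 20.04 D for a −0.25 D target; the nearest manufacturable
0.50 D-interval power (20.0 D) leaves a predicted −0.22 D, i.e. grid
coarseness alone shifts the plan by 0.03 D before any labelling error.

The full tolerance study on a synthetic bilateral cohort:

```r
cohort <- generate_cohort(cohort_spec(), seed = 1)   # 40 patients, 80 eyes
report <- run_mc_report(cohort, seed = 1)            # 10 replicates/formula/group
report
#> Monte Carlo tolerance report (seed 1, 10 replicates)
#>
#> HAIGIS formula
#>   Akreos AO    (SD 0.40 D): MedAE 0.20 D [0.14 - 0.24], within ±0.25 D 52.5 - 72.5%
#>   Softec HD    (SD 0.11 D): MedAE 0.06 D [0.03 - 0.07], within ±0.25 D 97.5 - 100.0%
#>   replicates with both comparison p < 0.001: 10 of 10
#>
#> SRKT formula
#>   Akreos AO    (SD 0.40 D): MedAE 0.20 D [0.15 - 0.28], within ±0.25 D 35.0 - 72.5%
#>   Softec HD    (SD 0.11 D): MedAE 0.05 D [0.04 - 0.06], within ±0.25 D 100.0 - 100.0%
#>   replicates with both comparison p < 0.001: 10 of 10
```

Reading the numbers: with a 0.40 D power-error SD the typical replicate's
median absolute refractive error is about 0.20 D and only 50–70% of eyes
land within ±0.25 D of prediction, whereas a 0.11 D SD keeps the median
error near 0.05 D with essentially every eye within ±0.25 D — the
spectacle-plane error is roughly half the power-error SD, because a diopter
of IOL power moves the spectacle refraction by only ~0.6–0.7 D. Every
replicate separates the two groups at p < 0.001 (Mann–Whitney on absolute
errors and chi-square on the ±0.25 D split).

`write_mc_report()` persists the per-replicate table as tidy CSV plus a
JSON aggregate block; `run_clinical_analog()` produces the analogous
clinical outcome table (MedAE/MAE/threshold percentages with group
comparisons) from observed rather than simulated refractions.

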