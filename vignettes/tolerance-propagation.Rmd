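---
title: "How IOL manufacturing tolerance becomes refractive error: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How IOL manufacturing tolerance becomes refractive error: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iolmc)
```

## The question

An intraocular lens is manufactured on a diopter grid (commonly 0.50 D,
sometimes 0.25 D) and its true power may deviate from the label. For
0.50 D-interval lenses the accepted tolerance in the 15.5–25.0 D range is
about ±0.40 D; 0.25 D-interval lenses are reported near ±0.11 D. How much
postoperative refractive prediction error does this labelling error alone
produce, once all other error sources — biometry, effective-lens-position
(ELP) estimation, keratometry — are held fixed? `iolmc` answers this with a
paired-eye simulation design: each synthetic patient receives one lens of
each interval class, and only the IOL power is randomized.

## Formula engines

Both engines model the pseudophakic eye as a two-lens system (cornea + IOL)
and carry the refraction to the spectacle plane at a vertex distance of
12 mm (the clinical standard; both engines accept another value).

**SRK/T.** The corneal radius is recovered from keratometry as
$r = 337.5/K$. Axial length is corrected beyond 24.2 mm
($L_{cor} = -3.446 + 1.715\,AL - 0.0237\,AL^2$), corneal width and dome
height follow from $r$ and $K$, and the ELP is the dome height plus an
offset encoding the lens- and surgeon-specific A-constant
($ACD_{const} = 0.62467A - 68.747$). The retina-corrected optical length is
$AL + 0.65696 - 0.02029\,AL$. When a very steep, small cornea makes the
dome-height square-root argument negative it is clamped to zero (the
published errata behaviour), so the engine is total on the supported
biometry range. Corneal index 1.333, aqueous index 1.336.

**Haigis.** The ELP is the linear predictor
$d = a_0 + a_1\,ACD + a_2\,AL$ (millimetres); the three constants absorb
lens geometry and systematic surgeon effects. Corneal power is computed
from the radius $r = 337.5/K$ with a corneal index of 1.3315 — the
formula's original physical index, which *undoes* the keratometer's 1.3375
convention. Which index a given biometer's implementation uses is generally
not observable from outside, so the index is an argument
(`corneal_index`); setting 1.3375 reproduces the keratometric variant. All
results in this package use 1.3315.

Both engines are strictly decreasing in IOL power, so the inversion
`power_for_target()` (Brent-style `uniroot` on \[−10, 40\] D, tolerance
10⁻¹⁰ D) has a unique root. The test suite holds the engines to 10⁻⁹ D
against independent transcriptions of the *published power-given-refraction*
equations inverted numerically — a genuinely different code path — and to a
10⁻⁷ D forward/inverse round trip.

**Grid rounding.** Continuous powers are carried at full precision
everywhere; rounding happens once, at surgical lens selection
(`round_to_grid()`). Exact half-interval ties round toward the *lower*
power: when the formula is aimed at a slightly myopic target, the
lower-power lens errs hyperopically toward plano, and surgical convention
prefers leaving the eye nearer plano over deepening myopia; any fixed
tie-break would do numerically, but one had to be fixed.

## Lens-constant optimization

"Data-adjusted" constants are those producing zero mean signed prediction
error on a reference cohort. For SRK/T this is a one-dimensional root find
on the A-constant over \[100, 130\] (the objective is monotone). For Haigis,
each eye's ELP is back-solved from its observed refraction (again a
monotone inversion, on 0.5–9.0 mm), ELP is regressed on (ACD, AL) by
ordinary least squares to give $a_1, a_2$ and an intercept, and the
intercept is then shifted so the cohort's mean prediction error is zero to
10⁻⁶ D. The zero-mean-error criterion defines the procedure, and with any
nonzero residual scatter the OLS intercept does not satisfy it exactly, so
the shift is applied; both the raw intercept (`a0_regression`) and the
shifted `a0` are reported so either convention can be read off.

## The Monte Carlo study

The defining construction: for each eye, the *zero-error power* $P_0$ is
the continuous power at which the formula's prediction equals the observed
postoperative spherical equivalent. At $P_0$ the prediction error is
identically zero, so biometry and ELP error are absorbed, and the study's
assumption — only IOL power is random — holds by construction.

Each replicate draws one manufactured power per eye,
$P \sim N(P_0, \sigma)$, with $\sigma$ = 0.40 D for the 0.50 D-interval
group and 0.11 D for the 0.25 D-interval group. The tolerance figures are
strictly *limits* in the standards literature; following the study design
this package emulates, they are treated as standard deviations. Drawn
powers are *not* re-rounded to the grid — manufacturing error is
continuous. The per-eye error is

$$e = R(P) - R(P_0),$$

the refraction the eye actually attains minus the refraction predicted at
the labelled power. (The source design states only that generated powers
"were used to calculate the refractive prediction error"; this difference
is the operationalization consistent with *observed minus predicted*, and
is documented here as the package's convention.) Since $R$ is locally
linear with slope about −0.65 D per D near clinical powers, $e$ is
approximately $N(0, 0.65\sigma)$: the spectacle-plane error is roughly half
the power-error SD, replicate MedAE ≈ 0.674 × 0.65σ (≈ 0.18 D at σ = 0.40,
≈ 0.05 D at σ = 0.11), and MedAE scales linearly in σ — all of which the
suite asserts.

Default 10 replicates per formula per group. Replicate $i$ uses a seed
derived deterministically from (study seed, $i$), so studies are exactly
reproducible and a replicate's result does not depend on how many
replicates surround it. Summaries per replicate: MedAE with IQR, MAE, mean
signed error, counts/percentages within ±0.25/0.50/0.75/1.00 D; aggregates:
min/median/max across replicates plus pooled percentages across all
replicate-eyes. Whether the authors of the emulated design drew one power
per eye per replicate or reused draws across formulas is not stated; this
package draws independently per formula.

## The synthetic cohort

The generator emulates the *statistical structure* the analysis needs, not
any real patient series:

* **Marginals.** Pooled bilateral biometry targets K 44.4 (1.36) D,
  ACD 3.15 (0.36) mm, AL 23.43 (0.70) mm — the two per-group columns of the
  emulated population are averaged since eyes are exchangeable by design.
* **Interocular correlation.** Per measure, a shared patient latent with
  variance $r\sigma^2$ plus eye-level noise with variance $(1-r)\sigma^2$,
  where $r = \sqrt{R^2_{target}}$, hits the published interocular
  R² (0.926 / 0.893 / 0.934 for K / ACD / AL) in population; the suite
  checks ±0.05 at 400 patients. K, ACD, and AL are drawn independently of
  one another (no joint values are available to calibrate a cross-measure
  correlation).
* **Surgery.** Each patient gets both lens models, the right/left
  assignment randomized; the implanted power is the grid-rounded Haigis
  power for a −0.25 D target (a slightly myopic target is standard; one
  formula had to be chosen for the emulation and Haigis, whose constants
  are per-lens here, is used). Patients whose continuous power falls
  outside 15.5–25.0 D are redrawn entirely (rejection, preserving Gaussian
  shape, rather than clipping), mirroring the inclusion rule.
* **Outcome noise.** Observed postoperative SE = prediction at the
  implanted power + Gaussian noise, SD 0.45 D with between-eye correlation
  0.6. The SD is a tunable chosen so the clinical-analog MAE lands in the
  0.30–0.50 D band a real series occupies; the correlation mirrors the
  qualitative "moderate to strong" interocular correlation of prediction
  error (no numeric value is published, so 0.6 is a documented assumption).
  The suite checks the induced error correlation lands in \[0.4, 0.8\].

What the generator does *not* model: age/sex structure, corneal
astigmatism, axial-length–keratometry correlation, formula-specific ELP
misestimation, or measurement drift. Passing tests therefore demonstrate
the error-propagation machinery on a population with realistic first- and
second-order structure, not that any clinical series would reproduce the
clinical-analog tables; the Monte Carlo conclusions are robust to this
because the zero-error construction makes them depend only on biometry
scale and the tolerance SDs.

## Statistical conventions

* Quartiles by linear interpolation (R type 7); the alternative hinge
  conventions differ by at most one interpolation step at n = 40 and do not
  move any conclusion.
* Mann–Whitney U: exact distribution when tie-free and $n_1 n_2 \le 400$,
  otherwise a tie-corrected normal approximation with continuity
  correction (the correction keeps the approximation within 0.02 of
  exhaustive enumeration at $n_1 = n_2 = 8$, which the suite asserts).
* Chi-square on 2×2 tables: uncorrected Pearson by default, Yates by flag.
  Two-sided p-values throughout; no multiplicity correction.
* Degenerate inputs are flagged, not silently passed: zero-variance
  comparisons are marked `degenerate`, zero marginals and unreachable
  targets raise errors naming the offending eye or row.

## Problem sizes and reproducibility

Default study sizes — 40 patients, 10 replicates, two formulas, two groups
— run in seconds; the package's own validation uses 400-patient cohorts for
distributional checks and 10⁵ draws for distributional-shape checks. Every
stochastic entry point takes an explicit integer seed and derives all
substreams from it; `generate_cohort()` attaches its spec and seed to the
returned cohort, `run_mc_study()` records its seed in the result, and CSV
persistence rounds to 6 decimals so a write/read round trip is lossless at
that precision.

## Known limitations

* Only SRK/T and Haigis are implemented (no Hoffer Q, Holladay, Barrett);
  no toric or multifocal optics; no post-refractive-surgery eyes.
* The tolerance-as-SD reading is conservative relative to
  tolerance-as-uniform-limit; lenses actually manufactured may be better
  than either.
* The Haigis corneal-index choice shifts absolute predicted refractions
  slightly; it cancels almost entirely in the simulated *differences*
  (error = actual minus labelled prediction), which is why the Monte Carlo
  results are insensitive to it.
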