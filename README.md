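# octnorms

Statistical tooling for cross-population studies of macular retinal and
choroidal thickness measured by optical coherence tomography on the ETDRS
grid.

Cohorts of this kind — two ethnic groups, most subjects contributing both
eyes, nine retinal sectors plus a central choroidal measurement per eye —
raise three linked problems: fellow eyes are strongly correlated, so
eye-level regressions need subject-level random effects; small studies
cannot adjust for every confounder, so the robustness of an association to
unmeasured-confounder measurement error has to be quantified; and
comparisons against previously published populations require
random-effects meta-analysis of study summaries. `octnorms` implements the
full pipeline, driven by a synthetic-cohort generator so that every stage
is testable without access to raw clinical data.

## The models

**Per-sector mixed model.** For subject *i*, eye *j* and response *k*
(thickness in µm):

    T_ijk = mu_k + beta_eth,k * 1[Ghanaian_i] + beta_age,k * (age_i - 60)/10
          + beta_sex,k * 1[male_i] + b_ik + e_ijk,
    b_ik ~ N(0, sigma_b^2),   e_ijk ~ N(0, sigma_e^2)

fitted by REML with the variance ratio `theta = sigma_b^2/sigma_e^2`
profiled to a bounded 1-D search (closed-form GLS at fixed theta). The
implied inter-eye correlation is `rho = sigma_b^2/(sigma_b^2+sigma_e^2)`.
Inference is Wald-z with Bonferroni adjustment over the 9 sectors.

**Confounder sensitivity.** Each targeted eye's response is perturbed to
`y(1+u)`, `u ~ U(-e, e)`, the model refitted, and the proportion of
simulations keeping the ethnicity association significant is traced over
an error grid `e = 0 ... 1`; thresholds `e*_95`, `e*_99` are read off the
isotonically smoothed curve.

**Meta-analysis.** DerSimonian–Laird random-effects pooling of study
means (`w_i = n_i/sd_i^2`, Cochran's Q, tau², I²), with eligibility
screening, seeded single-eye selection, decade age-bin stratification and
group comparisons.

**Power.** Analytic noncentral-F power for a p-covariate regression
(`f² = R²/(1−R²)`, `lambda = f² n`) and parametric-bootstrap post hoc
power at the observed design.

## Worked example

```r
library(octnorms)

sim <- generate_cohort(default_config(seed = 1))
sim$cohort
#> <cohort> 151 eye records, 79 subjects (37 European + 42 Ghanaian)

fit_sector(sim$cohort, "c0", family_size = 9)
#> <sector_fit> response 'c0': 151 eyes, 79 subjects
#> variance components: sigma_b^2 = 248.61, sigma_e^2 = 90.21 (ICC 0.73)
#>               term estimate   se     z  ci_lo  ci_hi p_raw p_bonferroni
#>        (Intercept)   251.94 2.85 88.56 246.37 257.52 0.000        0.000
#>  ethnicityGhanaian   -36.34 4.16 -8.74 -44.49 -28.19 0.000        0.000
#>        age_decades    -4.30 2.05 -2.10  -8.32  -0.28 0.036        0.325
#>            sexmale    13.94 4.88  2.86   4.38  23.51 0.004        0.038
```

The ethnicity row is the adjusted Ghanaian-minus-European difference for
this simulated draw: the foveal retina is 36.3 µm thinner (95% CI
[−44.5; −28.2], Bonferroni-adjusted p < 0.001) after controlling for age
and sex; the variance components imply an inter-eye correlation of 0.73.
Single draws scatter around the generating effect of −45.3 µm; averaging
refits across replicate cohorts recovers it (see the acceptance script
below).

```r
intereye_correlation(sim$cohort, "c0")
#> r = 0.860, 95% CI [0.784; 0.910]     (Fisher z, 72 both-eye subjects)

analytic_power(n = 79, p_covariates = 3, r_squared = 0.20)
#> <power_result> analytic power = 0.966 (f^2 = 0.250, lambda = 19.75, F(3, 75), alpha = 0.05)

sens <- run_sensitivity(sim$cohort,
                        sensitivity_config(response = "choroid",
                                           n_sims_per_level = 500, seed = 1))
sens$thresholds
#>  e_star_95 e_star_99
#>       0.90      0.70
```

The sensitivity run says that on this cohort the choroid–ethnicity
association would keep ≥ 95% of its perturbed refits significant up to a
multiplicative measurement error of 90% of the original value (99%
criterion: 70%).

`run_pipeline("out/", seed = 1)` chains all stages and writes CSV tables
plus a `manifest.json` with seeds and MD5 digests; reruns with the same
seed are bit-identical.

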