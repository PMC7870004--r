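# slgee — skewed-logit marginal models for correlated binary data

Repeated binary outcomes — an infant ill or not at each monthly visit,
a symptom present or absent across follow-ups — are routinely analyzed
with logistic GEE. The logit link is symmetric: the response curve is
steepest at probability 0.5. When the outcome is imbalanced, that
symmetry is an assumption, not a fact, and it can bias both effect
estimates and their standard errors.

`slgee` fits population-averaged regressions for clustered binary data
under the asymmetric **skewed logit** (Burr type-10, "scobit") link

π(η) = 1 − (1 + e^η)^(−α),  α > 0,

which nests the ordinary logit at α = 1 and moves the point of maximal
covariate sensitivity to η\* = −log α. Estimation is two-stage, for
longitudinal analysts who want marginal (population-averaged) effects:

1. **`fit_skew_glm()`** — joint maximum likelihood for (β, α) treating
   observations as independent, plus **`symmetry_lrt()`**, a 1-df
   likelihood-ratio test of α = 1.
2. **`gee_fit()` / `fit_all()`** — generalized estimating equations
   with α held fixed at the stage-1 estimate, under five working
   correlation structures (independence, exchangeable, AR(1),
   m-dependent, unstructured), with model-based and Huber sandwich
   covariances, Wald Z tests, variance-ratio diagnostics
   (`variance_ratio_table()`), and time-varying exposure odds ratios
   (`bv_time_effects()`).

A Gaussian-copula simulator (`simulate_morbidity_study()`) generates
infant-morbidity-like cohorts (327 subjects × 6 monthly visits,
realistic covariate prevalences, serial dependence, MCAR missingness)
with *exact* marginal means, and `recovery_experiment()` measures bias,
RMSE, and robust-interval coverage of the whole pipeline. The Prentice
power-logit link is also available. See the vignette
(`vignettes/skewed-logit-gee.Rmd`) for the model, assumptions, and
numerical details.

## Worked example

```r
library(slgee)

d <- simulate_morbidity_study(simulation_config(seed = 1))
X <- build_design(d)

stage1_logit <- fit_skew_glm(X, d$y, family = "logit")
stage1_skew  <- fit_skew_glm(X, d$y)          # estimates alpha too
symmetry_lrt(stage1_logit, stage1_skew)

fits <- fit_all(d, alpha = 3)                 # both arms, 5 structures
wald_table(fits$fits$slgee$ar1)
```

The skewed-logit AR(1) Wald table printed by that call:

```
       term   estimate   se_model  se_robust     wald_z       p_value
1 intercept -4.6098718 0.23531185 0.21653391 -21.289376 1.424129e-100
2 breastfed -0.1177398 0.08195163 0.08154585  -1.443848  1.487817e-01
3        bv  1.2607863 0.16906840 0.17119818   7.364484  1.778329e-13
4   bv_time -0.2436585 0.04213668 0.04220453  -5.773278  7.774398e-09
5       hiv  0.1679597 0.10016439 0.10348271   1.623071  1.045743e-01
6      male -0.3581364 0.08173315 0.08313564  -4.307857  1.648442e-05
7      time  0.1809470 0.05275932 0.05029778   3.597515  3.212714e-04
8    weight -0.1466656 0.07401394 0.06793605  -2.158877  3.085968e-02
```

The exposure (`bv`) raises the odds of morbidity strongly in month 1
and the effect attenuates by `bv_time` each month; the implied monthly
odds ratios are

```r
sl <- fits$fits$slgee$ar1
round(bv_time_effects(sl$beta[["bv"]], sl$beta[["bv_time"]]), 2)
#> month1 month2 month3 month4 month5 month6
#>   2.77   2.17   1.70   1.33   1.04   0.82
```

— a declining protective-to-harmful crossover pattern of the kind the
skewed-logit GEE is designed to detect. Variance ratios
(robust SE / model SE)² sit near 1 under AR(1) (0.99–1.06 for `bv`)
but inflate to ~1.36 under working independence, the standard signal
that the serial structure matters.

On a single 327-subject cohort the skewness itself is weakly
identified (its likelihood is nearly flat upward); `fit_skew_glm()`
boxes the estimate and warns when it lands on the boundary. Rely on
the LRT, not the magnitude of α̂, for the symmetry decision.

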