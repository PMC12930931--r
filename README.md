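# growmix

Latent-class growth mixture modelling of infant weight-for-length (g/cm)
from birth to 18 months, with the inference machinery for studying how
prenatal element exposures (As, Hg, Pb, Cu, Mn, Se measured in maternal
toenail clippings) relate to which growth trajectory an infant follows.

## Who this is for

Perinatal/environmental epidemiologists analysing longitudinal infant
anthropometry against exposure biomarkers, and methodologists who want a
self-contained, simulation-validated implementation of the one-step
(within-likelihood) relative-risk-ratio approach and its two-stage
comparator.

## The model

A K-class Gaussian growth mixture model — a finite mixture of linear mixed
models. For subject *i* in latent class *k*:

    y_ij | c_i = k  =  x(t_ij)' beta_k + b_i + e_ij,
    b_i ~ N(0, sigma_b^2),   e_ij ~ N(0, sigma_e^2)

with x(t) a quadratic B-spline over age (knots at 3.5 and 9 months, or
selected by minimizing the OLS sum of squared errors), and membership given
by a multinomial logit of exposure and covariates:

    P(c_i = k | w_i) = exp(w_i' gamma_k) / sum_l exp(w_i' gamma_l),  gamma_1 = 0.

Estimation is EM (random intercept and class treated as missing data) with
k-means-seeded restarts; K is chosen by BIC subject to class-share (>5%)
and posterior-quality (>80% of members above 0.7) rules; classes are named
against a growth-standard chart by the sum of squared differences of median
curves, the closest class ("Stable-slow") serving as reference. Exposure
effects come out as relative risk ratios per doubling —
`exp(delta * (gamma_j - gamma_ref))`, which equals the probability-ratio
definition exactly under the logit link — with Wald CIs from the observed
information; a two-stage multinomial comparator, 18-month LMS z-score
regressions, BMI cross-product interactions, and quantile-based
g-computation for the six-element mixture (risk ratio per simultaneous
one-quartile increase, signed weights, 500-subject-bootstrap CIs) complete
the toolkit. A calibrated synthetic cohort generator with known ground truth
backs every stage's tests.

## Worked example

```r
library(growmix)

sim <- default_calibration(n_subjects = 783, seed = 3)  # calibrated cohort
cohort <- generate_cohort(sim)
an <- preprocess_cohort(cohort)          # visit mapping, exclusion cascade,
                                         # LOD-aware exposure transforms
fit <- fit_gmm(an, K = 4, membership = membership_frame(an, "Hg"),
               n_starts = 3, seed = 1)
fit
#> Growth mixture model: 4 classes, 783 subjects, 7110 observations
#> logLik -23056.01  BIC 46438.51  sigma_b 5.963  sigma_e 4.801  converged
#> expected class shares: 28.5% 23.5% 35.2% 12.8%

rrr_onestep(fit, "Hg", "doubling", scale_sd = an$exposures$scale_sd, ref = 1)
#>   element class contrast estimate      lo95     hi95   method converged
#> 1      Hg     2 doubling 1.035461 0.8829317 1.214340 one_step      TRUE
#> 2      Hg     3 doubling 1.052228 0.9072719 1.220345 one_step      TRUE
#> 3      Hg     4 doubling 1.120428 0.9398279 1.335732 one_step      TRUE
```

The printed fit reports the maximized log-likelihood, BIC (subject-count
penalty), the shared random-intercept and residual SDs in g/cm, and the
expected class shares. `rrr_onestep()` rows are relative risk ratios per
doubling of toenail Hg for each class against the reference — 1.0 means no
association (this calibration generates null exposure effects; set nonzero
membership coefficients in the config to inject known ones). The full
pipeline — per-sex K sweep, selection report, chart-based class naming with
kappa transfer, all effect tables, and the mixture analysis — is one call:

```r
out <- run_pipeline(pipeline_config(sim = sim, out_dir = "run1", seed = 3))
```

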