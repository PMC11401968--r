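# dyadhg — Bayesian dyadic hurdle-gamma mediation models

`dyadhg` is for researchers studying how families cope after collective
trauma (floods, storms, disasters) with linked parent–youth questionnaire
data. It fits and compares two competing mediation directions over
posttraumatic stress symptoms (PTSS), coping self-efficacy (CSE), and
communal coping:

* **disaster distress**: PTSS → lack of CSE → communal coping
* **communal coping**: communal coping → lack of CSE → PTSS

Each member of a dyad contributes a mediator regression and an outcome
regression. Because PTSS is right-skewed and CSE / communal coping are
reverse-coded to be (their ceilings map to exact zeros), every outcome
follows a **hurdle-gamma** law

```
p(y) = hu                                        if y = 0
p(y) = (1 − hu) · Gamma(y; α, rate = α / e^η)    if y > 0
```

with a log link on the gamma mean, z-scored covariates in the linear
predictor η, and one jointly correlated 10-vector of dyad-level random
intercepts and slopes spanning both members (LKJ(1) prior), so cross-pair
correlations — e.g. parent vs youth communal-coping intercepts — are
estimable. The indirect effect per member is the per-draw product of the
path into and out of the mediator, summarized by exceedance probabilities
P(a·b > c); the two model directions are compared by a bridge-sampled Bayes
factor with the >3 decision rule.

The package is self-contained: it ships its own No-U-Turn sampler
(C++/Rcpp, hand-derived gradients), rank-normalized split R-hat and
bulk/tail ESS, bridge sampling, chained random-forest imputation,
questionnaire scoring/reliability helpers, a synthetic dyad generator whose
defaults reproduce the published study conditions (452 dyads, 2.3%
missingness), and a `run_pipeline()` orchestrator that writes CSV/JSON
artifacts plus a reproducibility manifest.

## Worked example

```r
library(dyadhg)

# a synthetic cohort at the study conditions, with 2.3% MCAR missingness
raw  <- inject_missingness(generate_dyads(dyad_config(n_dyads = 452, seed = 1)),
                           rate = 0.023, seed = 2)
prep <- preprocess_dyads(raw, seed = 3)   # exclude -> impute -> standardize
fit  <- fit_dyad_model(prep$data, "distress", priors = "informative",
                       mcmc = mcmc_config("desk", seed = 4))
summary(fit)
```

The fixed-effect block of the summary table prints (here truncated to the
coefficient rows; the full table also carries shapes, hurdle probabilities,
random-effect SDs, and bulk/tail ESS):

```
                 parameter estimate  lower upper rhat
1   b_p_lack_cse_Intercept   -0.038 -0.116 0.038    1
2        b_p_lack_cse_ptss    0.322  0.254 0.389    1
3  b_p_ccope_rev_Intercept    0.182  0.083 0.277    1
4       b_p_ccope_rev_ptss    0.076 -0.023 0.173    1
5   b_p_ccope_rev_lack_cse    0.116  0.011 0.224    1
6   b_y_lack_cse_Intercept   -0.011 -0.107 0.083    1
7        b_y_lack_cse_ptss    0.294  0.223 0.363    1
8  b_y_ccope_rev_Intercept    0.168  0.086 0.248    1
9       b_y_ccope_rev_ptss   -0.065 -0.150 0.019    1
10  b_y_ccope_rev_lack_cse    0.213  0.120 0.306    1
```

The `estimate` column holds posterior means of the standardized log-link
coefficients; `lower`/`upper` the 95% credible interval; R-hat is the
rank-normalized split version with the ≤ 1.01 gate. The generating values
here were the published point estimates — e.g. 0.25 for the parent
PTSS → lack-of-CSE path, estimated at 0.32 because the informative
normal(0.36, 0.06) prior pulls upward (the weak profile, used by the
recovery machinery, stays at the generating value).

```r
mp <- mediation_product(fit, "youth")
mp
exceedance_curve(mp, c(0.01, 0.03, 0.05))
member_difference(fit)
```

```
Mediation product for youth (b_y_lack_cse_ptss x b_y_ccope_rev_lack_cse)
  mean 0.063, median 0.062, 95% CI [0.033, 0.095]
  threshold probability
1      0.01     0.99975
2      0.03     0.98500
3      0.05     0.78975
Youth - parent mediation-effect difference
  mean 0.025, 95% CI [-0.023, 0.074], P(>0) = 0.854, evidence ratio 5.86
```

The mediation product is the per-draw `a·b`; the exceedance table gives
P(product > c) at each threshold; the member difference reports the
youth-minus-parent contrast with P(>0) and the one-sided evidence ratio
p/(1−p).

Model comparison and the full artifact-writing pipeline:

```r
res <- run_pipeline(run_config(out_dir = "run1", model = "both", seed = 1))
# writes dataset.csv, analysis.csv, fit_*_summary.csv, diagnostics_*.csv,
# mediation_*.csv, comparison.json (Bayes factor + decision), report.md,
# and manifest.json with md5 hashes of every artifact
```

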