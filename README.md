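# pedpk — pediatric population pharmacokinetics with size and maturation functions

`pedpk` is an R package for population-pharmacokinetic analysis of pediatric
cohorts, aimed at pharmacometricians who need a self-contained, tested
implementation of the standard neonatal/pediatric modelling workflow:
nonlinear mixed-effects compartment models whose parameters scale
allometrically with body weight and mature with post-conceptional age,
estimated from sparse therapeutic-drug-monitoring data.

Because children are not small adults, a clearance-like parameter is modelled
as

    CL_i = TVCL · (WT_i / 70 kg)^0.75 · PCA_i^Hill / (PCA_i^Hill + TM50^Hill) · exp(eta_i)

and a volume-like parameter as `Vd_i = TVVd · (WT_i/70)^1 · exp(eta_i)`, with
`eta ~ N(0, omega^2)` the inter-individual random effect, `TM50` the
post-conceptional age (weeks) at half the adult clearance and `Hill` the
sigmoidicity of the maturation curve. Residual error follows a
constant-coefficient-of-variation model, handled by default on the natural-log
scale (log-transform-both-sides). Estimation is first-order conditional
estimation with interaction (FOCE-I): a Laplace approximation of the marginal
likelihood at each subject's conditional mode, with an adaptive Gauss-Hermite
quadrature oracle available to bound the approximation error. Model evaluation
uses conditional weighted residuals (CWRES), visual predictive checks (VPC),
the nonparametric bootstrap, and stepwise covariate modelling (forward
p < 0.05, backward p < 0.01, with a |r| > 0.5 correlation pre-filter against
weight and age).

No patient data ship with the package. A synthetic-study module generates
complete pediatric trials — demographics, weight-based dosing, sparse TDM
sampling, observations — emulating three designs: a children's cyclosporine A
cohort (two 24-h infusions, n = 34), a neonatal phenobarbital cohort (IV
loading + oral maintenance, n = 28) and a neonatal vancomycin cohort
(intermittent infusions, n = 93), with true parameters set to the published
estimates of the corresponding studies.

## Worked example

Simulate a vancomycin-style neonatal study at its published design size, fit
the final model (one compartment, allometric size on CL and Vd, maturation on
CL fixed at its reference values), and inspect the estimates:

```r
library(pedpk)

st  <- generate_study("van", n = 93, seed = 1)
fit <- fit_foce(st$model, st$truth, st$dataset,
                inits = c(CL = 30, Vd = 8, omega2_CL = 0.1,
                          omega2_Vd = 0.1, sigma_pro = 0.3),
                control = list(se = FALSE, restarts = 0))
fit
#> pk_fit: OFV 1297.193 (converged), 93 subjects, 271 observations
#>           estimate
#> CL         67.6379
#> Vd          3.5421
#> omega2_CL   0.0000
#> omega2_Vd   0.3170
#> sigma_pro   0.4243
```

The clearance typical value (67.6 L/h, normalised to a 70-kg adult through
the allometric term) lands within 3% of the generating truth (69.4 L/h) and
the volume (3.54 L) within 10% of 3.23 L. `omega2_*` are the eta variances:
the volume eta (0.317, a ~60% CV against a 52.8% truth) is well supported,
while the small clearance eta (truth 10.4% CV) collapses to zero — three
samples per subject cannot distinguish it from residual noise (`sigma_pro`,
the log-scale residual SD: 0.424 against a 0.408 truth). Diagnostics follow
the same grammar:

```r
cw <- compute_cwres(fit, st$dataset)   # ~ N(0,1) when the model is right
v  <- vpc(fit, st$dataset, n_sim = 500, seed = 7)
bt <- bootstrap_fit(fit, st$dataset, n_resamples = 200, seed = 11)
```

The `analysis/` directory holds the numbered workflow scripts
(`01_simulate_studies.R` … `05_covariate_search.R`) that run the full
simulate → fit → compare → evaluate → covariate-search sequence and write
their tables under `results/`.

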