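---
title: "Population PK modelling of pediatric cohorts: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK modelling of pediatric cohorts: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpk)
```

## The problem

Dosing in neonates, infants and children cannot be read off adult values by
linear weight scaling: clearance-like processes scale allometrically with
body mass, and drug-eliminating organs mature over the first months of life.
`pedpk` implements the population-pharmacokinetic machinery used to quantify
both effects from sparse therapeutic-drug-monitoring data: nonlinear
mixed-effects compartment models with allometric size scaling and a
sigmoid-Emax maturation function, estimated by first-order conditional
estimation with interaction (FOCE-I), and evaluated with conditional
weighted residuals (CWRES), visual predictive checks (VPC) and the
nonparametric bootstrap. A synthetic-study generator emulates three
pediatric designs — a children's cyclosporine A cohort, a neonatal
phenobarbital cohort and a neonatal vancomycin cohort — so the whole
workflow is exercised end-to-end without any patient data.

## Model

**Structural models.** Linear one- to three-compartment disposition with
intravenous bolus, zero-order infusion and first-order oral absorption
input. One-compartment profiles are evaluated in closed form per dose and
superposed; two- and three-compartment profiles are propagated piecewise
with the matrix exponential of the rate matrix. An independent ODE
integration (deSolve) serves as the test oracle, never as the production
path.

**Parameter model.** For a structural parameter $P$ (clearance CL, volume
$V_d$, absorption rate $k_a$, bioavailability $F$) the individual value is

$$P_i = \theta_P \cdot
  \left(\frac{WT_i}{70\,\mathrm{kg}}\right)^{power} \cdot
  \frac{PCA_i^{Hill}}{PCA_i^{Hill} + TM_{50}^{Hill}} \cdot
  \prod_c \left(\frac{x_{ci}}{\tilde x_c}\right)^{\beta_c} \cdot
  e^{\eta_i},\qquad \eta_i \sim N(0, \omega^2),$$

with each multiplicative term optional per parameter. The allometric
exponent defaults to 0.75 for CL and 1 for $V_d$ (both can be estimated);
the maturation factor attaches to clearance only, with post-conceptional
age (PCA = gestational + postnatal age, weeks) as the default maturation
clock. $TM_{50}$ is the PCA at half the adult clearance and $Hill$ the
sigmoidicity. Inter-individual variability is exponential (log-normal);
reported CV% uses the exact form $\sqrt{e^{\omega^2}-1}$, with the
first-order $\sqrt{\omega^2}$ selectable.

**Residual error.** The estimation default is log-transform-both-sides
(LTBS): observations enter as $\log DV$ with additive residual SD $\sigma$,
which is first-order equivalent to a constant-CV (proportional) error of
magnitude $\sigma$ on the linear scale and keeps simulated concentrations
positive by construction. The literal linear-scale menu — additive,
proportional (CCV) and combined — is implemented and selectable
(`scale = "linear"`); the interaction term of FOCE-I is then active, as the
residual variance depends on the random effects through the prediction.

## Estimation

Per subject, the conditional objective

$$g(\eta) = \sum_j \left[\frac{(y_j - f_j(\eta))^2}{v_j(\eta)}
 + \log v_j(\eta)\right] + \eta^\top \Omega^{-1} \eta$$

is minimised by a damped Newton search with a Gauss-Newton Hessian, started
at $\eta = 0$ on every outer iteration so the objective is a deterministic
function of the parameters. The marginal $-2\log L$ is the Laplace
approximation at the mode,

$$\mathrm{OFV}_i = g(\hat\eta_i) + n_i \log 2\pi + \log\det\Omega
 + \log\det\left(\Omega^{-1} + G_i^\top V_i^{-1} G_i\right),$$

with $G_i = \partial f_i/\partial\eta$ at $\hat\eta_i$. This is exact when
the model is linear in $\eta$ with additive error, and the package carries
an adaptive Gauss-Hermite quadrature oracle (up to two etas) against which
the approximation is tested. The outer problem optimises Nelder-Mead over
log-transformed positive components (allometric exponents and covariate
coefficients stay untransformed, as they may be negative), with one restart
from the incumbent; standard errors come from the central finite-difference
Hessian of the OFV (relative step $10^{-4}$), $\mathrm{Var} =
2H^{-1}$. The full constant $n\log 2\pi$ is included by default; a
comparison-oriented convention without it is available (`constant =
FALSE`), as only OFV differences matter for likelihood-ratio decisions.
Nested models are compared by $\Delta$OFV against $\chi^2$ quantiles;
fixed-form additions that estimate no new parameter (df = 0) are flagged
against the conventional 3.84-point improvement instead, since no
likelihood-ratio p-value exists for them.

The per-subject inner problem for one-compartment models runs in compiled
code (Rcpp/Armadillo), mirroring a pure-R reference implementation that
remains the fallback for multi-compartment models; the two paths agree to
numerical identity in the tests.

### Numerical design: log-scale superposition

The printed parameter sets of the neonatal designs imply extremely fast
elimination for small subjects (terminal half-lives of minutes against
sampling windows of up to 23.5 h), so a trough concentration can lie many
hundreds of natural-log units below the dose peak — far beyond double
precision on the linear scale. All one-compartment predictions are
therefore computed as log-concentrations per dose and combined by
log-sum-exp, so the LTBS likelihood stays finite and informative no matter
how deep in the terminal phase a sample falls. The simulator guarantees
DV > 0 under LTBS; in the rare case that a simulated concentration
underflows even double-precision subnormals (about $e^{-745}$), the
observation is dropped with a message — the synthetic analogue of a sample
below any conceivable quantification limit.

## Synthetic study designs

The generator draws demographics from truncated normals (inverse-CDF
sampling, exact and seed-reproducible) with the cohort means, SDs and
ranges of the three studies; body weight shares a normal score with age
(correlation 0.6) so heavier subjects are older, and laboratory covariates
are truncated normals correlated with the weight score (default 0.3).
Body-surface area is a deterministic function of weight, deliberately, to
exercise the covariate pre-filter. True parameters are the final published
estimates of each study; IIV CV% values are converted to $\omega^2$ by the
exact log-normal relation.

* **csa** (children, n = 34): two 24-h infusions of 15 mg/kg starting 24 h
  apart, one sample 20 h into each infusion. Size scaling only (no
  maturation; the cohort is past infancy, and no gestational age is
  recorded).
* **phb** (neonates, n = 28): intravenous loading dose 15-20 mg/kg over
  15 min, then 3-5 mg/kg/day oral maintenance for 5 days starting 12-24 h
  after loading; default sampling is one trough 5 min-3 h before each
  subsequent dose. The `rich_sampling` variant used in recovery experiments
  draws six samples per subject, stratified with two in the intravenous
  loading phase — the only phase that separates bioavailability from
  clearance and volume — and four across the maintenance course.
* **van** (neonates, n = 93): 15 mg/kg infused over 1 h every 6-24 h (six
  doses); three samples per subject drawn as therapeutic-drug-monitoring
  pairs — half "peak-type" 0.5-2 h after a dose, half "trough-type" later
  in the interval, all within 0.5-23.5 h post dose. Early samples are
  essential here: with minutes-long half-lives every late sample is pure
  terminal phase, which identifies only the ratio CL/Vd; the near-plateau
  concentration during an infusion reads R/CL directly and anchors the
  split. A uniform draw over the whole window leaves the clearance typical
  value drifting by 10-15% between replicates; the peak/trough scheme — the
  realistic TDM practice for this drug class — pins it to a few percent.

What the generator does **not** emulate: electronic-record artifacts,
assay-specific censoring (no LLOQ), dropout, dose-adherence noise,
time-varying weight, or correlation between the etas. Passing recovery
tests on these cohorts therefore demonstrates internal consistency of
simulator and estimator under the published designs, not robustness to the
messiness of real hospital data.

## Identifiability of the maturation function

The recovery experiments surfaced a structural weakness worth documenting.
With $TM_{50}$ and $Hill$ both free, the profile likelihood of the
phenobarbital design is nearly flat along the ridge
$TM_{50} \to \infty,\ \theta_{CL} \propto TM_{50}^{Hill}$: on that ridge
the sigmoid degenerates to a pure power law $PCA^{Hill}$, which the cohort
(PCA ~ 31-51 weeks) fits marginally *better* than the generating sigmoid at
realistic noise levels — the exact-quadrature likelihood confirms this is
not an artifact of the FOCE approximation. The clearance typical value,
defined at the adult asymptote, is then unbounded. Even with $Hill$ fixed,
the strong local sensitivity $\partial\log CL/\partial\log TM_{50} =
Hill\,(1-F_{mat}) \approx 4$ means a 2% error in $TM_{50}$ moves the
recovered clearance by ~8%, so clearance and $TM_{50}$ cannot both be
recovered tightly from one replicate. The package follows the field's (and
the source studies') practice for the headline recovery experiments:
maturation parameters are fixed at their reference values when the target
is the clearance typical value, and the $TM_{50}$-estimation variant (Hill
fixed) is run separately to show the maturation parameter itself is
recoverable. Both variants are exercised in the acceptance tests.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `wt_ref` | 70 | kg | allometric reference weight |
| `power` (CL / Vd) | 0.75 / 1 | - | allometric exponents, fixed or estimated |
| `tm50`, `hill` | per design | weeks, - | maturation half-age and slope |
| `scale` | `"log"` | - | LTBS or literal linear-scale error menu |
| `n_sim` (VPC) | 1000 | - | simulation replicates |
| `bins` (VPC) | 8 | - | quantile time bins; <5-obs bins merge |
| `n_resamples` | 1000 | - | bootstrap resamples (the studies report 1000; one table header says 2000 — both are supported) |
| forward / backward p | 0.05 / 0.01 | - | stepwise covariate thresholds (df = 1: 3.84 / 6.63) |
| prefilter threshold | 0.5 | - | max |r| with weight/age before SCM |

## Numerical choices and degenerate inputs

* $k_a = k_e$ degeneracy: the oral profile switches to the analytic limit
  $F\,D\,k_e\,\tau e^{-k_e\tau}/V$ when $|k_a - k_e| < 10^{-8} k_e$; the
  phenobarbital design's fixed $k_a = 50\,h^{-1}$ exercises the large-ka
  regime, which the log-space formulation keeps stable.
* Maturation is evaluated through `plogis` on the log scale, so extreme
  Hill coefficients neither overflow nor lose monotonicity.
* CWRES uses the symmetric (eigen) square root of the covariance
  $G\Omega G^\top + V$, making it invariant to observation ordering;
  near-singular covariances are ridged by $10^{-10}$ with a warning.
* Ties between a dose and an observation at the same time resolve
  dose-first, so a trough recorded at the instant of the next dose reads
  the pre-dose concentration only if its time is strictly smaller.
* VPC percentiles are computed on the fitting scale (log under LTBS) and
  reported in mg/L; quantile-based time bins are used because sampling
  times in these designs cluster at troughs.
* Bootstrap refits start from the original point estimates and disable
  standard errors; runs with under 50% refit convergence are flagged
  unreliable.

## Problem sizes used in the shipped experiments

The package's tests and the acceptance script run the three designs at
their published sizes (34 / 28 / 93 subjects; the phenobarbital recovery
variant at n = 100 with six samples per subject). Monte-Carlo components
are scaled to keep the full suite reproducible on a single CPU: VPC
calibration uses 200 replicates (the analysis default is 1000), the
bootstrap demonstrations 20-50 resamples (reported analyses use 1000), the
covariate-search type-I study 50 replicates of a reduced design without
random effects, and the model-comparison ordering check 5 replicates of a
40-subject cohort. These sizes are stated here as the package's own choices so
results are reproducible as shipped.

## Known limitations

* Diagonal $\Omega$ only (the source models use univariate exponential
  etas); no eta covariance estimation.
* No Michaelis-Menten elimination, transit absorption, lag times, BLQ
  likelihood handling, or prediction-corrected VPC.
* FOCE-I shares the known small-sample biases of the method at large
  $\omega^2$; the quadrature oracle bounds the approximation error in the
  tests but is limited to two etas.
* The stepwise covariate search tests one functional form per candidate
  (power by default, linear selectable) with subject-level median
  imputation for missing covariate values.
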