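---
title: "Population pharmacokinetics of high-dose methotrexate: model, estimation and diagnostics"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-dose methotrexate (HD-MTX, >500 mg/m&sup2;) is given to patients with
intracranial germ-cell tumours as a split intravenous infusion — one third
of a 1.3 g/m&sup2; dose over 1 h, the remainder over the following 11 h —
with serum concentration monitoring from 24 h after the end of the
infusion (36 h after dose start) every 12 h up to 108 h, guiding folinate
rescue. Concentrations are measured in &mu;mol/L with an assay
quantitation range of 0.3–2,600 &mu;mol/L. Elimination is predominantly
renal, so renal function (eGFR), body size, hepatic markers and
co-medication are plausible determinants of clearance.

`mtxppk` implements the full population-pharmacokinetic workflow for this
setting: an analytic structural model, a covariate model on clearance (CL)
and central volume (Vc), FOCE-type nonlinear mixed-effects estimation,
stepwise covariate selection, and the standard model-evaluation battery
(goodness-of-fit, bootstrap, VPC, NPDE). Because no patient-level data
are public, the package also ships a synthetic-cohort generator that
emulates the study population and design; every statistical claim the
package makes is tested against cohorts from that generator.

## Structural model

Disposition is mammillary with first-order elimination from the central
compartment; one-, two- and three-compartment variants are supported, the
two-compartment form being the default (it is the structure that best
described these data). Concentrations are evaluated analytically: the
bolus response is a polyexponential $C(t)=A\sum_m c_m e^{-\lambda_m t}$
whose exponents are the eigenvalues of the micro-constant matrix
($\alpha \ge \beta$ solve $s^2-(k_{10}+k_{12}+k_{21})s+k_{10}k_{21}=0$
for two compartments, a cubic for three), and a constant-rate infusion
segment contributes the convolution
$R\,\sum_m \frac{c_m}{\lambda_m}\bigl(1-e^{-\lambda_m \min(t,\tau)}\bigr)
e^{-\lambda_m (t-\min(t,\tau))}$. Multi-segment and multi-course dosing
histories are superposed, which is exact for a linear system. The
`-expm1()` form keeps the small-rate limit stable, and $q=0$ falls back to
the one-compartment closed form rather than evaluating a 0/0 coefficient.
A stiff ODE integration (deSolve) is kept in the test suite as the
independent oracle; the analytic evaluator agrees with it to better than
1e-6 relative on randomized models, and is what makes 1,000-replicate
simulation studies affordable.

Amounts are carried in &mu;mol (molar mass 454.44 g/mol, configurable)
and volumes in litres so concentrations are natively &mu;mol/L, the assay
unit.

## Covariate model

Typical values follow the published final-model equations:

$$CL = 12.88\;(eGFR/102.2)^{0.23}(BW/47)^{0.39}e^{BLM}
       (TBIL/15.3)^{-0.05}(ALB/40.9)^{-0.18}\ \mathrm{L/h}$$

with $BLM=0.08$ under bleomycin co-medication and 0 otherwise, and

$$V_c = 72.04\;(BW/47)^{0.31}\ \mathrm{L},$$

with $Q = 1.08$ L/h and $V_p = 94.94$ L fixed. Continuous covariates
enter as powers of median-standardized values and binary covariates on
the log scale — the only two functional forms the model (and the stepwise
engine) uses. Inter-individual variability is exponential,
$\theta_i = \theta_{TV}e^{\eta_i}$, $\eta\sim N(0,\omega^2)$ on CL and
Vc; residual error is proportional, $C_{obs}=C_{pred}(1+\varepsilon)$,
$\varepsilon\sim N(0,\sigma^2)$ with $\sigma=0.37$ (additive and combined
families are also available). These defaults ship in
`inst/extdata/final_model.yaml` and are returned by `fixed_effects()` /
`load_model_config()`.

One interpretive choice deserves a flag: the published table lists the
IIV of CL and Vc as "CV%" values (2.98 and 0.32) that are not plausible
as either CV% or standard deviations. The package therefore treats IIV
magnitudes as user-set log-scale standard deviations with defaults
$\omega_{CL}=0.30$ and $\omega_{Vc}=0.32$ — values typical of HD-MTX
population analyses — and all recovery claims are made against those
defaults, not against the table entries.

In simulation, proportional residual draws are truncated at $-0.999$ so a
positive prediction cannot change sign; additive draws are not truncated,
and any negative simulated values are retained (the likelihood, not
truncation, handles them). Observations below the 0.3 &mu;mol/L
quantitation limit are flagged (`BQL`) but kept as ordinary values both in
simulation and, by default, in the likelihood — mirroring the assay
practice of still reporting such concentrations. An optional left-censored
(`censored_lloq = TRUE`) likelihood treats them as $P(y<LLOQ)$ instead.

## The synthetic cohort

`sample_covariates()` draws age (73.3% children, ages 3–48), sex (70.7%
female), and age-anchored height, body-mass index and serum creatinine,
from which body weight, BSA (Mosteller) and eGFR are derived — the
bedside Schwartz equation for children, the 2021 race-free CKD-EPI
equation for adults. Bilirubin, albumin and the 58.67% bleomycin
indicator are drawn independently. The anchors are tuned so that cohort
medians land on the study medians (BW 47 kg, height 155 cm, Scr 62
&mu;mol/L, eGFR 102.2 mL/min/1.73 m&sup2;, TBIL 15.3 &mu;mol/L, ALB
40.9 g/L) and spreads match the study ranges; all values are truncated to
those ranges. Two caveats are inherent to emulating a study that
published only medians and ranges. First, the marginal medians of
creatinine, height and eGFR are not jointly attainable under the Schwartz
formula for a children-dominated cohort, so the generator splits the
error (creatinine ≈ −4%, eGFR ≈ −1%, both inside a 5% band). Second,
with the stated design and final-model parameters the typical predicted
concentration at the first sample (36 h) is ≈0.4 &mu;mol/L, well below
the study's observed median concentration of 1.2 &mu;mol/L; the
generator follows the protocol and model, so its concentration marginals
do not reproduce that observed-data feature, and more than half of
simulated samples fall below the quantitation limit.

`simulate_cohort()` composes covariates, random effects, the BSA-scaled
split-infusion regimen (default two courses 504 h apart; the course count
is an assumption, the study does not state it), nominal sampling times
thinned by the reported retention rates (100% at 36 h, 53.07% at 48 h,
26.53% at 60 h, 1.39% at 72 h, none later), and residual error. Each
subject keeps at least one sample; with these defaults a 505-subject
cohort yields ≈3.6 observations per subject. Everything is reproducible
from one integer seed, and a truth table (covariates, $\eta$ draws, true
individual parameters) accompanies every dataset for recovery testing.

## Estimation

The marginal likelihood of each subject's observation vector is
approximated by a Laplace expansion at the conditional mode of
$\eta$: the inner problem minimizes the penalized deviance
$g(\eta) = \sum_j \bigl[\log 2\pi v_j + (y_j-f_j)^2/v_j\bigr] +
\eta'\Omega^{-1}\eta + \log\det 2\pi\Omega$ with
$v_j=\sigma_{add}^2+\sigma_{prop}^2 f_j(\eta)^2$ evaluated at the
conditional prediction (the "interaction" convention), via a damped
Newton search (Gauss–Newton curvature, Levenberg damping, gradient
tolerance 1e-9). Two refinements proved necessary under these study
conditions — a 37% proportional CV, ≈3.6 samples per subject, and
terminal-phase-only sampling where $\partial \log f/\partial\eta_{CL}$
is large:

* the curvature in the Laplace determinant is the exact
  (finite-difference) Hessian of $g$, not the Gauss–Newton form, which
  drops the variance-derivative terms of the interaction model; and
* a small adaptive Gauss–Hermite grid (3 nodes per dimension, scaled by
  the Hessian factor at the mode; `agq_nodes = 1` recovers pure Laplace)
  corrects the remaining curvature error.

Both were validated against a dense 41&sup2;-node Gauss–Hermite
quadrature of the exact marginal likelihood: with the Gauss–Newton-only
objective the maximizer was materially displaced (e.g. $\sigma$ pulled
from 0.37 to ≈0.40); with the refinements the objective's minimizer
coincides with the quadrature oracle's and recovery simulations center on
the generating values. The quadrature comparison lives on in the test
suite.

The outer problem maximizes the summed approximate likelihood over fixed
effects (log scale for positive parameters, free scale for covariate
coefficients) with `nlminb`, using an explicit central-difference
gradient (step 1e-3 on the transformed scale) — the inner modes are
warm-started across evaluations, and the explicit step keeps the
residual inner-optimization noise far below the differences the gradient
measures. Standard errors come from the inverse curvature
(`pracma::hessian`) of the objective at the optimum, delta-method
transformed back to the natural scale; estimated $\omega$ below 1e-4 is
reported as 0 with a boundary flag, mirroring the practice of fixing
unidentifiable variabilities to zero. OFV is $-2\log \hat L$ with all
constants, so AIC $=$ OFV $+2p$ and BIC $=$ OFV $+p\log n$ with $n$ the
number of observations (the convention consistent with the published
AIC/BIC arithmetic).

CWRES follows the conditional-linearization definition: the observation
minus the conditional prediction corrected to $\eta=0$, scaled by
$\sqrt{J\Omega J' + v}$ with everything at the mode. One behaviour worth
knowing: the dataset-level mean of CWRES is dominated by the cohort mean
of the true $\eta$ values (standard error $\approx 1/\sqrt{n_{subjects}}$,
not $1/\sqrt{n_{obs}}$), so calibration checks use large cohorts.

## Covariate selection

`run_stepwise()` alternates greedy forward inclusion (accept the largest
OFV drop if it reaches 6.64, the $\chi^2_1$ 0.01 critical value) with
backward elimination (a covariate survives only if its removal raises
OFV by more than 10.83, the 0.001 critical value), exactly the published
procedure. Every trial fit is recorded in an ordered audit trail (model
number, action, OFV before/after, &Delta;OFV, decision) exportable as
CSV. Ties within 1e-6 break by a canonical covariate order (eGFR, BW,
BLM, TBIL, ALB, then alphabetical) for determinism. Candidates may carry
a mutual-exclusion group (the body-weight/BSA collinearity case): at
most one member of a group enters, the better-fitting one. Trial fits
warm-start from the incumbent model's estimates; a cold-start control
exists through the ordinary fitting interface.

## Diagnostics

*Bootstrap* resamples subjects (the hierarchical unit) with replacement
to the original count, refits each replicate warm-started from the
original estimates, and reports medians with 2.5/97.5 percentiles;
failures are counted and excluded. *VPC* simulates replicate datasets at
the observed design and compares observed 5th/50th/95th percentiles per
time-after-dose bin with the 95% band of the same percentiles across
simulations; bins default to the exact nominal sampling times, with no
smoothing and no prediction correction (the evaluated study used a plain
VPC). *NPDE* decorrelates each subject's observed and simulated vectors
with the inverse lower-triangular Cholesky factor of the empirical
simulated covariance, takes each observation's rank fraction in its
simulated ensemble (pulled off 0/1 by half a count), maps through the
normal quantile, and tests the pooled values with the Wilcoxon
signed-rank test (mean 0), a two-sided &chi;&sup2; variance test against
1 (the conventional "Fisher variance test", otherwise unspecified in the
source analysis), and Shapiro–Wilk (on a seeded subsample of at most
5,000 values). Each subject's simulation stream is keyed to its subject
id, so diagnostics do not depend on dataset row order. TAD groups the
split 1 h + 11 h infusion into one dosing occasion, so a 36 h sample has
TAD 36 in every course.

## Problem sizes and what the tests show

The test suite exercises: exact worked-example arithmetic; the ODE
oracle at 100 random models; a 5-seed recovery screen at the full study
size (505 subjects, two courses) whose mean estimates must land inside
the published 95% confidence intervals for CL, Vc, the eGFR/BW/BLM
coefficients and &sigma;; stepwise power on 10 single-course cohorts of
400 subjects and type-I behaviour on 20 null cohorts of 250 (sizes chosen
so the likelihood-ratio signal matches what the full design provides,
while a selection experiment of 70+ model fits stays tractable); and
NPDE/VPC null calibration on 200–300-subject cohorts at 500 simulations.
Passing these shows the pipeline is consistent with the model that
generated the data under the study's design; it cannot show that the
published coefficients are right for real patients, nor how the pipeline
behaves under features the generator omits (time-varying covariates,
inter-occasion variability, model misspecification in the residual
distribution, assay drift).

## Known limitations

* Estimation supports diagonal $\Omega$ only; no inter-occasion
  variability; SAEM-type estimators are out of scope.
* The censored-quantitation likelihood uses the same Gauss–Newton inner
  curvature as the default path for its search; its Laplace determinant
  is exact but the censored contribution to the search direction is
  approximate.
* The exact OFV values of the original commercial-engine analysis are
  not reproducible without the clinical dataset; equivalence is claimed
  statistically (recovery within confidence intervals), not numerically.
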