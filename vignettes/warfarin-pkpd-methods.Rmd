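---
title: "Methods: sequential population PK-PD modelling of warfarin initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential population PK-PD modelling of warfarin initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warfpkpd)
```

## The model chain

Warfarin's anticoagulant effect is modelled in three sequential stages,
each conditioning on individual predictions from the one before:

1. **PK — dose to Cp(S).** Plasma S-warfarin follows a one-compartment
   model with first-order absorption and elimination,
   $$Cp(t) = \sum_{k:\,t_k \le t} \frac{F\,D_k\,K_a}{V_d\,(K_a - k_e)}
   \left(e^{-k_e (t - t_k)} - e^{-K_a (t - t_k)}\right),$$
   with $k_e = CL(S)/V_d$, absorption $K_a = 2\,h^{-1}$ and
   $V_d = 13.8$ L fixed, and bioavailability $F = 1$. Warfarin is dosed
   as the racemate; the S-enantiomer dose is taken as half the racemic
   dose (configurable), which makes the fixed constants consistent with
   the downstream potency parameters. The degenerate case $K_a = k_e$
   uses the analytic limit $D K_a t e^{-K_a t}/V_d$.

2. **PD-1 — Cp(S) to NPT.** Normal prothrombin (NPT, the fully
   carboxylated coagulation biomarker) is a turnover pool whose synthesis
   warfarin inhibits through an Emax term:
   $$\frac{d\,NPT}{dt} = K_{in}\left(1 -
   \frac{I_{max}\,Cp}{IC_{50} + Cp}\right) - K_{out}\,NPT,$$
   with $K_{in} = K_{out}\cdot NPT_0$ (baseline steady state),
   $I_{max} = 1$, and $NPT(0) = NPT_0$.

3. **PD-2 — NPT to INR.** The INR rises nonlinearly with fractional NPT
   inhibition:
   $$INR = INR_{base} + INR_{max}
   \left(\frac{NPT_0 - NPT}{NPT_0}\right)^{\lambda},$$
   with $INR_{max} = 5$ fixed, so INR spans roughly 1 to 6. The model is
   additive in the baseline; the inhibition fraction is clamped to
   $[0, 1]$ before exponentiation so that assay noise pushing observed
   NPT above baseline cannot produce complex powers.

Covariate submodels multiply the typical values:
$CL(S) = \theta_{CL}\cdot 0.543^{CYP2C9^*3}\cdot (BSA/1.74)^{2.14}$,
$IC_{50} = \theta_{IC50}\cdot 2.07^{VKORC1^*1}\cdot 1.30^{CYP4F2^*3}$,
and $\lambda = \theta_\lambda \exp\{0.00588\,(NPT_0 - 119)\}$.
`reference_popmodel()` carries the full reference parameter set,
including inter-individual log-normal standard deviations (39.9%, 38.5%,
45.6%, 24.1% for $CL$, $IC_{50}$, $K_{out}$, $\lambda$) and residual
errors (additive 0.0697 and 12.2 µg/mL for Cp and NPT; relative 24.7%
for INR). The VKORC1 effect is coded per *1 allele; the reference
genotype is the *2/*2 homozygote that dominates Asian cohorts, and the
rare *1/*1 genotype is extrapolated multiplicatively.

## Estimation

Each stage is a nonlinear mixed-effects model estimated by maximising a
Laplace approximation to the marginal likelihood (the first-order
conditional flavour: the expansion is taken about each subject's
conditional mode, with the error-variance interaction term retained for
the relative-error INR stage). Per subject,
$$-2\log L_i \approx q(\hat\eta_i) - d\log 2\pi +
\log\det\left(\tfrac{1}{2}\nabla^2 q(\hat\eta_i)\right),$$
where $q$ is the conditional $-2\log$ joint density and $d$ the number
of active random effects. For linear-Gaussian subproblems this is exact;
the test suite verifies agreement with adaptive Gauss-Hermite quadrature
on sharp-likelihood toys to $10^{-3}$.

Numerical choices that matter:

* The inner (conditional-mode) problems are solved in compiled code with
  analytic residual sensitivities: bracketed secant iteration on the
  gradient for the one-dimensional stages, and damped Newton with the
  exact analytic Hessian for the two-dimensional NPT stage. The exact
  Hessian also feeds the log-determinant, so no finite-difference noise
  enters the outer objective (the one-dimensional stages use a
  central-difference Hessian with step $10^{-3}$, balanced between
  truncation and round-off).
* The turnover ODE is linear in NPT, so the production path uses the
  exact integrating-factor solution with the inhibition input taken
  piecewise-linear on a uniform grid (1 h by default; 0.5 h in accuracy
  tests, 2 h inside covariate searches where only OFV differences
  matter). `deSolve::lsoda` on the same system is retained as an
  independent oracle (`npt_profile(method = "ode")`). At a 1 h step the
  grid solution agrees with the adaptive solver to about 0.3%,
  dominated by the aliasing of the sharp daily absorption peaks.
* Outer maximisation is quasi-Newton (`nlminb`) on log-transformed
  parameters (positivity by construction; covariate exponents and slopes
  unconstrained) with three deterministically jittered starts guarding
  against local minima (single warm starts inside searches and
  bootstrap). Relative convergence tolerance is $10^{-9}$ for final
  fits and $10^{-6}$ inside searches.
* Standard errors, when requested, come from the numerical Hessian of
  the marginal -2 log-likelihood with delta-method back-transformation;
  the bootstrap is the primary uncertainty statement, as in the
  reference analysis.

Sequential conditioning passes *individual* (empirical Bayes)
predictions downstream: the NPT stage uses each patient's EBE clearance
to generate the Cp(S) input, and the INR stage uses EBE IC50/Kout for
the NPT input. Patients with missing baseline NPT are excluded from the
PD stages, mirroring the reference analysis. The baseline INR of each
patient is the mean of the pre-treatment INR measurements.

Weighted residuals divide (observation - population prediction) by the
first-order standard deviation including the linearised
inter-individual contribution, $\sqrt{\sigma^2_{res} + (\partial f /
\partial\eta \cdot \omega)^2}$, so they are approximately standard
normal under a correct model.

## The synthetic cohort generator

No public dataset exists for the original 99-patient trial, so the
package generates cohorts that emulate its published structure:

* **Covariates.** Truncated-normal marginals matching the reported
  means and SDs (age 64.5 ± 15.2 yr, weight 68.4 ± 12.4 kg, height
  163.6 ± 8.2 cm, baseline NPT 118.2 ± 22.1 µg/mL, baseline INR
  1.05 ± 0.10, AST 29.2 ± 16.3, ALT 27.2 ± 17.5 IU/L, CLcr
  73.3 ± 36.6 mL/min), coupled through a Gaussian copula. Age is
  negatively correlated with weight (-0.358), BSA (-0.397) and CLcr
  (-0.568) as reported. BSA comes from the Du Bois formula; matching
  its reported spread (1.74 ± 0.18 m²) requires a weight-height
  correlation, set to 0.62 — with independent weight and height the
  BSA SD would be 0.15, visibly too narrow.
* **Genotypes.** Hardy-Weinberg draws at minor-allele frequencies 0.056
  (CYP2C9\*3), 0.096 (VKORC1\*1, i.e. 0.904 for the -1639A variant) and
  0.278 (CYP4F2\*3).
* **Dosing.** Daily dosing at a fixed clock time (administration times
  are not part of the published protocol). Three loading days at 1.5x
  the predicted maintenance dose — from a calibrated genotype-keyed
  table (targeting the reported 4.1 mg/day genotype-group mean starting
  dose) or the 5 mg/day standard protocol — then INR-driven titration
  at the day-4 and week-1/2/4 visits (+0.5 mg/day below the 2-3 target
  range, -0.5 above it, -1 at INR >= 4, floor 0.5 mg/day).
* **Sampling.** Visit-anchored times with ±6 h uniform jitter: INR at
  5 pre-treatment draws plus day 4 and weeks 1, 2, 4 (and later weeks
  with probability 0.525, giving 8-13 points, mean ~11.1); Cp(S) and
  NPT counts drawn to match the reported means of 9.2 and 10.2 points.
* **Noise and missingness.** Additive Gaussian residuals for Cp and NPT
  (floored at zero rather than redrawn), relative residuals for INR;
  3/99 patients emitted with missing baseline NPT to exercise the
  exclusion logic.

All randomness flows from one cohort-level seed (draws are sequential,
not per-patient streams; a cohort is reproducible from its seed but not
patient-by-patient under subsetting). What the generator does *not*
emulate: non-adherence and dropout, concomitant-medication effects
(amiodarone and friends are covariate flags only, with no PK
interaction), assay quantification limits, measurement error in the
baseline covariates, or any correlation structure beyond the published
ones. Passing recovery tests therefore shows the estimator is consistent
with its own generating mechanism at the study's design — not that the
published model is correct for real patients.

One consequence of the titration feedback is worth knowing: doses adapt
to each patient's simulated INR, so exposure feeds back into the design.
Population-prediction diagnostics (weighted-residual trends) are
confounded by this feedback even under a correct model — exactly as in
real titrated-dosing data — and the tests evaluate those trend
diagnostics on cohorts without inter-individual variability, where the
feedback is inert.

## Covariate search, bootstrap, cohort statistics

The stepwise search adds, per round, the candidate with the largest OFV
drop while it exceeds 3.84 ($\chi^2_1$ at P < 0.05; both power and
exponential forms are fitted for continuous candidates and the better
one competes, counted as one degree of freedom), then deletes covariates
whose removal raises the OFV by less than 6.63 (P < 0.01). Ties break by
candidate order, making the procedure deterministic given the data.

The bootstrap resamples patients with replacement (cohort size
preserved), refits the stage model from the original point estimates,
holds the covariate structure fixed, and reports the mean and the
2.5th/97.5th *ranked* estimates. For the PD stages the upstream
individual predictions are carried over from the original sequential
fit of each resampled patient rather than re-deriving the whole chain
per replicate. Refit failures are excluded and reported; more than 20%
of them aborts the run. Reference resample counts are 1,000 (Cp, INR)
and 100 (NPT); the test suite runs 100/50/100.

Cohort statistics mirror the clinical analysis: allele frequencies from
genotype counts; 2x2 odds ratios with Woolf intervals (Haldane-Anscombe
correction on zero cells); Mann-Whitney tests (exact permutation
enumeration up to 8 per group, tie-corrected normal approximation
beyond); Pearson chi-squared without continuity correction, switching to
Fisher's exact test when an expected cell drops below 5; and stepwise
logistic regression for the INR >= 4 outcome with likelihood-ratio entry
at P < 0.05, removal at P >= 0.10 (the common stepwise default; the
reference software's convention is not stated), a pre-screen dropping
continuous candidates correlating above |r| = 0.7 with the EBE
clearance or lambda, Wald confidence intervals, and a mid-rank
c-statistic with sensitivity/specificity at the 0.5 cutoff.

## Desk-scale choices and operating characteristics

The acceptance suite runs at sizes chosen to keep a full check-out under
half an hour on one core: one 99-patient recovery cohort (with the
three-start fits), ten replicate cohorts for covariate-selection
operating characteristics with a focused candidate roster (the
generating covariates plus body-size, demographic and liver-enzyme
decoys), fifty null single-candidate fits for the false-inclusion rate,
and 100/50/100 bootstrap replicates.

Two operating characteristics deserve honest comment, because they are
properties of the published effect sizes rather than of any particular
implementation:

* **Body-size collinearity.** BSA is computed from weight and height,
  and weight carries most of its variance, so the two are nearly
  interchangeable predictors of clearance. On replicate cohorts the
  forward step picks whichever fits the realisation better; BSA wins
  only in a fraction of replicates even though it is the generating
  covariate. A single-cohort selection of BSA over weight is therefore
  partly luck of the draw.
* **Retention power at P < 0.01.** The weaker genotype effect on IC50
  (the 1.30 CYP4F2 multiplier, with roughly half the cohort carriers)
  implies a noncentrality near the backward-deletion threshold: its
  deletion raises the OFV by only ~7-8 in expectation against a bar of
  6.63. Retention of the full generating covariate pair across most
  replicate cohorts is thus not expected at this sample size, and the
  corresponding acceptance check documents the shortfall rather than
  relaxing the threshold.

## Limitations

The INR cap ("maximum 6") is implemented as the additive
$INR_{base} + 5$ bound rather than a hard truncation at 6; the two
differ only when the baseline exceeds 1. The NPT integration grid
trades a ~0.3% local bias for speed; halving the step quarters it.
Sequential (conditional) estimation propagates empirical-Bayes
shrinkage from stage to stage, slightly inflating downstream
residual-error estimates relative to a joint fit — the same property
the original sequential analysis has. No LLOQ handling is implemented
because none is described for the reference assays.
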