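# warfpkpd

Sequential population pharmacokinetic-pharmacodynamic modelling of
warfarin initiation therapy, for pharmacometricians and clinical
pharmacologists studying over-anticoagulation (INR ≥ 4) during the
induction phase.

Warfarin's effect is modelled as a three-stage chain, each stage a
nonlinear mixed-effects model conditioning on individual predictions
from the one before:

1. **Dose → Cp(S)**: one-compartment kinetics of plasma S-warfarin with
   first-order absorption and elimination, Ka = 2 h⁻¹ and Vd = 13.8 L
   fixed, estimating the oral clearance CL(S) with covariates
   CL(S) = θ·0.543^CYP2C9\*3·(BSA/1.74)^2.14 and log-normal
   inter-individual variability;
2. **Cp(S) → NPT**: an indirect-response (turnover) model in which
   S-warfarin inhibits the synthesis of normal prothrombin through an
   Emax term, dNPT/dt = Kin·(1 − Cp/(IC50 + Cp)) − Kout·NPT with
   Kin = Kout·NPT₀, estimating IC50 (with VKORC1 and CYP4F2 genotype
   effects) and Kout;
3. **NPT → INR**: a nonlinear link
   INR = INR_base + 5·((NPT₀ − NPT)/NPT₀)^λ, estimating the exponent λ
   with a baseline-NPT effect.

Estimation is by Laplace (first-order conditional) approximate marginal
likelihood with an Rcpp core; around the structural chain the package
provides a synthetic-cohort generator emulating a 99-patient Asian
initiation trial (covariate distributions, genotype frequencies,
loading-dose protocols, INR-driven titration, sparse sampling), forward
inclusion / backward deletion covariate search on the objective
function, a non-parametric patient-resampling bootstrap, goodness-of-fit
and visual-predictive-check diagnostics, and the cohort statistics used
in the clinical analysis (allele frequencies, odds ratios, rank tests,
stepwise logistic regression for INR ≥ 4 with c-statistic).

## Worked example

```r
library(warfpkpd)

cohort <- simulate_cohort(seed = 1)     # 99 virtual patients
cohort
#> Synthetic warfarin cohort: 99 patients
#>   observations: CP = 898, INR = 1077, NPT = 995
#>   dose events: 8910
#>   missing baseline NPT: 3

fit_pk  <- fit_stage_pk(cohort)
fit_pk
#> Population PK fit: 99 patients, 898 observations
#>   OFV: -1956.8933
#>   theta: cl = 226.1
#>   cl ~ cyp2c9_star3 (cat): 0.705
#>   cl ~ bsa (power): 2.262
#>   omega (%): cl = 36.7
#>   sigma: 0.06946 (additive)

fit_npt <- fit_stage_npt(cohort, fit_pk)
fit_inr <- fit_stage_inr(cohort, fit_npt)
fit_inr
#> Population INR fit: 96 patients, 563 observations
#>   OFV: 1188.3293
#>   theta: lam = 3.487
#>   lam ~ npt0 (exp): 0.005098
#>   omega (%): lam = 32
#>   sigma: 0.2429 (relative)
#>   excluded patients: 3
```

The recovered fixed effects sit inside the reference bootstrap 95%
intervals (CL(S) 226 vs 219–260 mL/h; λ 3.49 vs 3.31–3.65), the three
patients with missing baseline NPT are excluded from the PD stages, and
comparing empirical Bayes estimates between outcome groups reproduces
the clinical signal — patients who reach INR ≥ 4 have markedly lower
clearance and a lower λ:

```r
flags <- observed_inr_ge4(cohort)
ebes  <- merge(ebe(fit_pk)[, c("patient_id", "cl")],
               ebe(fit_inr)[, c("patient_id", "lam")])
group_compare(ebes, flags[as.character(ebes$patient_id)],
              params = c("cl", "lam"))
#>   parameter median_flag median_ref            p
#> 1        cl       164.8      224.5 0.00062
#> 2       lam        3.05       3.77 0.00011
```

(`median_flag` is the INR ≥ 4 group; quartile columns omitted here.)

A full chained run — simulate, fit all stages, covariate search,
bootstrap, cohort statistics — is one call:

```r
run <- run_pipeline(run_config(seed = 1, do_covsearch = FALSE,
                               n_boot = c(pk = 200, npt = 50, inr = 200)))
```

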