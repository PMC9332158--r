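# codingintensity

Risk-adjusted **excess coding intensity** of inpatient procedures from
administrative claims.

Hospitals record, for every inpatient visit, a count of *additional* coded
procedures beyond the principal one. Comparing those counts across
facilities is meaningless without adjusting for patient mix (a revision
arthroplasty with a two-week stay legitimately accrues more procedure
codes than an uncomplicated knee replacement) and, when desired, for
facility characteristics. This package is for biostatisticians and
quality-control analysts who want a claims-only, two-stage residual
adjustment that flags visits and facilities coding above or below the
industry expectation — without any clinical or EHR data.

## The method

**Stage 1 — patient-level ZIP model.** The additional-procedure count
`Y_i` follows a zero-inflated Poisson given patient covariates `PL_i`:

    logit(pi_i)   = alpha1 + gamma * PL_i        (structural-zero probability)
    log(lambda_i) = alpha2 + beta  * PL_i        (Poisson rate)
    Y_i = 0 with prob pi_i,  else  Y_i ~ Poisson(lambda_i)

Fitted by full maximum likelihood (analytic score, BFGS plus Newton
polishing, Wald IRR/OR intervals). The per-visit residual is the
**excess coding intensity**

    ECI_i = Y_i - (1 - pi_i) * lambda_i

negative for under-coding, positive for over-coding, relative to the
patient-mix expectation.

**Stage 2 — facility-level adjustment.** ECI is regressed (visit-level
OLS, intercept included) on facility covariates `FL_i`, giving the
**adjusted excess coding intensity**

    AECI_i = ECI_i - theta_hat * FL_i

the exact OLS residual: zero-sum, orthogonal to every facility
characteristic, and attributable only to idiosyncratic facility behavior.
Aggregations (per-facility means and ranks, Census-division-by-quarter
means, monthly profiles with a one-way F test for admission-month
association) form the reporting surface.

A synthetic claims generator emulating a U.S. hip/knee arthroplasty
cohort (outcome mean ≈ 0.55, ≈ 60% female, ≈ 85% MS-DRG 470) drives all
examples and tests; real visit/facility CSVs plug into the same pipeline.

## Worked example

```r
library(codingintensity)

cfg <- make_default_config(seed = 1, n_facilities = 50, n_visits = 5000)
cfg$facility_effect_mode <- "rate_shift"   # give facilities real signal
res <- run_pipeline(cfg)

res$rmse
#> RMSE 0.8596 (risk-adjusted) vs 0.8710 (mean-only): 1.31% reduction

res$fit
#> Zero-inflated Poisson fit: n = 5000, logLik = -5037.399, converged (score sup-norm 7.4e-12)
#>                   estimate     se
#> zero_(Intercept)   -0.7076 0.2232
#> ...
#> count_log_los       0.3777 0.0433
#> count_ahrq_index   -0.2845 0.1199

head(res$ranking, 3)
#>   facility_id n_visits  mean_aeci rank
#> 1      F00006      103 -0.1675466    1
#> 2      F00034       99 -0.1388152    2
#> 3      F00002      102 -0.1150807    3

res$monthly
#> Monthly residual profile: F(11, 4988) = 1.133, p = 0.3303
```

Reading the output: the ZIP adjustment lowers prediction RMSE versus the
mean-only model (1.31% here — the synthetic default places only moderate
effects on sex, race, log length of stay and the AHRQ index, so the
reduction is small but strictly positive). `count_log_los = 0.3777` is an
incidence rate ratio of `exp(0.3777) ≈ 1.46`: each unit of log
length-of-stay multiplies the additional-procedure rate by ~1.46.
Facility F00006 under-codes by ~0.17 procedures per visit even after both
adjustment layers; F00007 over-codes by ~0.20. The monthly F test is
non-significant, as it should be — this configuration has no seasonal
component (set `seasonal_amplitude > 0` to generate an August trough).

Every artifact (ECI/AECI tables, ratio table, facility fit, ranking,
seasonal matrix, run log) is also written as CSV/JSON when `out_dir` is
given, and `run_pipeline(list(visits_csv = ..., facilities_csv = ...))`
runs the identical pipeline on your own tables.

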