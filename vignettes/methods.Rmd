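---
title: "Modeling excess coding intensity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling excess coding intensity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Inpatient claims record, for each visit, a count of *additional* coded
procedures beyond the principal one. That count varies with the patient
(age, sex, length of stay, diagnosis, payment group) and with the facility
(teaching and academic status, ownership, size, region, case mix). Coding
intensity that departs from what the patient and facility mix predicts —
under-coding or over-coding relative to industry practice — matters for
reimbursement, quality measurement and care monitoring, but raw counts
cannot be compared across facilities without risk adjustment.

`codingintensity` implements a two-stage residual adjustment on visit-level
claims:

1. **Patient stage.** A zero-inflated Poisson (ZIP) model of the additional
   procedure count \(Y_i\) given patient-level covariates \(PL_i\):
   \[
   \operatorname{logit}(\pi_i) = \alpha_1 + \gamma\,PL_i, \qquad
   Y_i \sim \mathrm{Poi}(\lambda_i) \text{ w.p. } 1-\pi_i, \qquad
   \log(\lambda_i) = \alpha_2 + \beta\,PL_i,
   \]
   with \(Y_i = 0\) with probability \(\pi_i\). Both components share one
   covariate set. The *excess coding intensity* of a visit is the residual
   against the mixture mean,
   \[
   \mathrm{ECI}_i = Y_i - (1-\pi_i)\lambda_i ,
   \]
   negative when coding falls below the patient-mix expectation.
2. **Facility stage.** ECI is regressed (ordinary least squares, intercept
   included, one row per visit) on facility-level covariates \(FL_i\),
   treating \(\mathrm{ECI}_i \sim N(\theta\,FL_i, \sigma^2)\), and the
   *adjusted* residual is
   \[
   \mathrm{AECI}_i = \mathrm{ECI}_i - \hat\theta\,FL_i .
   \]
   AECI is exactly the OLS residual: it sums to zero and is orthogonal to
   every facility design column, so any remaining per-facility mean AECI is
   idiosyncratic behavior unexplained by either adjustment layer.

ECI supports comparisons where facility-level differences should *not* be
adjusted away (e.g. payment); AECI supports comparisons where they should
(e.g. peer benchmarking). Aggregations — per-facility means and ranks,
means by Census division and calendar quarter, monthly profiles with a
one-way F test for admission-month association — are the reporting surface.

## The synthetic cohort

All testing runs on a synthetic claims generator
(`make_default_config()`, `generate_facilities()`, `generate_visits()`)
that emulates a 2019 U.S. hip/knee arthroplasty inpatient cohort:
categorical marginals with roughly 60% female, 84% White, 85% MS-DRG 470,
40% Medicare Traditional; length of stay `1 + lognormal` with mean about
2.5 days; an AHRQ tract summary index drawn Beta(1.5, 1.5) (mean 0.5,
SD 0.25); admission months with mild January/October excess. The outcome
is drawn from the ZIP truth itself, so every downstream stage can be
validated against known parameters.

Generator design choices, made once:

* **Effect placement.** True effects sit on sex, race, log length of stay
  and the AHRQ index, at incidence-rate-ratio / odds-ratio scales typical
  for this cohort (IRR 0.87–1.43, OR 0.93–1.16); the remaining claim
  fields are generated with realistic marginals but carry no effect, so
  the default truth is exactly recoverable from the default ~10-column
  patient design. Consequences: the generator does not emulate the very
  large MS-DRG revision/bilateral effects seen in real data, and the
  default RMSE reduction from risk adjustment is modest (a few percent)
  rather than the ~20% achievable when strong severity covariates carry
  signal. Tests therefore assert the *direction* of the RMSE improvement,
  not a magnitude.
* **Intercepts.** \(\alpha_1 = \log 0.46\) (reference-visit odds of a
  structural zero) and \(\alpha_2 = \log 0.46 + 0.3445\); the additive
  calibration makes the simulated cohort mean land at 0.55 additional
  procedures given the covariate distributions.
* **Unidentifiable slivers.** The real cohort's 0.01% "Unknown" sex level
  is not emulated: at synthetic scale it draws 0–5 visits, which makes its
  zero-component coefficient quasi-separated by construction. Separation
  handling is instead exercised by dedicated degenerate fixtures.
* **Facility effects.** The generative truth for facilities is a
  multiplicative shift on \(\lambda\): `rate_shift` mode adds
  \(\theta\,FL + u_f\), \(u_f \sim N(0, \mathrm{sd}^2)\), to the log rate.
  This keeps counts integer and nonnegative; it also means facility
  recovery tests assert sign and ordering of effects, not magnitudes,
  since ECI responds to a shift through \((1-\pi)\lambda(e^{\delta}-1)\).
* **Seasonality.** A single sinusoid on the log rate with its trough in
  August, amplitude 0 by default; applied whenever the amplitude is
  positive, independently of the facility-effect mode.
* **Independence.** Patient covariates are drawn independently of each
  other and of facilities; within-facility patient-mix correlation is not
  emulated (nothing in the cohort description pins it down). Passing tests
  therefore demonstrate correctness of the *method*, not robustness to
  confounded patient routing.
* **Reproducibility.** One root seed is split into fixed substreams per
  table, so enlarging the visit table never perturbs the facility draws,
  and identical configurations give byte-identical artifacts.

## Preprocessing

Fixed order in `preprocess_visits()`: natural-log length of stay (stays
\(\le 0\) become missing), complete-case filter (no imputation anywhere),
then single-pass rare-category collapsing. Levels with observed frequency
*strictly* below 0.1% (configurable) merge into an existing `Other` level
or a new `Other (collapsed)`; the inequality is strict so a level at
exactly 0.1% survives, and frequencies are computed once — merges never
cascade. `sex` is protected from collapsing by default, matching the
convention of reporting its rare levels as-is. Each merge is recorded in a
`category_map` that can replay the collapse exactly on new data.

Design matrices are reference-coded from a frozen `design_spec` (variable
order fixed, levels lexicographic within variable, intercept first), so
coefficient vectors are stable across runs. A reference level that is
absent from the data is an error in `encode_design()` — the contrast would
be undefined; `run_pipeline()` optionally substitutes the modal observed
level (all residual quantities are invariant to the reference choice) and
prunes exactly-aliased facility columns, which arise in small synthetic
cohorts where two rare levels can occur at the same single facility.

## Numerical choices in the ZIP fit

* Likelihood: zeros contribute
  \(\log(\pi + (1-\pi)e^{-\lambda})\) evaluated through a log-sum-exp
  identity; positives use \(\log(1-\pi) - \lambda + y\log\lambda -
  \log\Gamma(y+1)\). The analytic score is exact and is verified against
  central finite differences.
* Optimization: BFGS on the joint parameter vector (zero block from a
  logistic regression of \(1\{y=0\}\), count block from a Poisson
  regression on the positive counts, as starts), then Newton polishing
  with step halving until the score sup-norm falls below `tol` (default
  `1e-6`, `max_iter` 500). The fitted log-likelihood never falls below the
  start's; non-convergence warns and is flagged, never silent.
* Information and covariance: observed information by central finite
  differences of the analytic score; inverted through an
  eigendecomposition whose small (or slightly negative, from
  finite-difference noise) eigenvalues are floored at `1e-10` times the
  largest. Quasi-separated directions — a level perfectly predicting a
  positive count drives its zero-component coefficient toward \(-\infty\)
  along an asymptotically flat likelihood — thus get very large finite
  Wald variances instead of a singular solve, and the same pseudo-solve
  lets Newton run the flat direction out to the score tolerance.
* Inference: Wald intervals on the log/logit scale, exponentiated into
  IRRs (count block) and ORs (zero block). Coefficients whose estimate or
  standard error exceeds 15 on the log scale are `separation_flag`ged and
  displayed with a capped `0–Inf` interval rather than astronomical
  bounds. No penalization is applied; boundary estimates are reported as
  such.

The facility stage is plain QR least squares with \(t\)/\(F\) inference at
\(n - p\) degrees of freedom. Because each visit is a row, standard errors
ignore within-facility clustering — a deliberate property of the
two-stage design (the residual metrics are unaffected; only the facility
p-values are anti-conservative under clustering). Normality of ECI is used
only for this inference, never enforced or tested.

## Problem sizes and what the tests show

The test suite validates, at sizes chosen to keep full runs routine on a
single CPU: likelihood/score oracles at \(n \le 100\); coefficient
recovery on 20 replicates of 50,000 visits (aggregate 3-standard-error
coverage at least 95%); the Poisson limit at 50,000 visits (predicted
means within 1% of a `glm` Poisson fit); exact AECI orthogonality
identities; facility-signal recovery with ±20% rate shifts across 50
facilities of 1,000 visits (Spearman > 0.8 between per-facility mean ECI
and the true shifts, and ≥ 80% shrinkage of the covariate-attributable
group difference after adjustment); and month-association calibration
(type-I error within two binomial standard errors of 5% across 200 null
replicates; power above 80% against an August trough of amplitude 0.1 at
50,000 visits). Seasonality replicates form ECI from the known generator
expectation rather than refitting the ZIP model each time: this isolates
the F test's calibration from estimation noise and is the package's
declared testing condition.

## Limitations

* The facility stage is not a hierarchical model: no shrinkage toward the
  grand mean for small facilities, and no cluster-robust errors.
* One shared covariate set for both ZIP components; no zero-inflated
  negative binomial or hurdle alternative.
* Multicollinearity among claim covariates perturbs individual
  coefficients but not the residual metrics; interpret single coefficients
  cautiously.
* Synthetic categories are opaque labels: no ICD-10-PCS strings, DRG
  grouper logic or payment amounts are simulated.
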