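---
title: "Case/non-case disproportionality analysis with pvror: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case disproportionality analysis with pvror: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvror)
```

## The problem

Spontaneous-reporting pharmacovigilance databases collect individual case
safety reports (ICSRs): one report describes one patient, the drugs they were
taking (with a causality role assigned by the reporter) and the adverse
events observed, coded as MedDRA-style preferred terms (PTs). Such databases
have no denominator — nobody knows how many treated patients did *not*
generate a report — so incidence cannot be estimated. What can be estimated
is *disproportionality*: whether reports mentioning a drug of interest
mention a particular adverse event more often than the other reports do.

`pvror` implements the case/non-case design for this question, motivated by
the study of antidepressant classes and delirium reporting in adults aged 65
or over. Reports of the event of interest are "cases", all other reports are
"non-cases", and exposure is the mention of the drug or drug class in any
role (suspected, concomitant or interacting — restricting to suspected drugs
would condition on the reporter's causal judgment, which is part of what is
being measured).

## The statistic

For a 2×2 table with `a` exposed cases, `b` unexposed cases, `c` exposed
non-cases and `d` unexposed non-cases, the crude reporting odds ratio is

$$\mathrm{rOR} = \frac{ad}{bc},$$

with Woolf's standard error of the log odds ratio,
$\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$, and the 95% confidence
interval $\exp(\log \mathrm{rOR} \pm 1.96\,\mathrm{SE})$.

The adjusted r-OR comes from a multivariate logistic regression of case
status on the exposure indicator(s) and the adjustment covariates; the
reported estimate is $\exp(\hat\beta)$ for the exposure term with the Wald
interval $\exp(\hat\beta \pm 1.96\,\widehat{\mathrm{SE}}(\hat\beta))$. For a
single binary exposure and no covariates the logistic model is saturated and
the two routes coincide *exactly*: $\exp(\hat\beta) = ad/bc$ and the Wald
variance equals Woolf's $1/a+1/b+1/c+1/d$. The test suite checks this
identity to 10⁻⁶ on random tables; it is the package's main internal oracle.

**Signal rule.** An estimate is a *signal* if and only if the lower 95%
bound exceeds 1. Estimates below 1 are never reported as protective:
case/non-case analysis compares reporting odds, not risks, and a deficit of
reports is uninterpretable. `classify_signal()` therefore returns
`no_signal` for any interval whose lower bound is ≤ 1.

**Zero cells and low counts.** When any cell of the 2×2 table is zero the
Haldane–Anscombe correction adds 0.5 to all four cells before estimation
(configurable to `none`, which then raises an error instead). Estimates with
fewer than 10 exposed cases carry a `low_count_flag`; they are flagged,
never suppressed.

## Cohort construction

* **Eligibility.** Reports with recorded age ≥ 65 years (inclusive). Reports
  with missing age are excluded and counted in the exclusion log.
* **Complete case.** Sex is the only covariate with missing values in this
  design; reports missing it are dropped. A warning is emitted when more
  than 1% of reports are dropped for a variable — the conventional level at
  which imputation would be considered instead. Missing region is kept as
  its own `"Unknown"` level rather than excluded, since region is only an
  adjustment factor.
* **Outcome.** The primary composite definition of delirium covers the PTs
  *Delirium*, *Confusional state* and *Disorientation*, with exact
  canonicalized matching (trimmed, internal whitespace collapsed,
  case-insensitive). Three sensitivity definitions bracket it — (i) drops
  *Disorientation*, (ii) adds *Circadian rhythm sleep disorder*, (iii)
  further adds *Hallucinations* — and nest: (i) ⊆ primary ⊆ (ii) ⊆ (iii).
  Full MedDRA hierarchy traversal is out of scope; definitions are flat,
  configurable PT sets.
* **Exposure.** Six antidepressant classes mapped by drug name and/or ATC
  prefix: NSMRI = N06AA, SSRI = N06AB, MAOI = N06AF ∪ N06AG; SNRIs and
  alpha-2-adrenergic receptor antagonists have no ATC level of their own
  (both live in N06AX), so they are enumerated by name and the remaining
  N06AX members form the "other antidepressants" class. This membership is
  a package default, declared configurable rather than asserted as the only
  defensible split; the validator enforces pairwise disjointness at the
  drug-name level. A packaged drug-name → ATC dictionary (~75 entries)
  stands in for the licensed WHODrug dictionary; it covers every drug the
  analyses and fixtures mention.
* **Adjustment set.** Age band (65–74 vs 75+), sex, region (most frequent
  level as reference), four co-prescription indicators by ATC prefix
  (opioids N02, antipsychotics N05A, anxiolytics N05B, hypnotics N05C) and
  seventeen illness indicators, each matched by a single PT using MedDRA
  spellings (*Hyponatraemia*, *Hypoglycaemia*, ...). Constant columns are
  dropped and logged; a constant exposure column is an error.
* **Frequent drugs.** The per-drug analysis covers antidepressants mentioned
  in strictly more than 1000 reports (configurable; counted per report, not
  per row, before any case restriction).

### Design choices where the design was open

* **Joint vs separate exposure models.** The primary analysis defaults to
  one joint model carrying all six class indicators (`joint_exposure_model
  = TRUE`), which matches an adjustment set listing all classes together;
  fitting one model per class is available as a switch. Per-drug models
  carry the drug indicator plus the *other* five class indicators; the
  drug's own class indicator is excluded because it would double-count the
  drug's own exposure.
* **Exposure–confounder overlap.** When an exposure's drugs fall inside a
  co-prescription confounder's ATC prefix (the positive-control exposure
  N02AA sits inside the opioid confounder N02), the confounder column is
  computed excluding the exposure's matching drug entries. Otherwise the
  confounder would partially re-encode the exposure and inflate
  collinearity by construction. The exclusion is logged in the design
  matrix notes.
* **Reference levels** (age 65–74, sex F, most frequent region) are chosen
  for numerical stability; exposure estimates are invariant to this choice
  (tested), so nothing of substance depends on it.
* **Concomitant outcome.** The delirium-with-hyponatremia analysis defines
  the outcome as a primary-definition case that also reports
  *Hyponatraemia*; the hyponatremia confounder is removed from the
  adjustment set because it is part of the outcome. Classes with zero
  exposed outcome events cannot enter the logistic model (their coefficient
  diverges); their rows keep the corrected crude estimate and are flagged.
* **No multiplicity correction** across exposures, matching standard
  practice for this design; the export manifest records the number of tests
  performed so a reader can apply one.

## Numerical choices

* Logistic models are fitted by iteratively reweighted least squares
  (`stats::glm.fit`, binomial family) with relative deviance tolerance
  1e-8 and at most 100 iterations, followed by a few Newton–Raphson polish
  steps on the full likelihood until the coefficient step falls below
  1e-12. The polish costs microseconds and removes the ~1e-6·SE coefficient
  error left by a deviance-based stop, which would otherwise blur the exact
  saturated-model identity above. The covariance matrix is the inverse
  observed information at the polished optimum.
* Separation (complete or quasi-complete) is reported as an error naming
  the diverging column, detected as |β| > 15 on the log-odds scale together
  with boundary fitted probabilities. Firth-type penalization is a possible
  extension, deliberately not implemented.
* The 95% quantile is 1.96 exactly, for both Woolf and Wald intervals, so
  that the two coincide on saturated models; the difference from the exact
  normal quantile (1.959964) is two orders of magnitude below the 2-decimal
  reporting precision.
* Variance-inflation factors are classical VIFs on the dummy-coded design:
  VIF_j = 1/(1−R²_j) from the OLS regression of column j on the others.
  Exactly collinear columns are reported with infinite VIF and named;
  VIF > 5 is flagged. Generalized VIFs for multi-level factors are not
  computed — the design matrix is already dummy-coded, and the per-column
  diagnostic is what the flag threshold refers to.
* Exports format numbers with 15 significant digits, making `results.csv`
  byte-identical across runs with the same input and configuration.

## The synthetic ICSR generator

Real pharmacovigilance databases are proprietary, so the package ships a
generator whose ground truth is known by construction. For each report
$i$ (all on the logit scale):

$$Z_{ij} \sim \mathrm{Bern}(\pi_j), \qquad
  X_{id} \sim \mathrm{Bern}(\mathrm{logit}^{-1}(\alpha_d + \textstyle\sum_j \delta_{dj} Z_{ij})),$$
$$Y_i \sim \mathrm{Bern}(\mathrm{logit}^{-1}(\beta_0 + \textstyle\sum_d \beta_d X_{id} + \sum_j \gamma_j Z_{ij})), \qquad
  H_i \sim \mathrm{Bern}(\mathrm{logit}^{-1}(\eta_0 + \textstyle\sum_d \eta_d X_{id})),$$

where $Z$ are confounder indicators (each materializing as an event PT or a
concomitant drug entry), $X$ drug exposures, $Y$ case status (a case reports
one delirium PT drawn from configurable term weights, default 0.3/0.5/0.2
for *Delirium*/*Confusional state*/*Disorientation*) and $H$ hyponatremia
(adding the PT *Hyponatraemia*). Reports whose event list would otherwise be
empty draw 1–3 background PTs from a 20-term vocabulary, so every report has
at least one event. Exposed drugs receive a reporter role with probabilities
0.70/0.25/0.05 (suspect/concomitant/interacting); roles only exercise the
parser, since exposure is role-agnostic downstream. All randomness comes
from one seeded stream with a fixed draw order (demographics → confounders →
drugs → case → hyponatremia → events), giving byte-identical output for
identical configurations.

This construction makes $e^{\beta_d}$ *exactly* the conditional odds ratio
that the adjusted analysis estimates — a clean recovery target — and
$e^{\eta_d}$ the hyponatremia-pathway odds ratio.

**Demographics** default to the large-database profile for this age range:
41% of reports in the 65–74 band (ages uniform within band; the 75+ band is
truncated at 95, an arbitrary documented bound that banded analyses never
see), 54% female, 0.5% missing sex, five world regions with fixed weights.

**Presets.** Five named scenarios cover the validation needs:

| preset | truth | purpose |
|---|---|---|
| `null` | all effects 0, 10% case rate | signal-rule calibration |
| `single_effect` | one drug, OR 3, 20% exposure, 8% baseline case rate | parameter recovery |
| `confounded` | direct OR 1; confounder π = 0.30 with γ = δ = log 3 | crude vs adjusted contrast |
| `study_like` | six classes, ORs 1–3; opioid and dementia confounding; SSRI hyponatremia pathway (OR 4) | end-to-end shape and subgroup tests |
| `controls` | positive-control opioid OR 3, negative-control bisphosphonate OR 1 | control-harness validation |

The free parameters (baseline prevalences on the logit scale, confounder
prevalence 0.30, case-rate intercepts logit(0.08–0.10)) were fixed once at
magnitudes typical of elderly-population ICSR data — opioid co-prescription
in roughly a quarter of reports, single-drug exposure prevalences of 0.5–5%
per drug, case events around a tenth of reports — and are part of the
scenario definitions, not tuning knobs. A back-of-envelope power check for
the `confounded` scenario (population crude OR ≈ 1.33, |z| ≈ 5 at
n = 20,000) shows the crude/adjusted contrast is identifiable at the sizes
the validation uses.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: duplicate reports, reporting-delay
dynamics and secular trends, under-reporting (including the differential
under-reporting of hypoactive delirium), country-specific reporting
cultures, dose/date arithmetic, free-text coding noise, and the full MedDRA
and WHODrug vocabularies. Tests against the generator validate the
*estimators and the pipeline*, not the epidemiology of any particular
database.

## Validation sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: 50
random 2×2 tables for the oracle identity; 2,000 replicates of n = 2,000
for Woolf coverage at OR 2; 2,000 replicates of the `null` preset at
n = 10,000 for signal-rule calibration (nominal 2.5% one-sided rate); 200
replicates each of `confounded` (n = 20,000) and `single_effect`
(n = 50,000); and 100 replicates of `controls` (n = 30,000). These sizes
put Monte-Carlo error comfortably inside the acceptance bands (e.g. ±0.35
points on the null signal rate) while keeping a full run within minutes.

## Known limitations

* Wald/Woolf intervals are asymptotic; with very small cells the
  Haldane–Anscombe correction keeps estimates defined but coverage is no
  longer nominal — hence the low-count flag rather than a claim of
  validity.
* No exact logistic regression, Firth correction, or Bayesian
  disproportionality statistics (IC/BCPNN, EBGM); the lower-bound rule on
  the adjusted r-OR is the only signal criterion.
* The confounder dictionary maps each illness to exactly one PT; real
  term families (e.g. "unspecified infections") are broader, and the
  dictionary is configurable for that reason.
* r-ORs quantify reporting disproportionality, not risk. Nothing in this
  package supports causal or incidence statements.
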