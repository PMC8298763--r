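---
title: "A medication-based algorithm for advanced Parkinson's disease in claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A medication-based algorithm for advanced Parkinson's disease in claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apdclaims)
```

## The problem

Administrative claims record diagnoses, procedures and dispensed drugs
for very large populations, but Parkinson's disease (PD) diagnosis codes
carry no stage information, and clinical rating scales (Hoehn & Yahr)
never reach a claims table. Studies of *advanced* PD (APD) therefore need
a proxy. Prior proxies keyed on medical services — assistive-device or
skilled-nursing claims — which capture late physical disability but miss
earlier advanced disease and depend on Part A/B data that many
stakeholders (stand-alone drug plans, pharmacies, benefit managers) do
not hold.

`apdclaims` implements a pharmacy-only proxy: progressive
neurodegeneration pushes levodopa requirements upward, so *sustained high
dosing* marks advanced disease. Concretely, a patient is assigned APD if
any 30-day average of their daily levodopa-equivalent dose (LED) strictly
exceeds 1000 mg/day during the study year; everyone else is
mild-moderate (≤ 1000 mg/day). The threshold is chosen to favour
specificity over sensitivity: patients flagged by it are very likely to
have advanced disease, while some advanced patients who cannot tolerate
high doses will be missed.

## From dispensing events to daily dose

A pharmacy claim states a fill date, a days supply, a quantity of units
and a strength (mg of active moiety per unit; for carbidopa/levodopa
combinations, the levodopa moiety). Each claim is spread at its own rate

$$\text{rate} = \frac{\text{quantity} \times \text{strength}}{\text{days supply}} \quad \text{mg/day}$$

over a half-open interval of `days_supply` days from the fill date (a
30-day supply filled on day $d$ covers $d \dots d+29$). Claims data do
not say what patients actually swallowed, so two conventions are
config-exposed rather than guessed:

* **Overlapping same-drug refills** (`overlap_policy`). Default
  `push_forward`: an early refill begins coverage the day after the
  previous supply runs out, so stockpiling extends coverage instead of
  doubling the apparent dose — the alternative would misclassify early
  refillers as high-dose patients. `sum_overlap` (supplies add) is
  available for sensitivity analysis. Different drugs always sum.
* **Boundary handling** (`lookback`). Supply extending past the period
  end is truncated. Fills dated before the period start are ignored by
  default (a single-calendar-year study has no earlier dispensing data);
  with `lookback = TRUE` their in-period days count.

Both choices preserve mass: reconstructed mg per drug never exceeds
dispensed mg, with equality when no supply crosses a period boundary —
a property the test-suite checks against an event-driven pill-stock
simulation that consumes one day of supply per calendar day.

## LED conversion

Patients take drugs besides levodopa, so daily doses are mapped to a
common levodopa-equivalent scale using the per-drug factors from the
standard systematic-review conversion algorithm for oral anti-PD
medication (shipped, editable, in `inst/extdata/drug_reference.yaml`):
levodopa IR ×1.0, levodopa CR ×0.75, pramipexole ×100, ropinirole ×20,
rotigotine ×30, rasagiline ×100, selegiline ×10, amantadine ×1, and so
on. COMT adjuncts are special: entacapone contributes
$0.33 \times$ the *concurrent* daily levodopa dose (tolcapone 0.5),
computed after the levodopa channel, and contributes nothing on days
with no levodopa supply.

Two channels result: plain levodopa mg/day (used by the levodopa-dose
sensitivity rules) and LED mg/day. Note that with the CR factor 0.75 a
patient on controlled-release levodopa alone has LED *below* their
levodopa channel; the frequently quoted invariant LED ≥ levodopa holds
only for factor tables with factors ≥ 1 on levodopa-class drugs, and the
package asserts it only under that condition.

## Classification

For a rule (channel, threshold $T$, window $w = 30$), every run of $w$
consecutive days fully inside the period is averaged (a sliding-sum
implementation, oracle-checked against explicit per-window means to
1e-9 relative error; zero-dose days count). The patient is APD iff the
maximum window mean is **strictly** greater than $T$ — exact ties go to
mild-moderate, because the mild-moderate stratum is defined as
≤ 1000 mg/day. One qualifying month suffices by design: a high dose that
was later reduced still signals advanced disease. Four named rules ship:
LED > 1000 (primary), levodopa > 1000, levodopa > 800, LED > 800.
Windows slide by one day with no calendar alignment.

Useful consequences, enforced as tests: lowering the threshold never
shrinks the APD set; when LED ≥ levodopa pointwise, levodopa-rule APD is
a subset of LED-rule APD at equal threshold; every cohort member gets
exactly one status per rule.

## Cohort, indicators, regressions

Inclusion mirrors a fee-for-service Medicare design: a PD diagnosis
claim (ICD-9-CM 332.0, inpatient or outpatient), age ≥ 65, continuous
Parts A+B+D enrollment (12 monthly flags), alive through the period, at
least one levodopa claim, and complete covariates. Age is evaluated at
the period start (the natural reference for a calendar-year study; the
reference date is configurable since conventions vary). Every filter is
a pure per-patient predicate, so the final cohort is independent of
filter order; only the funnel counts depend on it.

Nine binary severity indicators are extracted from medical claims by
configurable code sets: DBS procedure codes, fall and hallucination
diagnoses, DME claims for a walker or wheelchair (Hoehn–Yahr stage 4
proxies) or a specialty bed (stage 5 proxy), any dementia diagnosis,
skilled-nursing-facility care and hospice care. Matching is exact or by
code prefix on normalized codes (uppercased, dots stripped), restricted
to the claim setting where the indicator demands one (DME, SNF,
HOSPICE). One claim may trigger several indicators. The shipped lists
are illustrative — the indicators' defining code sets are never printed
in the claims literature in reusable form — and all package tests use
clearly synthetic codes instead of the defaults.

Validation regresses each indicator on APD status (mild-moderate as
reference) with adjustment for age band (reference 65–69), sex
(reference female), race (reference white), region (reference
northeast), RxHCC risk score (entered linearly; the score is consumed as
a given covariate, never computed from diagnoses) and neurologist care.
Estimation is the binomial GLM via iteratively reweighted least squares
(tolerance 1e-10, 100-iteration cap); odds ratios are
$\exp(\hat\beta_{\text{APD}})$ with Wald 95% CIs
$\exp(\hat\beta \pm 1.96\,\widehat{SE})$, which are exactly symmetric on
the log scale. Wald p-values are the default with a likelihood-ratio
option; per-indicator tests are reported unadjusted for multiplicity, as
is conventional for this kind of descriptive validation. Perfect
separation or non-convergence is flagged (`converged = FALSE`), never
silently estimated. Descriptive comparisons use chi-square tests for
categorical variables and a t-test for the risk score, with percentages
rounded half-up to one decimal to match publication convention.

## The synthetic generator

Real Medicare claims cannot ship with a package, so the generator
produces structurally faithful tables with known ground truth:

* **Latent severity** is Bernoulli(`apd_fraction`, default 0.2 — the
  share reported for this algorithm in the aged Medicare PD
  population).
* **Trajectories are dispensing events, not daily series**: 30-day
  supplies refilled with ±3 days of uniform jitter, quantities rounded
  to whole units, so the reconstruction engine is genuinely exercised.
  Advanced patients draw a daily levodopa target in 1200–1500 mg/day,
  mild patients 300–600 mg/day plus (40% of patients) a dopamine
  agonist worth 150–300 LED mg/day; 30% of advanced patients add
  entacapone. These defaults make the strata separable at the
  1000 mg/day threshold *by construction* (a full 30-day supply at the
  advanced rate always yields one fully covered window above threshold;
  the richest mild trajectory stays below it), which is what lets the
  round-trip check demand ≥ 99% classifier/latent agreement. Configs
  that violate separability are rejected before generation.
* **Covariate marginals** default to the published overall column of an
  aged Medicare PD cohort: age bands 11.5 / 19.3 / 22.9 / 46.3%, 48.5%
  male, race 87.6 / 4.6 / 7.7%, region 19.6 / 26.7 / 36.5 / 17.1%, risk
  score ~ Normal(1.48, 0.46) clamped to [0.72, 6.30], neurologist-visit
  probability 0.663 (mild) / 0.842 (advanced). They are presentation
  defaults, not population estimates.
* **Indicators** are drawn from per-indicator logistic models:
  baseline prevalence at the published mild-moderate rates, true odds
  ratios on the latent label defaulting to the published adjusted
  estimates (DBS 2.96 … dementia 1.21), plus a small age trend
  (log-OR 0.095 per band) so that covariate adjustment is doing real
  work in the recovery checks. Claim codes are drawn from synthetic
  code sets (`inst/extdata/synthetic_code_sets.yaml`).
* **Excludable patients** (default 10%) each violate exactly one
  inclusion criterion — under 65, an enrollment gap, death during the
  year, no levodopa, or missing race — so the attrition funnel can be
  checked count-for-count against generator bookkeeping.

Generation is byte-deterministic given the seed (Mersenne-Twister with
inversion normals; generator tag `apdclaims-synthetic-1` in the ground
truth).

What passing these tests does *not* show: real claims have dose
titration within the year, therapy switching, partial adherence,
correlated comorbidity and indicator co-occurrence, none of which the
generator models. The synthetic checks validate the *mechanics*
(reconstruction arithmetic, window logic, funnel accounting, estimator
calibration), not the clinical validity of the 1000 mg/day threshold,
which can only be established against medical records.

## Numerical choices and scales

Rolling means use a sliding sum (long-double accumulation); threshold
comparisons are strict with no tolerance, since reconstructed rates are
exact rationals of the claim fields. Percentages are rounded half-up
(with a binary-representation epsilon) to one decimal. The
parameter-recovery simulation runs 200 replicates of n = 20,000 at true
ORs {1.2, 2.0, 3.0} (baseline prevalence 0.15); the end-to-end check
uses n = 10,000 patients, sizes at which binomial noise on the APD share
is ~0.4 percentage points and log-OR standard errors are ≈ 0.04–0.05 —
large enough for meaningful calibration, small enough to run routinely.
The classifier oracle suite uses 1,000 piecewise-constant random series
whose segment levels straddle both thresholds on both channels.

## Limitations

Dose frequency (≥ 5 doses/day, itself an APD marker) cannot be inferred
from claims and is not modelled. Single-year windows miss advanced
patients whose dose was raised and lowered in different years;
device-based indicator claims only capture equipment newly obtained
during the year. Infusion therapies and DBS dosing are out of scope of
the LED table. The algorithm will misclassify dose-intolerant advanced
patients as mild-moderate (low sensitivity by design) and
tremor-dominant medication-resistant mild patients as advanced. The
RxHCC score is taken as supplied; no Medicare Advantage logic exists.
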