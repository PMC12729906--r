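---
title: "Methods: two-phase stewardship cost-of-resource-use analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase stewardship cost-of-resource-use analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspcost)
```

## The question the package answers

Hospital antimicrobial stewardship programs (ASPs) audit and restrict the
use of broad-spectrum and high-cost antimicrobials. Whether a maturing
program is *paying for itself* is an economic question: between an early
("preliminary") and a mature ("developed") program phase, how did the
monetary value of resource use change? `aspcost` implements a
cost-of-resource-use comparison from the hospital perspective, built from
four measures:

1. **Cost saving — antimicrobial consumption.** Consumption is measured in
   defined daily doses (DDD): for a course, grams per day times duration in
   days, divided by the drug's DDD grams (the assumed average adult
   maintenance dose per day for the main indication). Cost is consumption
   priced per DDD (or, optionally, summed per-course acquisition cost).
2. **Cost saving — resource utilization.** Micro-costing: each resource
   event (cultures, laboratory tests and biopsies before and after therapy
   start, IV-to-oral switch events within the first three days of
   antibiotic therapy) is multiplied by its unit cost.
3. **Cost avoidance.** Rule-based monetization of adverse outcomes:
   hospitalization as initial length of stay times the bed-day cost;
   30-day readmission stays priced the same way; a fixed C. difficile
   infection (CDI) recipe — oral vancomycin 125 mg four times daily for ten
   days plus one diagnostic culture; and adverse drug events (ADEs) costed
   as two extra bed-days when implicated with an injectable antimicrobial,
   one when oral.
4. **Operational cost.** Staffing time — daily data collection, daily
   clinical rounds, monthly committee meetings — valued at hourly rates and
   annualized: per role, `headcount x rate x ((daily hours) x working days
   + meeting hours x 12)`.

`compare_periods()` differences the two phases category by category
(positive favors the developed phase) and enforces the decomposition
identity `net = (DDD saving + resource saving) + avoidance + operational
saving`, both in totals and per patient. Per-patient values divide each
phase by its **own** patient count before differencing; the net total is
never divided by a pooled n, because the two phases' denominators differ
(81 vs 105 in the motivating study).

## Eligibility model

Episodes enter the analysis when at least one antimicrobial course is for
a targeted agent (18 restricted drugs, `targeted_drugs()`), starts within
3 days of admission, and runs at least 48 continuous hours; ICU episodes
are excluded because critical-care protocols bypass stewardship review.
Choices made where the rules are genuinely open:

* Admission is day 0 and the 3-day window is **inclusive** (start days
  0–3). Sites wanting a stricter reading can lower `max_start_day`.
* "The same antimicrobial for 48 consecutive hours" is operationalized as
  a single course record with duration ≥ 2 days. The data model stores
  courses, not individual administrations, so gap-merging of split course
  records is not attempted; whether the 48-hour rule should apply per drug
  or per regimen when drugs are switched is unspecified in the source
  rules, and the per-course reading is this package's choice.
* The decision cascade is ordered (targeted drug → start window → 48-hour
  rule → ICU exclusion) and the reason code names the first failed rule,
  so ineligibility reports are deterministic.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_start_day` | 3 | days | inclusive start window |
| `min_continuous_hours` | 48 | hours | continuity requirement |
| `bed_day` cost | input | QAR/day | dominant cost driver |
| `vancomycin_125mg_dose`, `cdi_diagnostic_culture` | input | QAR | the CDI recipe (40 doses + 1 culture) |
| ADE extra days | 2 / 1 | days | injectable / oral rule |
| `working_days_per_year` | 365 | days | data collection and rounds are daily activities; weekday-only sites pass 260 |
| `qar_per_usd` | 3.64 | — | the riyal's USD peg |
| one-way / multivariate uncertainty | ±20% / ±10% | — | triangular half-widths |
| iterations | 1000 | — | Monte Carlo size |

Every price lives in `unit_cost_table()` — no monetary constant is baked
into code. DDD values are likewise configuration: the bundled
`ddd_reference.csv` carries WHO-style values with provenance comments, and
the reference is versioned, so production sites should pin their own.

## Sensitivity analysis

Both the one-way and the multivariate analyses are Monte Carlo: inputs are
drawn from a symmetric triangular distribution (min = base×(1−pct), mode =
base, max = base×(1+pct); `pct = 0` degenerates to the base point mass),
1000 iterations by default, with an explicit seed recorded in every
result. A deterministic low/base/high endpoint mode is available for the
one-way analysis but is not the default. The probability "in favor of the
developed phase" is the fraction of iterations with net reduction strictly
greater than zero; exact ties count as not in favor.

The tornado ranking regresses standardized outcomes on standardized draws
and orders inputs by absolute standardized regression coefficient,
breaking ties by input name; a zero-variance input is reported with
coefficient 0 and a warning.

`reconstruct_cost_model()` builds the shipped three-input base case from
two aggregate phase ledgers:

* **hospitalization (bed-day) cost** scales every bed-day-priced line —
  hospitalization, readmission and ADE extra stay — in both phases,
  consistently with how the costing engine prices them;
* **initial length of stay** scales the hospitalization lines;
* **ADE extra days** scales the ADE lines. This input varies the 2/1
  day-multipliers (and hence the resulting cost), not an independent cost
  lump; the alternative reading (varying the ADE cost directly) is
  equivalent up to the bed-day interaction.

A consequence worth stating plainly: because the hospitalization term is
the *product* of the bed-day price and the length of stay, those two
inputs have almost identical standardized influence on the net outcome
(their true coefficients differ only through the small ADE term, by about
2% on the motivating study's aggregates — and in the direction that puts
the length of stay fractionally ahead). At 1000 iterations the estimated
ranking of those top two inputs is within Monte Carlo noise. Reported
tornado orderings of near-tied inputs should therefore not be
over-interpreted; the robust qualitative facts are that the
hospitalization-cost/LOS pair dominates and the ADE input ranks last.

## The synthetic generator

`default_profiles()` encodes the two study phases: n = 81 vs 105; an
antifungal-heavy drug mix (fluconazole, caspofungin predominant; 8.6%
antibacterial) versus an antibacterial-heavy one (ertapenem,
ciprofloxacin; 94.3%); initial stays with mean ± sd of 34.02 ± 51.21 vs
7.12 ± 10.47 days; CDI incidence 30.9% vs 15.2%; zero readmissions and
zero ADEs in both phases (ADE and readmission probabilities are
profile-adjustable so those costing paths stay testable). Ages, sex mix
and resource-event rates follow the published demographics where stated;
resource-event Poisson means are otherwise plausible values chosen once.

Lengths of stay are drawn from the lognormal matched by moments to the
profile's mean and sd — with sd > mean in the preliminary arm, a
right-skewed family is forced. The LOS is **not** truncated: truncating at
2 days (so that a within-stay course could always reach 48 hours) would
shift the developed arm's mean from 7.12 to about 9.2 days and break
parameter recovery. Instead, eligibility is guaranteed through the course
model: course durations carry a 2-day floor and start days lie in 0–3, and
a course may extend past discharge (the realistic oral step-down case).
Consequently every generated episode passes the default policy, and at
n = 10,000 the empirical LOS moments and event rates recover the profile
values within three standard errors.

What the generator does **not** emulate: correlations between severity and
stay length (e.g. comorbidity–LOS dependence), seasonal admission
structure, drug switching within a course, or ward-level price
heterogeneity. Passing tests on generated cohorts therefore demonstrate
the arithmetic and statistical machinery, not the clinical realism of any
particular site's data.

## Numerical conventions

* All arithmetic at full double precision; rounding (half away from zero,
  `report_round()`) happens only in reports and presentations.
* Ledger conservation — each category total equals the sum of its
  components — is validated to 1e-6 currency units.
* Cohort CSVs are written with 17 significant digits, so write → read is
  exact and two writes are byte-identical; report files carry no
  timestamps, so identical configurations and seeds regenerate identical
  bytes.
* The Shapiro–Wilk normality gate uses α = 0.05 per sample (the gate's
  level is a package choice; the source rules state only the comparison
  α); both samples must pass for the t-test, which is the equal-variance
  Student form by default with Welch behind a flag. The chi-square test is
  uncorrected by default; Yates correction is a flag and moves borderline
  2×2 p-values (e.g. a 0.0065 ↔ 0.0101 shift on the motivating study's
  sex table).
* Seeds are explicit arguments everywhere, and the sampling helpers
  restore the global RNG state.

## Known limitations and internal inconsistencies of published aggregates

When the published aggregate tables of the motivating study are fed
through `compare_periods()` as inputs, two of their printed figures cannot
be reconciled with their own components: the developed-phase avoidance
components sum 290 QAR below the printed total, and the printed net
reduction differs from the sum of its printed category components (the
package computes 13,230,794 QAR where 13,205,840 is printed, and 181,568
vs 180,910 per patient). The package asserts its own decomposition
identity on every input rather than reproducing either printed net. The
operational-cost USD presentation likewise only reproduces when each
phase's USD total is rounded to whole dollars before differencing, which
is how the published table is laid out.

Problem sizes used by the test and acceptance suites — cohorts of 186
(the study structure) down to 4–40 episodes for property tests, 10,000
episodes or draws for parameter-recovery and moment checks, 1000 Monte
Carlo iterations, 1000 null simulations for the type-I error check — are
the package's own choices balancing statistical resolution against a
few-second suite.

## A worked run

```{r demo, eval = FALSE}
cfg <- make_demo_workspace(tempfile("asp-demo"), seed = 7)
res <- run_analysis(cfg)
print(res$cba)
print(res$psa)
res$tornado
```

The demo writes the full report bundle (period ledgers, cost-benefit
table in QAR and USD, cohort statistics, Monte Carlo draws and tornado
table, and a run-info JSON) into the workspace's `reports/` directory.
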