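# aspcost

Cost and resource-use analysis for hospital antimicrobial stewardship
programs (ASPs), in R.

## The problem

Stewardship programs restrict and audit high-cost, broad-spectrum
antimicrobials. Hospital administrations want to know whether a maturing
program is associated with reduced spending on resource use. `aspcost`
implements the pharmacoeconomic comparison between two program phases — an
early ("preliminary") and a mature ("developed") year — from the hospital
perspective, for analysts working with patient-episode extracts and
finance-department unit costs.

The comparison is built from four measures, each computed per phase and
then differenced (positive favors the developed phase):

- **Antimicrobial consumption saving.** Consumption in defined daily doses,
  DDD = (g/day × days) / DDD grams, priced per DDD (or by acquisition
  cost);
- **Resource-utilization saving.** Micro-costing: each culture, laboratory
  test, biopsy (before/after therapy start) and IV-to-oral switch event ×
  its unit cost;
- **Cost avoidance.** Bed-day-priced hospitalization and 30-day readmission
  stays; a fixed C. difficile recipe (oral vancomycin 125 mg × 4/day × 10
  days + one diagnostic culture); adverse drug events as 2 (injectable) or
  1 (oral) extra bed-days;
- **Operational saving.** Annualized staffing time: Σ roles headcount ×
  rate × ((data-collection + rounds hours/day) × working days + meeting
  hours/month × 12).

The net reduction satisfies the decomposition identity
`net = saving_DDD + saving_resource + avoidance + operational`, totals and
per patient (each phase divided by its own n). A Monte Carlo probabilistic
sensitivity analysis propagates triangular input uncertainty
(min = base(1−p), mode = base, max = base(1+p)) through the model, reports
the probability that the net reduction favors the developed phase, and
ranks inputs by standardized regression coefficients (a tornado analysis).
Normality-gated two-sample tests (Shapiro–Wilk → Student t or
Mann–Whitney U) and chi-square/Fisher contingency tests compare the two
cohorts' demographics and outcomes. A seeded synthetic-cohort generator
reproduces the statistical structure of a two-phase oncology ASP study
(n = 81 vs 105, antifungal- vs antibacterial-heavy drug mix, lognormal
stays 34.02 ± 51.21 vs 7.12 ± 10.47 days, CDI 30.9% vs 15.2%) so the whole
pipeline is testable without patient data.

## Worked example

```r
library(aspcost)
cfg <- make_demo_workspace("demo", seed = 7)   # synthetic two-phase workspace
res <- run_analysis(cfg)
print(res$cba)
```

```
Cost-benefit analysis: preliminary (n = 81) vs developed (n = 105)
Sign convention: positive favors developed period 

                                              total QAR                  per patient QAR     
 Cost saving, antimicrobial consumption (DDD)    178,390 (USD    49,008)   2,513 (USD    690)
 Cost saving, resource utilization               -21,080 (USD    -5,791)     150 (USD     41)
 Total cost saving                               157,310 (USD    43,217)   2,663 (USD    732)
 Cost avoidance                               11,373,730 (USD 3,124,651) 153,547 (USD 42,183)
 Operational cost saving                         -80,150 (USD   -22,019)     798 (USD    219)
 Net reduction in monetary spending           11,450,890 (USD 3,145,849) 157,008 (USD 43,134)

Antimicrobial consumption saving: 1451.2 DDDs
```

On this synthetic workspace the developed phase spends 178,390 QAR less on
antimicrobials (antifungal-heavy vs antibacterial-heavy mix), incurs
21,080 QAR *more* on diagnostics in total yet less per patient (the
per-patient column divides each phase by its own cohort size), and avoids
11.4M QAR of hospitalization-driven cost — the shorter developed-phase
stays dominate the net.

```r
print(res$psa)
```

```
Sensitivity analysis (multivariate): 1000 iterations over 3 input(s)
  base-case outcome: 11450890
  outcome mean 11452158 [2.5%: 10213037, 97.5%: 12726212]
  probability in favor of developed period: 100.0%
  conclusion stable (all outcomes share base-case sign): TRUE
```

With ±10% triangular uncertainty on the bed-day cost, the initial length
of stay and the ADE extra-stay multipliers, every one of the 1000
iterations keeps the net reduction positive. `res$tornado` shows the
bed-day-cost/length-of-stay pair dominating (near-identical standardized
coefficients ≈ 0.7, since the hospitalization term is their product) with
the ADE input last (≈ 0).

`run_analysis()` also writes the report bundle — `period_summaries.csv`,
`cost_benefit.csv`/`.md`, `cohort_stats.csv`, `sensitivity_outcomes.csv`,
`tornado.csv`, `run_info.json` — into the workspace's `reports/`
directory; identical configs and seeds regenerate byte-identical files.

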