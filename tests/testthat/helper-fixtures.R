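# Shared fixtures: a tiny drug reference, a tiny price table, and small
# hand-assembled cohorts. Everything is built in code at test time.

tiny_ref <- function() {
  ddd_reference(data.frame(
    drug = c("fluconazole", "ertapenem", "ciprofloxacin", "ciprofloxacin",
             "cefepime"),
    route = c("", "", "oral", "injectable", ""),
    ddd_grams = c(0.2, 1, 1, 0.5, 4)))
}

tiny_costs <- function(scale = 1) {
  unit_cost_table(bed_day = 1000 * scale, culture_test = 160 * scale,
                  lab_test = 100 * scale, biopsy = 500 * scale,
                  iv_to_oral_switch_event = 700 * scale,
                  cdi_diagnostic_culture = 30 * scale,
                  vancomycin_125mg_dose = 2 * scale,
                  cost_per_ddd = c(fluconazole = 7, ertapenem = 20,
                                   ciprofloxacin = 3, cefepime = 5) * scale)
}

# one fully-featured episode with known arithmetic
demo_episode <- function(id = "e1", period = "preliminary", ...) {
  patient_episode(
    id = id, period = period, age_years = 60, sex = "female",
    los_initial_days = 10, cdi = TRUE,
    cultures_before = 2, labs_before = 3, cultures_after = 1,
    labs_after = 4, iv_to_oral_switches = 1,
    courses = data.frame(drug_name = "fluconazole", route = "oral",
                         daily_dose_grams = 0.4, duration_days = 7,
                         start_day = 0),
    ade_events = data.frame(implicated_route = "injectable"),
    ...)
}

# small randomized profile for property tests (fast to generate)
small_profile <- function(period = "preliminary", n = 30) {
  p <- default_profiles()[[period]]
  p$n <- as.integer(n)
  # exercise every costing path, including ADEs and readmissions
  p$ade_prob_injectable <- 0.2
  p$ade_prob_oral <- 0.2
  p$readmission_prob <- 0.15
  p
}

# Independent brute-force accumulation of period totals, written directly
# against the raw tables (no cost_ledger / episode helpers), used as the
# oracle for period_totals on small cohorts.
brute_period_totals <- function(cohort, ref, costs) {
  ep <- cohort$episodes
  co <- cohort$courses
  ad <- cohort$ade_events
  ddd_of <- function(drug, route) {
    t <- ref$table
    hit <- t$ddd_grams[t$drug == drug & t$route == route]
    if (!length(hit)) hit <- t$ddd_grams[t$drug == drug & t$route == ""]
    hit[1]
  }
  ddd_total <- 0
  anti <- 0
  for (i in seq_len(nrow(co))) {
    d <- co$daily_dose_grams[i] * co$duration_days[i] /
      ddd_of(co$drug_name[i], co$route[i])
    ddd_total <- ddd_total + d
    anti <- anti + d * costs$cost_per_ddd[[co$drug_name[i]]]
  }
  resource <- sum(ep$cultures_before * costs$culture_test +
                    ep$labs_before * costs$lab_test +
                    ep$biopsies_before * costs$biopsy +
                    ep$cultures_after * costs$culture_test +
                    ep$labs_after * costs$lab_test +
                    ep$biopsies_after * costs$biopsy +
                    ep$iv_to_oral_switches * costs$iv_to_oral_switch_event)
  avoid <- sum(ep$los_initial_days * costs$bed_day) +
    sum(ifelse(ep$readmitted_30d, ep$los_readmission_days, 0) * costs$bed_day) +
    sum(ep$cdi) * (40 * costs$vancomycin_125mg_dose +
                     costs$cdi_diagnostic_culture)
  if (nrow(ad)) {
    avoid <- avoid + sum(ifelse(ad$implicated_route == "injectable", 2, 1)) *
      costs$bed_day
  }
  list(ddd_total = ddd_total, antimicrobial = anti,
       resource_total = resource, avoidance_total = avoid)
}

# printed-aggregate period summaries of the two study phases, used by the
# acceptance checks; all numbers are inputs read off the published tables
printed_summaries <- function() {
  pre <- period_summary("preliminary", 81, cost_ledger(
    antimicrobial_ddd_cost = 1569699,
    ddd_total = 1,
    resource = c(cultures_before = 640, labs_before = 24730,
                 biopsies_before = 0, cultures_after = 2880,
                 labs_after = 28994, biopsies_after = 0, iv_to_oral = 68001),
    avoidance = c(hospitalization = 16827888, cdi = 5050, readmission = 0,
                  ade = 1086868),
    operational = 74190))
  dev <- period_summary("developed", 105, cost_ledger(
    antimicrobial_ddd_cost = 300321,
    ddd_total = 1,
    resource = c(cultures_before = 720, labs_before = 28892,
                 biopsies_before = 0, cultures_after = 2943,
                 labs_after = 37641, biopsies_after = 0, iv_to_oral = 75760),
    avoidance = c(hospitalization = 4567221, cdi = 3536, readmission = 0,
                  ade = 1379108),
    operational = 61714))
  list(pre = pre, dev = dev)
}
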