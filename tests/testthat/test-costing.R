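test_that("course DDD arithmetic follows dose x duration / DDD", {
  ref <- tiny_ref()
  expect_equal(course_ddd(list(drug_name = "fluconazole", route = "oral",
                               daily_dose_grams = 2, duration_days = 5),
                          ddd_reference(data.frame(drug = "fluconazole",
                                                   route = "",
                                                   ddd_grams = 1))), 10)
  expect_equal(course_ddd(list(drug_name = "fluconazole", route = "oral",
                               daily_dose_grams = 2, duration_days = 0), ref), 0)
  # 0.4 g/day x 7 days at a 0.2 g DDD
  expect_equal(course_ddd(list(drug_name = "fluconazole", route = "oral",
                               daily_dose_grams = 0.4, duration_days = 7),
                          ref), 14)
  # route-specific DDD takes precedence over the default row
  expect_equal(course_ddd(list(drug_name = "ciprofloxacin",
                               route = "injectable",
                               daily_dose_grams = 0.5, duration_days = 2),
                          ref), 2)
  expect_error(course_ddd(list(drug_name = "unknownium", route = "oral",
                               daily_dose_grams = 1, duration_days = 2), ref),
               "unknownium")
})

test_that("period consumption sums DDDs and prices them", {
  ref <- tiny_ref()
  costs <- tiny_costs()
  cohort <- generate_cohort(small_profile(n = 5), seed = 1)
  empty <- asp_cohort(cohort$episodes[0, ], cohort$courses[0, ],
                      cohort$ade_events[0, ])
  expect_equal(period_consumption(empty, ref, costs),
               list(ddd_total = 0, antimicrobial_cost = 0))

  one <- asp_cohort(list(patient_episode("e", courses = data.frame(
    drug_name = "fluconazole", route = "oral", daily_dose_grams = 0.4,
    duration_days = 5, start_day = 0))))
  # 0.4 x 5 / 0.2 = 10 DDD at 7/DDD
  expect_equal(period_consumption(one, ref, costs),
               list(ddd_total = 10, antimicrobial_cost = 70))

  unpriced <- unit_cost_table(1, 1, 1, 1, 1, 1, 1,
                              cost_per_ddd = c(ertapenem = 5))
  expect_error(period_consumption(one, ref, unpriced), "fluconazole")

  # acquisition-cost mode sums the per-course amounts instead
  two <- asp_cohort(list(patient_episode("e", courses = data.frame(
    drug_name = "fluconazole", route = "oral", daily_dose_grams = 0.4,
    duration_days = 5, start_day = 0, acquisition_cost = 123.5))))
  expect_equal(period_consumption(two, ref, costs, mode = "acquisition")$antimicrobial_cost,
               123.5)
  expect_error(period_consumption(one, ref, costs, mode = "acquisition"),
               "acquisition_cost")
})

test_that("printed period antimicrobial totals give the published 80.9% cost reduction", {
  # the two phases' published antimicrobial totals are inputs
  reduction <- 100 * (1 - 300321 / 1569699)
  expect_equal(report_round(reduction, 1), 80.9)
})

test_that("micro-costing multiplies counts by unit costs", {
  costs <- tiny_costs()
  e <- patient_episode("e", cultures_before = 2, labs_after = 3,
                       iv_to_oral_switches = 1)
  rc <- episode_resource_cost(e, costs)
  expect_equal(rc[["cultures_before"]], 320)
  expect_equal(rc[["labs_after"]], 300)
  expect_equal(rc[["iv_to_oral"]], 700)

  zero <- episode_resource_cost(patient_episode("z"), costs)
  expect_true(all(zero == 0))
})

test_that("avoidance components follow the bed-day, CDI-recipe and ADE rules", {
  costs <- tiny_costs()  # bed_day 1000, vanc dose 2, cdi culture 30
  base <- patient_episode("e", los_initial_days = 10)
  av <- episode_avoidance_cost(base, costs)
  expect_equal(av[["hospitalization"]], 10000)
  expect_equal(av[["cdi"]], 0)
  expect_equal(av[["readmission"]], 0)
  expect_equal(av[["ade"]], 0)

  # CDI recipe: 4 doses/day x 10 days of vancomycin 125 mg plus one culture
  cdi <- patient_episode("e", cdi = TRUE)
  expect_equal(episode_avoidance_cost(cdi, costs)[["cdi"]], 40 * 2 + 30)

  inj <- patient_episode("e", ade_events = data.frame(
    implicated_route = "injectable"))
  oral <- patient_episode("e", ade_events = data.frame(
    implicated_route = "oral"))
  halfbed <- tiny_costs(); halfbed$bed_day <- 500
  expect_equal(episode_avoidance_cost(inj, halfbed)[["ade"]], 1000)
  expect_equal(episode_avoidance_cost(oral, halfbed)[["ade"]], 500)

  readm <- patient_episode("e", readmitted_30d = TRUE,
                           los_readmission_days = 3)
  expect_equal(episode_avoidance_cost(readm, costs)[["readmission"]], 3000)
})

test_that("published resource and avoidance line items sum to their printed totals", {
  s <- printed_summaries()
  expect_equal(s$pre$ledger$resource_total, 125245)
  expect_equal(s$dev$ledger$resource_total, 145956)
  expect_equal(s$pre$ledger$avoidance_total, 17919806)
  expect_true(validate_ledger(s$pre$ledger))
})

test_that("period totals equal a brute-force accumulation on small cohorts", {
  ref <- tiny_ref()
  costs <- tiny_costs()
  prof <- small_profile(n = 5)
  prof$drug_table <- prof$drug_table[prof$drug_table$drug_name %in%
                                       c("fluconazole", "ciprofloxacin",
                                         "cefepime"), ]
  for (s in 1:4) {
    cohort <- generate_cohort(prof, seed = s)
    got <- period_totals(cohort, ref, costs)
    want <- brute_period_totals(cohort, ref, costs)
    expect_equal(got$ledger$ddd_total, want$ddd_total)
    expect_equal(got$ledger$antimicrobial_ddd_cost, want$antimicrobial)
    expect_equal(got$ledger$resource_total, want$resource_total)
    expect_equal(got$ledger$avoidance_total, want$avoidance_total)
  }
})

test_that("period totals are additive over disjoint cohorts and refuse empty input", {
  ref <- tiny_ref()
  costs <- tiny_costs()
  prof <- small_profile(n = 12)
  prof$drug_table <- prof$drug_table[prof$drug_table$drug_name %in%
                                       c("fluconazole", "ciprofloxacin"), ]
  cohort <- generate_cohort(prof, seed = 9)
  ids <- cohort$episodes$id
  pick <- function(keep) asp_cohort(
    cohort$episodes[cohort$episodes$id %in% keep, ],
    cohort$courses[cohort$courses$id %in% keep, ],
    cohort$ade_events[cohort$ade_events$id %in% keep, ])
  a <- pick(ids[1:5]); b <- pick(ids[6:12])
  ta <- period_totals(a, ref, costs)$ledger
  tb <- period_totals(b, ref, costs)$ledger
  tall <- period_totals(cohort, ref, costs)$ledger
  expect_equal(tall$resource, ta$resource + tb$resource)
  expect_equal(tall$avoidance, ta$avoidance + tb$avoidance)
  expect_equal(tall$antimicrobial_ddd_cost,
               ta$antimicrobial_ddd_cost + tb$antimicrobial_ddd_cost)
  expect_equal(tall$ddd_total, ta$ddd_total + tb$ddd_total)

  empty <- asp_cohort(cohort$episodes[0, ], cohort$courses[0, ],
                      cohort$ade_events[0, ])
  expect_error(period_totals(empty, ref, costs), "empty cohort")
})

test_that("monetary outputs are homogeneous in unit costs; DDDs are price-invariant", {
  ref <- tiny_ref()
  prof <- small_profile(n = 10)
  prof$drug_table <- prof$drug_table[prof$drug_table$drug_name %in%
                                       c("fluconazole", "ciprofloxacin"), ]
  cohort <- generate_cohort(prof, seed = 5)
  t1 <- period_totals(cohort, ref, tiny_costs())$ledger
  t3 <- period_totals(cohort, ref, tiny_costs(scale = 3))$ledger
  expect_equal(t3$antimicrobial_ddd_cost, 3 * t1$antimicrobial_ddd_cost)
  expect_equal(t3$resource, 3 * t1$resource)
  expect_equal(t3$avoidance, 3 * t1$avoidance)
  expect_equal(t3$ddd_total, t1$ddd_total)
})

test_that("annual operational cost follows the staffing roster formula", {
  one <- staffing_config(data.frame(
    role = "physician", headcount = 1, hourly_rate = 100,
    data_collection_hours_per_day = 0, rounds_hours_per_day = 1,
    meeting_hours_per_month = 0), working_days_per_year = 260)
  expect_equal(annual_operational_cost(one), 26000)

  meetings <- staffing_config(data.frame(
    role = c("a", "b"), headcount = 1, hourly_rate = 100,
    data_collection_hours_per_day = 0, rounds_hours_per_day = 0,
    meeting_hours_per_month = 5))
  expect_equal(annual_operational_cost(meetings), 12000)

  empty <- staffing_config(data.frame(
    role = character(), headcount = numeric(), hourly_rate = numeric(),
    data_collection_hours_per_day = numeric(),
    rounds_hours_per_day = numeric(), meeting_hours_per_month = numeric()))
  expect_equal(annual_operational_cost(empty), 0)
})

test_that("cost tables and staffing rosters round-trip through their file formats", {
  d <- withr::local_tempdir()
  costs <- tiny_costs()
  p <- file.path(d, "unit_costs.csv")
  write_unit_costs(costs, p)
  back <- read_unit_costs(p)
  expect_equal(back$bed_day, costs$bed_day)
  expect_equal(back$cost_per_ddd, costs$cost_per_ddd)
  expect_error(read_unit_costs(file.path(d, "nope.csv")), "nope.csv")

  staff <- default_unit_costs()$staffing$developed
  ps <- file.path(d, "staffing.yaml")
  write_staffing(staff, ps)
  back <- read_staffing(ps)
  expect_equal(annual_operational_cost(back), annual_operational_cost(staff))

  ref <- tiny_ref()
  pr <- file.path(d, "ddd.csv")
  utils::write.csv(ref$table, pr, row.names = FALSE)
  expect_equal(read_ddd_reference(pr)$table$ddd_grams, ref$table$ddd_grams)
})
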