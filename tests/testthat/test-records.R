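test_that("eligibility cascade applies the inclusion rules in order", {
  pol <- eligibility_policy()

  short <- patient_episode("a", courses = data.frame(
    drug_name = "fluconazole", route = "oral", daily_dose_grams = 0.4,
    duration_days = 1.5, start_day = 0))
  d <- is_eligible(short, pol)
  expect_false(d$eligible)
  expect_identical(d$reason, "min_continuous_hours")

  icu <- patient_episode("b", icu_flag = TRUE, courses = data.frame(
    drug_name = "fluconazole", route = "oral", daily_dose_grams = 0.4,
    duration_days = 5, start_day = 0))
  d <- is_eligible(icu, pol)
  expect_false(d$eligible)
  expect_identical(d$reason, "icu_excluded")

  ok <- patient_episode("c", courses = data.frame(
    drug_name = "fluconazole", route = "oral", daily_dose_grams = 0.4,
    duration_days = 5, start_day = 0))
  d <- is_eligible(ok, pol)
  expect_true(d$eligible)
  expect_identical(d$reason, "ok")

  untargeted <- patient_episode("d", courses = data.frame(
    drug_name = "metronidazole", route = "oral", daily_dose_grams = 1.5,
    duration_days = 5, start_day = 0))
  expect_identical(is_eligible(untargeted, pol)$reason, "not_targeted")

  late <- patient_episode("e", courses = data.frame(
    drug_name = "fluconazole", route = "oral", daily_dose_grams = 0.4,
    duration_days = 5, start_day = 4))
  expect_identical(is_eligible(late, pol)$reason, "max_start_day")

  # the start-day window is inclusive: day 3 still qualifies
  day3 <- patient_episode("f", courses = data.frame(
    drug_name = "fluconazole", route = "oral", daily_dose_grams = 0.4,
    duration_days = 2, start_day = 3))
  expect_true(is_eligible(day3, pol)$eligible)
})

test_that("eligibility is monotone in the policy thresholds", {
  set.seed(42)
  drugs <- c(targeted_drugs()[1:5], "metronidazole", "vancomycin")
  for (i in 1:60) {
    ep <- patient_episode(
      "x", icu_flag = runif(1) < 0.3,
      courses = data.frame(
        drug_name = sample(drugs, 2, replace = TRUE),
        route = sample(c("oral", "injectable"), 2, replace = TRUE),
        daily_dose_grams = runif(2, 0.1, 4),
        duration_days = runif(2, 0, 6),
        start_day = sample(0:6, 2, replace = TRUE)))
    strict <- is_eligible(ep, eligibility_policy(max_start_day = 1,
                                                 min_continuous_hours = 72))
    relaxed <- is_eligible(ep, eligibility_policy(max_start_day = 3,
                                                  min_continuous_hours = 48))
    if (strict$eligible) expect_true(relaxed$eligible)
  }
})

test_that("cohort write/read round-trips exactly and writes are byte-identical", {
  cohort <- generate_cohort(small_profile(n = 25), seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(cohort, d1)
  back <- read_cohort(d1)
  # exact field equality, including doubles
  expect_equal(back$episodes[order(back$episodes$id), ],
               cohort$episodes[order(cohort$episodes$id), ],
               ignore_attr = TRUE, tolerance = 0)
  expect_equal(back$courses$duration_days[order(back$courses$id)],
               cohort$courses$duration_days[order(cohort$courses$id)],
               tolerance = 0)
  expect_identical(nrow(back$ade_events), nrow(cohort$ade_events))

  write_cohort(cohort, d2)
  for (f in c("episodes.csv", "courses.csv", "ade_events.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("empty cohorts round-trip as header-only files", {
  cohort <- generate_cohort(small_profile(n = 5), seed = 1)
  empty <- asp_cohort(cohort$episodes[0, ], cohort$courses[0, ],
                      cohort$ade_events[0, ])
  d <- withr::local_tempdir()
  write_cohort(empty, d)
  expect_length(readLines(file.path(d, "episodes.csv")), 1L)
  back <- read_cohort(d)
  expect_identical(nrow(back$episodes), 0L)
})

test_that("invalid cohort files raise named validation errors", {
  cohort <- generate_cohort(small_profile(n = 4), seed = 2)
  d <- withr::local_tempdir()
  write_cohort(cohort, d)

  ep <- utils::read.csv(file.path(d, "episodes.csv"))
  ep$los_initial_days[2] <- -1
  utils::write.csv(ep, file.path(d, "episodes.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "los_initial_days")

  ep$los_initial_days[2] <- 1
  ep$sex <- NULL
  utils::write.csv(ep, file.path(d, "episodes.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "missing mandatory column")

  expect_error(read_cohort(withr::local_tempdir()), "episodes file not found")
})

test_that("episode invariants are enforced at construction", {
  expect_error(patient_episode("a", los_initial_days = -2), "los_initial_days")
  expect_error(patient_episode("a", los_readmission_days = 3), "readmitted_30d")
  expect_error(patient_episode("a", cultures_before = 1.5), "cultures_before")
  expect_error(patient_episode("a", courses = data.frame(
    drug_name = "x", route = "topical", daily_dose_grams = 1,
    duration_days = 1, start_day = 0)), "route")
})

test_that("filtering is idempotent and drops child rows with their episode", {
  cohort <- generate_cohort(small_profile(n = 20), seed = 3)
  # force some ineligible episodes
  cohort$episodes$icu_flag[1:5] <- TRUE
  pol <- eligibility_policy()
  once <- filter_eligible(cohort, pol)
  twice <- filter_eligible(once, pol)
  expect_identical(once$episodes, twice$episodes)
  expect_identical(once$courses, twice$courses)
  expect_identical(nrow(once$episodes), 15L)
  expect_true(all(once$courses$id %in% once$episodes$id))
})
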