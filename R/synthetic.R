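#' Cohort generation profile
#'
#' Parameterizes the synthetic generator for one program phase: cohort
#' size, drug mix, length-of-stay moments (matched by a lognormal), event
#' probabilities and resource-event rates. Defaults for the two study
#' phases are provided by [default_profiles()].
#'
#' @param period phase label.
#' @param n cohort size (>= 1).
#' @param antibacterial_fraction fraction of first courses that are
#'   antibacterial (implied by the drug table weights; kept for reference).
#' @param drug_table data frame with columns `drug_name`, `route`,
#'   `daily_dose_grams`, `mean_duration_days`, `weight`.
#' @param los_mean,los_sd target moments of the initial length of stay,
#'   days; the generator draws from the lognormal matching them.
#' @param cdi_prob probability of hospital-onset C. difficile infection.
#' @param ade_prob_injectable,ade_prob_oral per-episode probabilities of an
#'   adverse drug event implicated with each route (default 0; the study
#'   phases recorded none, but nonzero values exercise the ADE costing
#'   path).
#' @param readmission_prob probability of 30-day readmission (default 0).
#' @param readmission_los_mean mean readmission stay when readmitted, days.
#' @param resource_means named numeric of Poisson means for the seven
#'   resource-event counts.
#' @param age_mean,age_sd age distribution (normal, truncated at 18).
#' @param male_fraction probability of male sex.
#' @param second_course_prob probability of a second antimicrobial course.
#' @return an object of class `cohort_profile`.
#' @export
cohort_profile <- function(period, n, antibacterial_fraction, drug_table,
                           los_mean, los_sd, cdi_prob,
                           ade_prob_injectable = 0, ade_prob_oral = 0,
                           readmission_prob = 0, readmission_los_mean = 5,
                           resource_means = c(cultures_before = 0.4,
                                              labs_before = 3,
                                              biopsies_before = 0,
                                              cultures_after = 0.4,
                                              labs_after = 4,
                                              biopsies_after = 0,
                                              iv_to_oral_switches = 0.5),
                           age_mean = 50, age_sd = 18,
                           male_fraction = 0.5, second_course_prob = 0.1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (los_sd < 0) stop("los_sd must be >= 0", call. = FALSE)
  .check_prob(c(antibacterial_fraction, cdi_prob, ade_prob_injectable,
                ade_prob_oral, readmission_prob, male_fraction,
                second_course_prob), "probabilities")
  drug_table <- as.data.frame(drug_table)
  stopifnot(all(c("drug_name", "route", "daily_dose_grams",
                  "mean_duration_days", "weight") %in% names(drug_table)))
  structure(list(period = period, n = as.integer(n),
                 antibacterial_fraction = antibacterial_fraction,
                 drug_table = drug_table, los_mean = los_mean,
                 los_sd = los_sd, cdi_prob = cdi_prob,
                 ade_prob_injectable = ade_prob_injectable,
                 ade_prob_oral = ade_prob_oral,
                 readmission_prob = readmission_prob,
                 readmission_los_mean = readmission_los_mean,
                 resource_means = resource_means,
                 age_mean = age_mean, age_sd = age_sd,
                 male_fraction = male_fraction,
                 second_course_prob = second_course_prob),
            class = "cohort_profile")
}

#' Default generation profiles for the two study phases
#'
#' Encodes the published structure of the two cohorts: a preliminary phase
#' of 81 patients with an antifungal-heavy drug mix (fluconazole and
#' caspofungin predominant, antibacterials 8.6%), long right-skewed stays
#' (mean 34.02, sd 51.21 days), C. difficile incidence 30.9%; and a
#' developed phase of 105 patients dominated by antibacterials (ertapenem
#' and ciprofloxacin predominant, 94.3%), short stays (mean 7.12, sd 10.47
#' days), C. difficile incidence 15.2%. Neither phase recorded 30-day
#' readmissions or adverse drug events, so those probabilities default to
#' zero.
#'
#' @return list with elements `preliminary` and `developed`, each a
#'   [cohort_profile()].
#' @export
default_profiles <- function() {
  pre_drugs <- data.frame(
    drug_name = c("fluconazole", "caspofungin", "voriconazole",
                  "posaconazole", "amphotericin", "cefepime", "ciprofloxacin"),
    route = c("oral", "injectable", "oral", "oral", "injectable",
              "injectable", "oral"),
    daily_dose_grams = c(0.4, 0.05, 0.4, 0.3, 0.035, 4, 1),
    mean_duration_days = c(12, 14, 14, 14, 12, 8, 7),
    weight = c(0.573, 0.146, 0.100, 0.050, 0.045, 0.050, 0.036))
  dev_drugs <- data.frame(
    drug_name = c("ertapenem", "ciprofloxacin", "cefepime", "linezolid",
                  "amikacin", "teicoplanin", "fluconazole", "caspofungin"),
    route = c("injectable", "oral", "injectable", "oral", "injectable",
              "injectable", "oral", "injectable"),
    daily_dose_grams = c(1, 1, 4, 1.2, 1, 0.4, 0.4, 0.05),
    mean_duration_days = c(6, 7, 6, 8, 6, 7, 10, 12),
    weight = c(0.324, 0.295, 0.150, 0.080, 0.050, 0.044, 0.040, 0.017))
  list(
    preliminary = cohort_profile(
      period = "preliminary", n = 81, antibacterial_fraction = 0.086,
      drug_table = pre_drugs, los_mean = 34.02, los_sd = 51.21,
      cdi_prob = 0.309, readmission_prob = 0,
      resource_means = c(cultures_before = 0.3, labs_before = 3,
                         biopsies_before = 0, cultures_after = 0.4,
                         labs_after = 3.5, biopsies_after = 0,
                         iv_to_oral_switches = 1.2),
      age_mean = 47.8, age_sd = 17.62, male_fraction = 0.667,
      second_course_prob = 0.31),
    developed = cohort_profile(
      period = "developed", n = 105, antibacterial_fraction = 0.943,
      drug_table = dev_drugs, los_mean = 7.12, los_sd = 10.47,
      cdi_prob = 0.152, readmission_prob = 0,
      resource_means = c(cultures_before = 0.3, labs_before = 2.8,
                         biopsies_before = 0, cultures_after = 0.3,
                         labs_after = 3.6, biopsies_after = 0,
                         iv_to_oral_switches = 1.0),
      age_mean = 54.7, age_sd = 19.89, male_fraction = 0.467,
      second_course_prob = 0.057))
}

# lognormal parameters matching a target mean and sd by moments
.lnorm_params <- function(mean, sd) {
  if (mean <= 0) stop("los_mean must be > 0 to moment-match a lognormal",
                      call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic cohort from a profile
#'
#' Draws exactly `profile$n` episodes: lognormal initial stays whose
#' moments match the profile's, Bernoulli C. difficile / ADE / readmission
#' events, Poisson resource-event counts, and antimicrobial courses drawn
#' from the profile's drug frequency table. Course durations have a 2-day
#' floor (at least 48 continuous hours) and start days lie in 0..3, so
#' every generated episode passes the default [eligibility_policy()];
#' a course may extend past discharge (oral step-down), so the length of
#' stay itself is not truncated. Reproducible given `seed`.
#'
#' @param profile a [cohort_profile()].
#' @param seed RNG seed (optional; the global RNG state is restored).
#' @return an `asp_cohort`.
#' @export
generate_cohort <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "cohort_profile"))
  .with_seed(seed, {
    n <- profile$n
    prefix <- substr(profile$period, 1, 3)
    ids <- sprintf("%s-%05d", prefix, seq_len(n))
    lp <- .lnorm_params(profile$los_mean, profile$los_sd)
    age <- pmax(18, stats::rnorm(n, profile$age_mean, profile$age_sd))
    readmitted <- stats::runif(n) < profile$readmission_prob
    los_re <- ifelse(readmitted,
                     stats::rlnorm(n, .lnorm_params(profile$readmission_los_mean,
                                                    profile$readmission_los_mean)[1],
                                   .lnorm_params(profile$readmission_los_mean,
                                                 profile$readmission_los_mean)[2]),
                     0)
    rm_ <- profile$resource_means
    episodes <- data.frame(
      id = ids, period = profile$period, age_years = age,
      sex = ifelse(stats::runif(n) < profile$male_fraction, "male", "female"),
      icu_flag = FALSE,
      los_initial_days = stats::rlnorm(n, lp[["meanlog"]], lp[["sdlog"]]),
      readmitted_30d = readmitted, los_readmission_days = los_re,
      cdi = stats::runif(n) < profile$cdi_prob,
      death_30d = FALSE, infection_related_death = FALSE,
      resistance_developed = FALSE,
      cultures_before = stats::rpois(n, rm_[["cultures_before"]]),
      labs_before = stats::rpois(n, rm_[["labs_before"]]),
      biopsies_before = stats::rpois(n, rm_[["biopsies_before"]]),
      cultures_after = stats::rpois(n, rm_[["cultures_after"]]),
      labs_after = stats::rpois(n, rm_[["labs_after"]]),
      biopsies_after = stats::rpois(n, rm_[["biopsies_after"]]),
      iv_to_oral_switches = stats::rpois(n, rm_[["iv_to_oral_switches"]]))

    draw_courses <- function(ep_ids, first) {
      k <- length(ep_ids)
      if (!k) return(NULL)
      dt <- profile$drug_table
      rows <- sample.int(nrow(dt), k, replace = TRUE,
                         prob = dt$weight / sum(dt$weight))
      mean_dur <- dt$mean_duration_days[rows]
      # 2-day floor keeps the 48-hour continuity rule satisfied
      dur <- 2 + stats::rgamma(k, shape = 1.5, scale = pmax(mean_dur - 2, 0.5) / 1.5)
      start <- if (first) {
        sample(0:3, k, replace = TRUE, prob = c(0.5, 0.3, 0.15, 0.05))
      } else {
        sample(2:6, k, replace = TRUE)
      }
      data.frame(id = ep_ids, drug_name = dt$drug_name[rows],
                 route = dt$route[rows],
                 daily_dose_grams = dt$daily_dose_grams[rows],
                 duration_days = dur, start_day = start,
                 acquisition_cost = NA_real_)
    }
    second <- ids[stats::runif(n) < profile$second_course_prob]
    courses <- rbind(draw_courses(ids, first = TRUE),
                     draw_courses(second, first = FALSE))
    courses <- courses[order(match(courses$id, ids)), , drop = FALSE]

    ade_inj <- ids[stats::runif(n) < profile$ade_prob_injectable]
    ade_oral <- ids[stats::runif(n) < profile$ade_prob_oral]
    ade <- rbind(
      if (length(ade_inj)) data.frame(id = ade_inj,
                                      implicated_route = "injectable"),
      if (length(ade_oral)) data.frame(id = ade_oral,
                                       implicated_route = "oral"))
    if (is.null(ade)) {
      ade <- data.frame(id = character(), implicated_route = character())
    } else {
      ade <- ade[order(match(ade$id, ids)), , drop = FALSE]
    }
    asp_cohort(episodes, courses, ade)
  })
}

#' Generate the full two-phase study cohort
#'
#' @param profiles list with `preliminary` and `developed`
#'   [cohort_profile()]s (default [default_profiles()]).
#' @param seed RNG seed.
#' @return an `asp_cohort` containing both phases.
#' @export
generate_study_cohort <- function(profiles = default_profiles(), seed = NULL) {
  .with_seed(seed, {
    pre <- generate_cohort(profiles$preliminary)
    dev <- generate_cohort(profiles$developed)
    asp_cohort(rbind(pre$episodes, dev$episodes),
               rbind(pre$courses, dev$courses),
               rbind(pre$ade_events, dev$ade_events))
  })
}

#' Bundled WHO-style DDD reference
#'
#' Reads the package's bundled defined-daily-dose reference covering the 18
#' targeted agents (`inst/extdata/ddd_reference.csv`, with provenance
#' comments in the file). Values follow the WHO ATC/DDD convention for the
#' main adult indication; sites should substitute their own versioned
#' reference for production use.
#'
#' @return a [ddd_reference()].
#' @export
default_ddd_reference <- function() {
  read_ddd_reference(system.file("extdata", "ddd_reference.csv",
                                 package = "aspcost", mustWork = TRUE))
}

#' Synthetic default unit costs, DDD reference and staffing rosters
#'
#' Internally consistent positive prices sufficient to run the whole
#' pipeline end to end. The bed-day rate (6,107 QAR) is consistent with the
#' study's aggregate hospitalization costs; the remaining prices are
#' synthetic plausible values for a tertiary setting and every drug the
#' default profiles can generate is priced. The two staffing rosters carry
#' the published activity hours (the preliminary phase: a physician and a
#' clinical pharmacist each in 5 meeting-hours/month and 3 daily
#' data-collection hours, the physician in 1 daily rounds hour; the
#' developed phase: five roles at 10 meeting-hours/month plus a physician
#' fellow and a clinical pharmacist each doing 3 daily data-collection
#' hours and 1 daily rounds hour); the hourly rates are synthetic.
#'
#' @return list with elements `costs` ([unit_cost_table()]), `ddd`
#'   ([ddd_reference()]) and `staffing` (list of two
#'   [staffing_config()]s).
#' @export
default_unit_costs <- function() {
  prices <- c(cefepime = 40, linezolid = 350, teicoplanin = 120,
              tigecycline = 500, ertapenem = 180, amikacin = 20,
              colistin = 300, ciprofloxacin = 15, moxifloxacin = 50,
              aztreonam = 250, ceftazidime = 40, daptomycin = 700,
              anidulafungin = 1100, fluconazole = 30, amphotericin = 800,
              caspofungin = 1200, posaconazole = 600, voriconazole = 400)
  costs <- unit_cost_table(bed_day = 6107, culture_test = 160,
                           lab_test = 100, biopsy = 500,
                           iv_to_oral_switch_event = 700,
                           cdi_diagnostic_culture = 160,
                           vancomycin_125mg_dose = 2.5,
                           cost_per_ddd = prices,
                           currency_code = "QAR", price_year = 2023)
  pre_roles <- data.frame(
    role = c("physician", "clinical_pharmacist"),
    headcount = c(1, 1), hourly_rate = c(250, 150),
    data_collection_hours_per_day = c(3, 3),
    rounds_hours_per_day = c(1, 0),
    meeting_hours_per_month = c(5, 5))
  dev_roles <- data.frame(
    role = c("id_consultant", "clinical_pharmacist", "clinical_microbiologist",
             "infection_control_practitioner", "stewardship_nurse",
             "physician_fellow"),
    headcount = 1, hourly_rate = c(350, 150, 300, 120, 100, 200),
    data_collection_hours_per_day = c(0, 3, 0, 0, 0, 3),
    rounds_hours_per_day = c(0, 1, 0, 0, 0, 1),
    meeting_hours_per_month = c(10, 10, 10, 10, 10, 0))
  list(costs = costs, ddd = default_ddd_reference(),
       staffing = list(preliminary = staffing_config(pre_roles),
                       developed = staffing_config(dev_roles)))
}

#' Materialize a complete demo workspace
#'
#' Generates the two-phase synthetic cohort and writes every input file the
#' pipeline consumes — the cohort CSV trio, `unit_costs.csv`,
#' `ddd_reference.csv`, the two staffing YAMLs, a sensitivity YAML and a
#' ready-to-run `config.yaml` — so that [run_analysis()] can be pointed at
#' the directory directly.
#'
#' @param dir workspace directory (created if absent).
#' @param seed RNG seed for the cohort generation.
#' @return path to the written `config.yaml`, invisibly.
#' @export
make_demo_workspace <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- generate_study_cohort(seed = seed)
  defaults <- default_unit_costs()
  cohort_dir <- file.path(dir, "cohort")
  write_cohort(cohort, cohort_dir)
  write_unit_costs(defaults$costs, file.path(dir, "unit_costs.csv"))
  ref_tab <- defaults$ddd$table
  ref_tab$ddd_grams <- .fmt_num(ref_tab$ddd_grams)
  utils::write.csv(ref_tab, file.path(dir, "ddd_reference.csv"),
                   row.names = FALSE, quote = FALSE)
  write_staffing(defaults$staffing$preliminary,
                 file.path(dir, "staffing_preliminary.yaml"))
  write_staffing(defaults$staffing$developed,
                 file.path(dir, "staffing_developed.yaml"))
  yaml::write_yaml(list(inputs = list("hospitalization_cost", "initial_los",
                                      "ade_extra_days"),
                        pct_one_way = 0.20, pct_multivariate = 0.10,
                        iterations = 1000),
                   file.path(dir, "sensitivity.yaml"))
  cfg <- list(cohort_dir = "cohort",
              unit_costs = "unit_costs.csv",
              ddd_reference = "ddd_reference.csv",
              staffing_preliminary = "staffing_preliminary.yaml",
              staffing_developed = "staffing_developed.yaml",
              sensitivity = "sensitivity.yaml",
              out_dir = "reports",
              qar_per_usd = 3.64,
              seed = seed)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
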