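#' The default set of stewardship-targeted antimicrobial agents
#'
#' Eighteen restricted agents reviewed by the stewardship program: broad
#' spectrum antibacterials plus the systemic antifungals whose empiric use
#' the program audits. Eligibility filtering keys on these names.
#'
#' @return character vector of 18 drug names.
#' @export
targeted_drugs <- function() {
  c("cefepime", "linezolid", "teicoplanin", "tigecycline", "ertapenem",
    "amikacin", "colistin", "ciprofloxacin", "moxifloxacin", "aztreonam",
    "ceftazidime", "daptomycin", "anidulafungin", "fluconazole",
    "amphotericin", "caspofungin", "posaconazole", "voriconazole")
}

#' Eligibility policy for episode inclusion
#'
#' An episode enters the costing analysis when at least one antimicrobial
#' course is for a targeted agent, starts within `max_start_day` days of
#' admission (admission = day 0, so the default 3 accepts start days 0-3),
#' and runs for at least `min_continuous_hours` (a single course record of
#' duration >= 2 days operationalizes "the same antimicrobial for 48
#' consecutive hours"). Critically ill (ICU) episodes are excluded by
#' default because they follow a separate, non-stewardship protocol.
#'
#' @param targeted set of targeted drug names.
#' @param max_start_day latest admissible course start day (inclusive).
#' @param min_continuous_hours minimum continuous therapy, in hours.
#' @param exclude_icu drop episodes with any ICU stay?
#' @return an object of class `eligibility_policy`.
#' @export
eligibility_policy <- function(targeted = targeted_drugs(),
                               max_start_day = 3,
                               min_continuous_hours = 48,
                               exclude_icu = TRUE) {
  if (max_start_day < 0) stop("max_start_day must be >= 0", call. = FALSE)
  if (min_continuous_hours <= 0) stop("min_continuous_hours must be > 0", call. = FALSE)
  structure(list(targeted_drugs = as.character(targeted),
                 max_start_day = max_start_day,
                 min_continuous_hours = min_continuous_hours,
                 exclude_icu = isTRUE(exclude_icu)),
            class = "eligibility_policy")
}

.episode_cols <- c("id", "period", "age_years", "sex", "icu_flag",
                   "los_initial_days", "readmitted_30d", "los_readmission_days",
                   "cdi", "death_30d", "infection_related_death",
                   "resistance_developed",
                   "cultures_before", "labs_before", "biopsies_before",
                   "cultures_after", "labs_after", "biopsies_after",
                   "iv_to_oral_switches")
.course_cols <- c("id", "drug_name", "route", "daily_dose_grams",
                  "duration_days", "start_day", "acquisition_cost")
.ade_cols <- c("id", "implicated_route")

#' Construct a single patient episode
#'
#' Convenience constructor for one admission record: demographics, period
#' label, outcome flags, resource-event counts, plus its antimicrobial
#' courses and adverse-drug-event (ADE) sub-records. Episodes are the
#' atomic costing unit; [asp_cohort()] bundles many of them.
#'
#' @param id episode identifier (unique within a cohort).
#' @param period phase label, `"preliminary"` or `"developed"`.
#' @param age_years,sex,icu_flag demographics; `sex` is `"male"`/`"female"`.
#' @param los_initial_days length of the initial admission, days.
#' @param readmitted_30d,los_readmission_days 30-day readmission flag and its
#'   length of stay (must be 0 when not readmitted).
#' @param cdi hospital-onset Clostridioides difficile infection flag.
#' @param death_30d,infection_related_death,resistance_developed outcome flags.
#' @param courses data frame with columns `drug_name`, `route`
#'   (`"injectable"`/`"oral"`), `daily_dose_grams`, `duration_days`,
#'   `start_day`, and optional `acquisition_cost` (QAR for the whole course).
#' @param ade_events data frame with column `implicated_route`.
#' @param cultures_before,labs_before,biopsies_before counts of tests
#'   performed before therapy start.
#' @param cultures_after,labs_after,biopsies_after counts after therapy start.
#' @param iv_to_oral_switches number of IV-to-oral switches within the first
#'   three days of antibiotic therapy.
#' @return a list of class `patient_episode`.
#' @export
patient_episode <- function(id, period = "preliminary", age_years = 50,
                            sex = "male", icu_flag = FALSE,
                            los_initial_days = 0, readmitted_30d = FALSE,
                            los_readmission_days = 0, cdi = FALSE,
                            death_30d = FALSE, infection_related_death = FALSE,
                            resistance_developed = FALSE,
                            courses = NULL, ade_events = NULL,
                            cultures_before = 0, labs_before = 0,
                            biopsies_before = 0, cultures_after = 0,
                            labs_after = 0, biopsies_after = 0,
                            iv_to_oral_switches = 0) {
  .check_enum(period, c("preliminary", "developed"), "period")
  .check_enum(sex, c("male", "female"), "sex")
  .check_nonneg(age_years, "age_years")
  .check_nonneg(los_initial_days, "los_initial_days")
  .check_nonneg(los_readmission_days, "los_readmission_days")
  if (!isTRUE(readmitted_30d) && los_readmission_days != 0) {
    stop("los_readmission_days must be 0 when readmitted_30d is FALSE",
         call. = FALSE)
  }
  for (f in c("cultures_before", "labs_before", "biopsies_before",
              "cultures_after", "labs_after", "biopsies_after",
              "iv_to_oral_switches")) {
    .check_count(get(f), f)
  }
  if (is.null(courses)) {
    courses <- data.frame(drug_name = character(), route = character(),
                          daily_dose_grams = numeric(), duration_days = numeric(),
                          start_day = numeric(), acquisition_cost = numeric())
  } else {
    courses <- as.data.frame(courses)
    if (is.null(courses$acquisition_cost)) courses$acquisition_cost <- NA_real_
    if (nrow(courses)) {
      if (any(!nzchar(courses$drug_name))) stop("drug_name must be non-empty", call. = FALSE)
      .check_enum(courses$route, c("injectable", "oral"), "route")
      .check_nonneg(courses$daily_dose_grams, "daily_dose_grams")
      .check_nonneg(courses$duration_days, "duration_days")
      .check_count(courses$start_day, "start_day")
    }
  }
  if (is.null(ade_events)) {
    ade_events <- data.frame(implicated_route = character())
  } else {
    ade_events <- as.data.frame(ade_events)
    if (nrow(ade_events)) {
      .check_enum(ade_events$implicated_route, c("injectable", "oral"),
                  "implicated_route")
    }
  }
  structure(list(id = as.character(id), period = period,
                 age_years = age_years, sex = sex, icu_flag = isTRUE(icu_flag),
                 los_initial_days = los_initial_days,
                 readmitted_30d = isTRUE(readmitted_30d),
                 los_readmission_days = los_readmission_days,
                 cdi = isTRUE(cdi), death_30d = isTRUE(death_30d),
                 infection_related_death = isTRUE(infection_related_death),
                 resistance_developed = isTRUE(resistance_developed),
                 cultures_before = cultures_before, labs_before = labs_before,
                 biopsies_before = biopsies_before,
                 cultures_after = cultures_after, labs_after = labs_after,
                 biopsies_after = biopsies_after,
                 iv_to_oral_switches = iv_to_oral_switches,
                 courses = courses, ade_events = ade_events),
            class = "patient_episode")
}

#' Bundle patient episodes into a cohort
#'
#' A cohort is a relational bundle of three tables: `episodes` (one row per
#' admission), `courses` and `ade_events` (child tables keyed by episode
#' `id`). All invariants of the episode data model are validated on
#' construction.
#'
#' @param episodes either a list of [patient_episode()] objects or an
#'   episodes data frame.
#' @param courses,ade_events child data frames (ignored when `episodes` is a
#'   list of episode objects).
#' @return an object of class `asp_cohort`.
#' @export
asp_cohort <- function(episodes, courses = NULL, ade_events = NULL) {
  if (is.list(episodes) && length(episodes) &&
      inherits(episodes[[1]], "patient_episode")) {
    eps <- do.call(rbind, lapply(episodes, function(e) {
      as.data.frame(e[.episode_cols], stringsAsFactors = FALSE)
    }))
    courses <- do.call(rbind, lapply(episodes, function(e) {
      if (nrow(e$courses) == 0) return(NULL)
      cbind(id = e$id, e$courses[, setdiff(.course_cols, "id")])
    }))
    ade_events <- do.call(rbind, lapply(episodes, function(e) {
      if (nrow(e$ade_events) == 0) return(NULL)
      cbind(id = e$id, e$ade_events[, "implicated_route", drop = FALSE])
    }))
    episodes <- eps
  }
  episodes <- as.data.frame(episodes)
  if (is.null(courses)) {
    courses <- data.frame(id = character(), drug_name = character(),
                          route = character(), daily_dose_grams = numeric(),
                          duration_days = numeric(), start_day = numeric(),
                          acquisition_cost = numeric())
  }
  courses <- as.data.frame(courses)
  if (is.null(courses$acquisition_cost)) courses$acquisition_cost <- NA_real_
  if (is.null(ade_events)) {
    ade_events <- data.frame(id = character(), implicated_route = character())
  }
  ade_events <- as.data.frame(ade_events)
  x <- structure(list(episodes = episodes, courses = courses,
                      ade_events = ade_events), class = "asp_cohort")
  validate_cohort(x)
}

#' Validate cohort invariants
#'
#' Checks the schema (mandatory columns) and the data-model invariants:
#' nonnegative lengths of stay, counts and doses; enum-valued routes, sex
#' and period; readmission length 0 when not readmitted; child records
#' keyed to an existing episode.
#'
#' @param x an `asp_cohort`.
#' @return `x`, invisibly usable, after validation (errors name the field).
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "asp_cohort"))
  miss <- setdiff(.episode_cols, names(x$episodes))
  if (length(miss)) {
    stop("episodes table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(.course_cols, names(x$courses))
  if (length(miss)) {
    stop("courses table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ep <- x$episodes
  if (anyDuplicated(ep$id)) stop("episode ids must be unique", call. = FALSE)
  .check_enum(ep$period, c("preliminary", "developed"), "period")
  .check_enum(ep$sex, c("male", "female"), "sex")
  .check_nonneg(ep$age_years, "age_years")
  .check_nonneg(ep$los_initial_days, "los_initial_days")
  .check_nonneg(ep$los_readmission_days, "los_readmission_days")
  if (any(!ep$readmitted_30d & ep$los_readmission_days != 0)) {
    stop("los_readmission_days must be 0 when readmitted_30d is FALSE",
         call. = FALSE)
  }
  for (f in c("cultures_before", "labs_before", "biopsies_before",
              "cultures_after", "labs_after", "biopsies_after",
              "iv_to_oral_switches")) {
    .check_count(ep[[f]], f)
  }
  co <- x$courses
  if (nrow(co)) {
    if (any(is.na(co$drug_name) | !nzchar(co$drug_name))) {
      stop("drug_name must be non-empty", call. = FALSE)
    }
    .check_enum(co$route, c("injectable", "oral"), "route")
    .check_nonneg(co$daily_dose_grams, "daily_dose_grams")
    .check_nonneg(co$duration_days, "duration_days")
    .check_count(co$start_day, "start_day")
    orphan <- setdiff(co$id, ep$id)
    if (length(orphan)) {
      stop("courses reference unknown episode id(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  ad <- x$ade_events
  if (nrow(ad)) {
    .check_enum(ad$implicated_route, c("injectable", "oral"), "implicated_route")
    orphan <- setdiff(ad$id, ep$id)
    if (length(orphan)) {
      stop("ade_events reference unknown episode id(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  x
}

#' @export
print.asp_cohort <- function(x, ...) {
  tab <- table(factor(x$episodes$period, c("preliminary", "developed")))
  cat("ASP cohort:", nrow(x$episodes), "episodes (",
      tab[["preliminary"]], "preliminary /", tab[["developed"]], "developed ),",
      nrow(x$courses), "courses,", nrow(x$ade_events), "ADE events\n")
  invisible(x)
}

#' Extract one episode from a cohort
#'
#' @param cohort an `asp_cohort`.
#' @param id episode identifier.
#' @return a `patient_episode`-like list including its `courses` and
#'   `ade_events` child rows.
#' @export
episode <- function(cohort, id) {
  i <- match(id, cohort$episodes$id)
  if (is.na(i)) stop("unknown episode id: ", id, call. = FALSE)
  e <- as.list(cohort$episodes[i, ])
  e$courses <- cohort$courses[cohort$courses$id == id, , drop = FALSE]
  e$ade_events <- cohort$ade_events[cohort$ade_events$id == id, , drop = FALSE]
  class(e) <- "patient_episode"
  e
}

#' Episode eligibility decision
#'
#' Applies the inclusion rules of the stewardship analysis to one episode.
#' Rules are checked in a fixed cascade and the reason code names the first
#' failed rule: `"not_targeted"` (no course for a targeted agent),
#' `"max_start_day"` (no targeted course starting within the window),
#' `"min_continuous_hours"` (no timely targeted course lasting long enough),
#' `"icu_excluded"` (critically ill), else `"ok"`.
#'
#' @param episode a [patient_episode()] (or the list returned by
#'   [episode()]).
#' @param policy an [eligibility_policy()].
#' @return list with elements `eligible` (logical) and `reason` (character).
#' @export
is_eligible <- function(episode, policy = eligibility_policy()) {
  stopifnot(inherits(policy, "eligibility_policy"))
  co <- episode$courses
  decide <- function(reason) list(eligible = identical(reason, "ok"),
                                  reason = reason)
  keep <- co$drug_name %in% policy$targeted_drugs
  if (!any(keep)) return(decide("not_targeted"))
  co <- co[keep, , drop = FALSE]
  keep <- co$start_day <= policy$max_start_day
  if (!any(keep)) return(decide("max_start_day"))
  co <- co[keep, , drop = FALSE]
  if (!any(co$duration_days * 24 >= policy$min_continuous_hours)) {
    return(decide("min_continuous_hours"))
  }
  if (policy$exclude_icu && isTRUE(episode$icu_flag)) {
    return(decide("icu_excluded"))
  }
  decide("ok")
}

#' Eligibility decisions for every episode in a cohort
#'
#' @param cohort an `asp_cohort`.
#' @param policy an [eligibility_policy()].
#' @return data frame with columns `id`, `eligible`, `reason`.
#' @export
eligibility <- function(cohort, policy = eligibility_policy()) {
  ids <- cohort$episodes$id
  res <- lapply(ids, function(i) is_eligible(episode(cohort, i), policy))
  data.frame(id = ids,
             eligible = vapply(res, `[[`, logical(1), "eligible"),
             reason = vapply(res, `[[`, character(1), "reason"))
}

#' Filter a cohort to its eligible episodes
#'
#' Idempotent: filtering twice with the same policy equals filtering once.
#'
#' @inheritParams eligibility
#' @return an `asp_cohort` restricted to eligible episodes (child tables
#'   subset accordingly).
#' @export
filter_eligible <- function(cohort, policy = eligibility_policy()) {
  el <- eligibility(cohort, policy)
  keep <- el$id[el$eligible]
  asp_cohort(cohort$episodes[cohort$episodes$id %in% keep, , drop = FALSE],
             cohort$courses[cohort$courses$id %in% keep, , drop = FALSE],
             cohort$ade_events[cohort$ade_events$id %in% keep, , drop = FALSE])
}

# ---- delimited I/O ----------------------------------------------------------

.write_table <- function(df, path, num_cols) {
  out <- df
  for (cn in intersect(num_cols, names(out))) out[[cn]] <- .fmt_num(out[[cn]])
  for (cn in names(out)) if (is.logical(df[[cn]])) out[[cn]] <- ifelse(df[[cn]], "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write a cohort to delimited text
#'
#' Writes `episodes.csv`, `courses.csv` and `ade_events.csv` into `dir`,
#' UTF-8 comma-delimited with "." decimal separator. Column order and the
#' sort order (episode id, then child-row order) are deterministic, so two
#' writes of the same cohort are byte-identical; numeric fields are written
#' with 17 significant digits so [read_cohort()] recovers them exactly.
#'
#' @param cohort an `asp_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ep <- cohort$episodes[order(cohort$episodes$id), .episode_cols, drop = FALSE]
  co <- cohort$courses[order(cohort$courses$id), .course_cols, drop = FALSE]
  ad <- cohort$ade_events[order(cohort$ade_events$id), .ade_cols, drop = FALSE]
  .write_table(ep, file.path(dir, "episodes.csv"),
               c("age_years", "los_initial_days", "los_readmission_days",
                 "cultures_before", "labs_before", "biopsies_before",
                 "cultures_after", "labs_after", "biopsies_after",
                 "iv_to_oral_switches"))
  .write_table(co, file.path(dir, "courses.csv"),
               c("daily_dose_grams", "duration_days", "start_day",
                 "acquisition_cost"))
  .write_table(ad, file.path(dir, "ade_events.csv"), character())
  invisible(dir)
}

.read_csv_checked <- function(path, what, logical_cols = character()) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in intersect(logical_cols, names(df))) {
    v <- df[[cn]]
    if (!is.logical(v)) {
      bad <- which(!v %in% c("TRUE", "FALSE", "true", "false"))
      if (length(bad)) {
        stop(sprintf("%s: unparseable logical '%s' at data line(s) %s",
                     path, cn, paste(bad, collapse = ", ")), call. = FALSE)
      }
      df[[cn]] <- toupper(v) == "TRUE"
    }
  }
  df
}

#' Read a cohort from delimited text
#'
#' Counterpart of [write_cohort()]: reads the three-table CSV schema from
#' `dir` and validates every data-model invariant. A header-only file yields
#' an empty cohort; schema problems (missing mandatory columns) and
#' invariant violations (e.g. a negative length of stay) are errors naming
#' the field.
#'
#' @param dir directory containing `episodes.csv`, `courses.csv`,
#'   `ade_events.csv`.
#' @return an `asp_cohort`.
#' @export
read_cohort <- function(dir) {
  ep <- .read_csv_checked(file.path(dir, "episodes.csv"), "episodes",
                          c("icu_flag", "readmitted_30d", "cdi", "death_30d",
                            "infection_related_death", "resistance_developed"))
  co <- .read_csv_checked(file.path(dir, "courses.csv"), "courses")
  ad <- .read_csv_checked(file.path(dir, "ade_events.csv"), "ade_events")
  if (nrow(ep)) ep$id <- as.character(ep$id)
  if (nrow(co)) co$id <- as.character(co$id)
  if (nrow(ad)) ad$id <- as.character(ad$id)
  if (nrow(co) && !is.numeric(co$acquisition_cost)) {
    co$acquisition_cost <- as.numeric(co$acquisition_cost)
  }
  asp_cohort(ep, co, ad)
}
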