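#' Defined-daily-dose reference table
#'
#' The defined daily dose (DDD) is the assumed average maintenance dose per
#' day of a drug for its main adult indication; antimicrobial consumption is
#' measured as grams administered divided by the DDD grams. DDD values are
#' configuration, not code: the package bundles a WHO-style reference file
#' (`system.file("extdata", "ddd_reference.csv", package = "aspcost")`) and
#' tests use small synthetic references.
#'
#' @param table data frame with columns `drug`, `route` (empty string for a
#'   route-independent default) and `ddd_grams` (> 0).
#' @return an object of class `ddd_reference`.
#' @export
ddd_reference <- function(table) {
  table <- as.data.frame(table)
  stopifnot(all(c("drug", "route", "ddd_grams") %in% names(table)))
  if (any(!is.finite(table$ddd_grams) | table$ddd_grams <= 0)) {
    stop("every ddd_grams must be > 0", call. = FALSE)
  }
  table$route[is.na(table$route)] <- ""
  structure(list(table = table), class = "ddd_reference")
}

#' Read a DDD reference from CSV
#'
#' Lines starting with `#` are treated as provenance comments and skipped.
#'
#' @param path CSV file with columns `drug`, `route`, `ddd_grams`.
#' @return a [ddd_reference()].
#' @export
read_ddd_reference <- function(path) {
  if (!file.exists(path)) stop("DDD reference file not found: ", path, call. = FALSE)
  ddd_reference(utils::read.csv(path, comment.char = "#",
                                stringsAsFactors = FALSE))
}

#' Look up the DDD grams for a drug
#'
#' A row whose `route` matches exactly takes precedence over the
#' route-independent default row (empty `route`).
#'
#' @param ref a [ddd_reference()].
#' @param drug drug name.
#' @param route `"injectable"` or `"oral"` (optional).
#' @return DDD in grams.
#' @export
ddd_grams <- function(ref, drug, route = "") {
  tab <- ref$table
  hit <- tab[tab$drug == drug & tab$route == route, , drop = FALSE]
  if (!nrow(hit)) hit <- tab[tab$drug == drug & tab$route == "", , drop = FALSE]
  if (!nrow(hit)) {
    stop("drug absent from DDD reference: ", drug, call. = FALSE)
  }
  hit$ddd_grams[[1]]
}

#' Unit cost table
#'
#' All monetary denominators of the costing engine. Every cost operation
#' reads from this table; no price is ever a literal in code. Amounts are in
#' the base currency (`currency_code`, default QAR) at `price_year` prices.
#'
#' @param bed_day daily cost of an occupied bed (per day).
#' @param culture_test,lab_test,biopsy unit costs per test/procedure.
#' @param iv_to_oral_switch_event cost booked per IV-to-oral switch event.
#' @param cdi_diagnostic_culture cost of one C. difficile diagnostic culture.
#' @param vancomycin_125mg_dose cost of one oral vancomycin 125 mg dose.
#' @param cost_per_ddd named numeric vector, price per DDD by drug.
#' @param currency_code,price_year currency metadata.
#' @return an object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(bed_day, culture_test, lab_test, biopsy,
                            iv_to_oral_switch_event, cdi_diagnostic_culture,
                            vancomycin_125mg_dose, cost_per_ddd = numeric(),
                            currency_code = "QAR", price_year = 2023) {
  for (f in c("bed_day", "culture_test", "lab_test", "biopsy",
              "iv_to_oral_switch_event", "cdi_diagnostic_culture",
              "vancomycin_125mg_dose")) {
    .check_nonneg(get(f), f)
  }
  .check_nonneg(cost_per_ddd, "cost_per_ddd")
  structure(list(bed_day = bed_day, culture_test = culture_test,
                 lab_test = lab_test, biopsy = biopsy,
                 iv_to_oral_switch_event = iv_to_oral_switch_event,
                 cdi_diagnostic_culture = cdi_diagnostic_culture,
                 vancomycin_125mg_dose = vancomycin_125mg_dose,
                 cost_per_ddd = cost_per_ddd,
                 currency_code = currency_code, price_year = price_year),
            class = "unit_cost_table")
}

.uct_scalar_fields <- c("bed_day", "culture_test", "lab_test", "biopsy",
                        "iv_to_oral_switch_event", "cdi_diagnostic_culture",
                        "vancomycin_125mg_dose")

#' Write a unit cost table to CSV
#'
#' Long format with columns `component`, `amount`, `currency`, `year`;
#' per-drug DDD prices are stored as components named
#' `cost_per_ddd.<drug>`.
#'
#' @param costs a [unit_cost_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_unit_costs <- function(costs, path) {
  comp <- c(.uct_scalar_fields,
            if (length(costs$cost_per_ddd))
              paste0("cost_per_ddd.", names(costs$cost_per_ddd)))
  amt <- c(unlist(costs[.uct_scalar_fields], use.names = FALSE),
           unname(costs$cost_per_ddd))
  df <- data.frame(component = comp, amount = .fmt_num(amt),
                   currency = costs$currency_code, year = costs$price_year)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a unit cost table from CSV
#'
#' @param path CSV written by [write_unit_costs()] (or hand-edited in the
#'   same `component, amount, currency, year` layout).
#' @return a [unit_cost_table()].
#' @export
read_unit_costs <- function(path) {
  if (!file.exists(path)) stop("unit cost file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("component", "amount") %in% names(df)))
  miss <- setdiff(.uct_scalar_fields, df$component)
  if (length(miss)) {
    stop("unit cost file is missing component(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  amt <- function(name) df$amount[match(name, df$component)]
  is_ddd <- startsWith(df$component, "cost_per_ddd.")
  prices <- df$amount[is_ddd]
  names(prices) <- sub("^cost_per_ddd\\.", "", df$component[is_ddd])
  unit_cost_table(bed_day = amt("bed_day"), culture_test = amt("culture_test"),
                  lab_test = amt("lab_test"), biopsy = amt("biopsy"),
                  iv_to_oral_switch_event = amt("iv_to_oral_switch_event"),
                  cdi_diagnostic_culture = amt("cdi_diagnostic_culture"),
                  vancomycin_125mg_dose = amt("vancomycin_125mg_dose"),
                  cost_per_ddd = prices,
                  currency_code = if ("currency" %in% names(df)) df$currency[[1]] else "QAR",
                  price_year = if ("year" %in% names(df)) df$year[[1]] else NA_integer_)
}

#' DDDs consumed by one antimicrobial course
#'
#' `daily_dose_grams * duration_days / ddd_grams`; 0 when the duration is 0.
#'
#' @param course a one-row data frame or list with `drug_name`, `route`,
#'   `daily_dose_grams`, `duration_days`.
#' @param ref a [ddd_reference()].
#' @return consumption in DDDs.
#' @export
#' @examples
#' ref <- ddd_reference(data.frame(drug = "fluconazole", route = "",
#'                                 ddd_grams = 0.2))
#' course_ddd(list(drug_name = "fluconazole", route = "oral",
#'                 daily_dose_grams = 0.4, duration_days = 7), ref)  # 14
course_ddd <- function(course, ref) {
  if (course$duration_days == 0) return(0)
  course$daily_dose_grams * course$duration_days /
    ddd_grams(ref, course$drug_name, course$route)
}

#' Antimicrobial consumption and cost of a period
#'
#' Sums DDDs over every course of the cohort and costs them either at the
#' per-DDD price from the unit cost table (`mode = "per_ddd"`, the default)
#' or as the sum of per-course acquisition costs (`mode = "acquisition"`).
#'
#' @param cohort an `asp_cohort`.
#' @param ref a [ddd_reference()].
#' @param costs a [unit_cost_table()].
#' @param mode antimicrobial costing mode.
#' @return list with `ddd_total` (DDDs) and `antimicrobial_cost`.
#' @export
period_consumption <- function(cohort, ref, costs,
                               mode = c("per_ddd", "acquisition")) {
  mode <- match.arg(mode)
  co <- cohort$courses
  if (!nrow(co)) return(list(ddd_total = 0, antimicrobial_cost = 0))
  ddds <- vapply(seq_len(nrow(co)),
                 function(i) course_ddd(co[i, ], ref), numeric(1))
  if (mode == "per_ddd") {
    missing_price <- setdiff(unique(co$drug_name), names(costs$cost_per_ddd))
    if (length(missing_price)) {
      stop("no per-DDD price for drug(s): ",
           paste(missing_price, collapse = ", "), call. = FALSE)
    }
    cost <- sum(ddds * unname(costs$cost_per_ddd[co$drug_name]))
  } else {
    if (anyNA(co$acquisition_cost)) {
      stop("acquisition_cost missing for drug(s): ",
           paste(unique(co$drug_name[is.na(co$acquisition_cost)]),
                 collapse = ", "), call. = FALSE)
    }
    cost <- sum(co$acquisition_cost)
  }
  list(ddd_total = sum(ddds), antimicrobial_cost = cost)
}

#' Micro-costed resource use of one episode
#'
#' Bottom-up costing: each resource component is its event count times its
#' unit cost. Components mirror the resource-utilization rows of the period
#' ledger: culture/laboratory/biopsy counts before and after therapy start,
#' plus IV-to-oral switch events.
#'
#' @param episode a [patient_episode()].
#' @param costs a [unit_cost_table()].
#' @return named numeric vector of the seven resource components.
#' @export
episode_resource_cost <- function(episode, costs) {
  c(cultures_before = episode$cultures_before * costs$culture_test,
    labs_before = episode$labs_before * costs$lab_test,
    biopsies_before = episode$biopsies_before * costs$biopsy,
    cultures_after = episode$cultures_after * costs$culture_test,
    labs_after = episode$labs_after * costs$lab_test,
    biopsies_after = episode$biopsies_after * costs$biopsy,
    iv_to_oral = episode$iv_to_oral_switches * costs$iv_to_oral_switch_event)
}

#' Rule-based avoided (or incurred-equivalent) costs of one episode
#'
#' Four components:
#' \itemize{
#'   \item hospitalization: initial length of stay times the bed-day cost;
#'   \item readmission: readmission length of stay times the bed-day cost
#'     when readmitted within 30 days, else 0;
#'   \item cdi: a fixed treatment recipe when hospital-onset C. difficile
#'     infection occurred — oral vancomycin 125 mg four times daily for ten
#'     days (40 doses) plus one diagnostic culture;
#'   \item ade: two extra bed-days per adverse drug event implicated with an
#'     injectable antimicrobial, one per oral event.
#' }
#' The bed-day rate is the cohort-level `costs$bed_day` unless the episode
#' carries a `bed_day_override` (ward-specific rate).
#'
#' @inheritParams episode_resource_cost
#' @return named numeric vector `hospitalization`, `cdi`, `readmission`,
#'   `ade`.
#' @export
episode_avoidance_cost <- function(episode, costs) {
  bed <- episode$bed_day_override
  if (is.null(bed) || is.na(bed)) bed <- costs$bed_day
  ade_days <- 0
  if (nrow(episode$ade_events)) {
    ade_days <- sum(ifelse(episode$ade_events$implicated_route == "injectable",
                           2, 1))
  }
  c(hospitalization = episode$los_initial_days * bed,
    cdi = if (isTRUE(episode$cdi)) {
      4 * 10 * costs$vancomycin_125mg_dose + costs$cdi_diagnostic_culture
    } else 0,
    readmission = if (isTRUE(episode$readmitted_30d)) {
      episode$los_readmission_days * bed
    } else 0,
    ade = ade_days * bed)
}

#' Itemized cost ledger of a period
#'
#' Named nonnegative components mirroring the period resource-utilization
#' table: total antimicrobial consumption (DDDs) and its cost, the seven
#' micro-costed resource components, the four avoidance components, and the
#' annual operational (staffing) cost. Category totals are stored and must
#' equal the sum of their components to within 1e-6 currency units.
#'
#' @param antimicrobial_ddd_cost total antimicrobial cost.
#' @param ddd_total total consumption in DDDs.
#' @param resource named numeric of the seven resource components.
#' @param avoidance named numeric of the four avoidance components.
#' @param operational annual operational cost.
#' @return an object of class `cost_ledger` with `resource_total` and
#'   `avoidance_total` fields.
#' @export
cost_ledger <- function(antimicrobial_ddd_cost = 0, ddd_total = 0,
                        resource = c(cultures_before = 0, labs_before = 0,
                                     biopsies_before = 0, cultures_after = 0,
                                     labs_after = 0, biopsies_after = 0,
                                     iv_to_oral = 0),
                        avoidance = c(hospitalization = 0, cdi = 0,
                                      readmission = 0, ade = 0),
                        operational = 0) {
  .check_nonneg(antimicrobial_ddd_cost, "antimicrobial_ddd_cost")
  .check_nonneg(ddd_total, "ddd_total")
  .check_nonneg(resource, "resource")
  .check_nonneg(avoidance, "avoidance")
  .check_nonneg(operational, "operational")
  need_r <- c("cultures_before", "labs_before", "biopsies_before",
              "cultures_after", "labs_after", "biopsies_after", "iv_to_oral")
  need_a <- c("hospitalization", "cdi", "readmission", "ade")
  stopifnot(setequal(names(resource), need_r), setequal(names(avoidance), need_a))
  structure(list(antimicrobial_ddd_cost = antimicrobial_ddd_cost,
                 ddd_total = ddd_total,
                 resource = resource[need_r],
                 resource_total = sum(resource),
                 avoidance = avoidance[need_a],
                 avoidance_total = sum(avoidance),
                 operational = operational),
            class = "cost_ledger")
}

#' Check ledger conservation
#'
#' Asserts that each stored category total equals the sum of its components
#' to within `tol` currency units.
#'
#' @param ledger a [cost_ledger()].
#' @param tol tolerance (default 1e-6).
#' @return `TRUE` invisibly, or an error.
#' @export
validate_ledger <- function(ledger, tol = 1e-6) {
  stopifnot(inherits(ledger, "cost_ledger"))
  if (abs(ledger$resource_total - sum(ledger$resource)) > tol) {
    stop("resource_total does not equal the sum of its components", call. = FALSE)
  }
  if (abs(ledger$avoidance_total - sum(ledger$avoidance)) > tol) {
    stop("avoidance_total does not equal the sum of its components", call. = FALSE)
  }
  invisible(TRUE)
}

#' Period summary: cohort size plus its cost ledger
#'
#' @param period phase label.
#' @param n_patients number of (eligible) patients, >= 1.
#' @param ledger a [cost_ledger()].
#' @return an object of class `period_summary`.
#' @export
period_summary <- function(period, n_patients, ledger) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  validate_ledger(ledger)
  structure(list(period = period, n_patients = as.integer(n_patients),
                 ledger = ledger), class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  l <- x$ledger
  cat(sprintf("Period '%s' (n = %d)\n", x$period, x$n_patients))
  cat(sprintf("  antimicrobial: %.0f (%.1f DDDs)\n",
              l$antimicrobial_ddd_cost, l$ddd_total))
  cat(sprintf("  resource total: %.0f | avoidance total: %.0f | operational: %.0f\n",
              l$resource_total, l$avoidance_total, l$operational))
  invisible(x)
}

#' Aggregate a cohort into a period summary
#'
#' Component-wise sum of per-episode resource and avoidance costs plus the
#' period's antimicrobial consumption, with an optional annual operational
#' cost from a staffing configuration.
#'
#' @param cohort a non-empty `asp_cohort` (episodes of one period).
#' @param ref a [ddd_reference()].
#' @param costs a [unit_cost_table()].
#' @param staffing optional [staffing_config()]; its
#'   [annual_operational_cost()] fills the ledger's operational component.
#' @param period period label; defaults to the episodes' (unique) period.
#' @param mode antimicrobial costing mode, see [period_consumption()].
#' @return a [period_summary()].
#' @export
period_totals <- function(cohort, ref, costs, staffing = NULL, period = NULL,
                          mode = c("per_ddd", "acquisition")) {
  if (!nrow(cohort$episodes)) {
    stop("cannot summarize an empty cohort (per-patient costs undefined)",
         call. = FALSE)
  }
  mode <- match.arg(mode)
  if (is.null(period)) {
    period <- unique(cohort$episodes$period)
    if (length(period) != 1) {
      stop("cohort spans several periods; pass `period` or split first",
           call. = FALSE)
    }
  }
  cons <- period_consumption(cohort, ref, costs, mode)
  res <- c(cultures_before = 0, labs_before = 0, biopsies_before = 0,
           cultures_after = 0, labs_after = 0, biopsies_after = 0,
           iv_to_oral = 0)
  avo <- c(hospitalization = 0, cdi = 0, readmission = 0, ade = 0)
  for (id in cohort$episodes$id) {
    e <- episode(cohort, id)
    res <- res + episode_resource_cost(e, costs)
    avo <- avo + episode_avoidance_cost(e, costs)
  }
  op <- if (is.null(staffing)) 0 else annual_operational_cost(staffing)
  period_summary(period, nrow(cohort$episodes),
                 cost_ledger(antimicrobial_ddd_cost = cons$antimicrobial_cost,
                             ddd_total = cons$ddd_total,
                             resource = res, avoidance = avo,
                             operational = op))
}

#' Stewardship staffing configuration
#'
#' Describes the team whose time the program consumes: per role, a
#' headcount, an hourly rate, daily data-collection and clinical-rounds
#' hours, and monthly committee-meeting hours. Daily activities run on
#' `working_days_per_year` days (default 365, since the program's data
#' collection and rounds are daily activities; weekday-only sites can pass
#' 260).
#'
#' @param roles data frame with columns `role`, `headcount`, `hourly_rate`,
#'   `data_collection_hours_per_day`, `rounds_hours_per_day`,
#'   `meeting_hours_per_month`.
#' @param working_days_per_year days per year on which daily activities run.
#' @param months_per_year fixed at 12.
#' @return an object of class `staffing_config`.
#' @export
staffing_config <- function(roles, working_days_per_year = 365,
                            months_per_year = 12) {
  roles <- as.data.frame(roles)
  need <- c("role", "headcount", "hourly_rate",
            "data_collection_hours_per_day", "rounds_hours_per_day",
            "meeting_hours_per_month")
  miss <- setdiff(need, names(roles))
  if (length(miss)) {
    stop("staffing roles are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (f in setdiff(need, "role")) .check_nonneg(roles[[f]], f)
  .check_nonneg(working_days_per_year, "working_days_per_year")
  if (months_per_year != 12) stop("months_per_year must be 12", call. = FALSE)
  structure(list(roles = roles,
                 working_days_per_year = working_days_per_year,
                 months_per_year = 12L), class = "staffing_config")
}

#' Annual operational cost of running the program
#'
#' Sums, over roles, `headcount * hourly_rate *
#' ((data_collection_hours_per_day + rounds_hours_per_day) *
#' working_days_per_year + meeting_hours_per_month * 12)`.
#'
#' @param staffing a [staffing_config()].
#' @return annual cost in the currency of the hourly rates.
#' @export
annual_operational_cost <- function(staffing) {
  stopifnot(inherits(staffing, "staffing_config"))
  r <- staffing$roles
  if (!nrow(r)) return(0)
  sum(r$headcount * r$hourly_rate *
        ((r$data_collection_hours_per_day + r$rounds_hours_per_day) *
           staffing$working_days_per_year +
           r$meeting_hours_per_month * 12))
}

#' Read/write staffing configuration as YAML
#'
#' @param path YAML file with keys `working_days_per_year` and `roles` (a
#'   list of role records).
#' @return [read_staffing()] returns a [staffing_config()];
#'   [write_staffing()] returns `path` invisibly.
#' @export
read_staffing <- function(path) {
  if (!file.exists(path)) stop("staffing file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  roles <- do.call(rbind, lapply(y$roles, function(r) as.data.frame(r)))
  staffing_config(roles,
                  working_days_per_year = if (is.null(y$working_days_per_year))
                    365 else y$working_days_per_year)
}

#' @rdname read_staffing
#' @param staffing a [staffing_config()].
#' @export
write_staffing <- function(staffing, path) {
  y <- list(working_days_per_year = staffing$working_days_per_year,
            roles = lapply(seq_len(nrow(staffing$roles)), function(i) {
              as.list(staffing$roles[i, ])
            }))
  yaml::write_yaml(y, path)
  invisible(path)
}
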