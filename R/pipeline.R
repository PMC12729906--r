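#' Run the full two-phase cost-of-resource-use analysis
#'
#' Config-driven pipeline tying the stages together: read the cohort and
#' cost tables, filter episodes through the eligibility policy, cost each
#' phase (consumption, micro-costed resources, avoidance, operational),
#' aggregate the cost-benefit result, compare the cohorts statistically,
#' and run the multivariate sensitivity analysis on the reconstructed cost
#' model. Writes, into `out_dir`:
#' \itemize{
#'   \item `period_summaries.csv` — the per-phase itemized ledgers;
#'   \item `cost_benefit.csv` and `cost_benefit.md` — the cost-benefit
#'     table in both currencies;
#'   \item `cohort_stats.csv` — the comparative statistics table;
#'   \item `sensitivity_outcomes.csv` and `tornado.csv` — Monte Carlo
#'     draws/outcomes and the standardized-regression ranking;
#'   \item `run_info.json` — inputs, seed, iteration count and package
#'     version (no timestamps, so identical runs produce byte-identical
#'     outputs).
#' }
#'
#' @param config a list or the path to a YAML file with entries
#'   `cohort_dir`, `unit_costs`, `ddd_reference`, `staffing_preliminary`,
#'   `staffing_developed`, optional `sensitivity` (YAML with `inputs`,
#'   `pct_multivariate`, `iterations`), `out_dir`, `qar_per_usd`, `seed`.
#'   Relative paths are resolved against the config file's directory.
#' @param seed overrides the config's seed when given.
#' @return invisible list with the computed objects (`cba`, `summaries`,
#'   `stats`, `psa`, `tornado`) and the written file `paths`.
#' @export
run_analysis <- function(config, seed = NULL) {
  base_dir <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/") || grepl("^[A-Za-z]:", p)) p else file.path(base_dir, p)
  }
  need <- c("cohort_dir", "unit_costs", "ddd_reference",
            "staffing_preliminary", "staffing_developed", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("config is missing entr(y/ies): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed
  costs <- read_unit_costs(resolve(config$unit_costs))
  ref <- read_ddd_reference(resolve(config$ddd_reference))
  staffing <- list(preliminary = read_staffing(resolve(config$staffing_preliminary)),
                   developed = read_staffing(resolve(config$staffing_developed)))
  cohort <- read_cohort(resolve(config$cohort_dir))
  policy <- eligibility_policy()
  eligible <- filter_eligible(cohort, policy)
  summaries <- lapply(c(preliminary = "preliminary", developed = "developed"),
                      function(p) {
    sub <- asp_cohort(
      eligible$episodes[eligible$episodes$period == p, , drop = FALSE],
      eligible$courses[eligible$courses$id %in%
                         eligible$episodes$id[eligible$episodes$period == p], ,
                       drop = FALSE],
      eligible$ade_events[eligible$ade_events$id %in%
                            eligible$episodes$id[eligible$episodes$period == p], ,
                          drop = FALSE])
    if (!nrow(sub$episodes)) {
      stop("no eligible episodes in period '", p, "'", call. = FALSE)
    }
    period_totals(sub, ref, costs, staffing = staffing[[p]], period = p)
  })
  cba <- compare_periods(summaries$preliminary, summaries$developed)
  stats_tab <- compare_cohorts(eligible)
  scfg <- list(inputs = c("hospitalization_cost", "initial_los",
                          "ade_extra_days"),
               pct_multivariate = 0.10, iterations = 1000)
  if (!is.null(config$sensitivity)) {
    user <- config$sensitivity
    if (is.character(user)) user <- yaml::read_yaml(resolve(user))
    scfg[names(user)] <- user
  }
  model <- reconstruct_cost_model(summaries$preliminary, summaries$developed)
  psa <- multivariate(model, inputs = unlist(scfg$inputs),
                      pct = scfg$pct_multivariate,
                      n_iterations = scfg$iterations, seed = seed)
  tor <- tornado(psa)

  out_dir <- resolve(config$out_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ccfg <- currency_config(qar_per_usd = if (is.null(config$qar_per_usd))
    3.64 else config$qar_per_usd)
  paths <- list(
    period_summaries = file.path(out_dir, "period_summaries.csv"),
    cost_benefit = file.path(out_dir, "cost_benefit.csv"),
    cost_benefit_md = file.path(out_dir, "cost_benefit.md"),
    cohort_stats = file.path(out_dir, "cohort_stats.csv"),
    sensitivity = file.path(out_dir, "sensitivity_outcomes.csv"),
    tornado = file.path(out_dir, "tornado.csv"),
    run_info = file.path(out_dir, "run_info.json"))
  write_period_summaries(unname(summaries), paths$period_summaries)
  write_cba_table(cba, paths$cost_benefit, ccfg)
  write_cba_report(cba, paths$cost_benefit_md, ccfg)
  st <- stats_tab
  st$statistic <- .fmt_num(st$statistic)
  st$p_value <- .fmt_num(st$p_value)
  utils::write.csv(st, paths$cohort_stats, row.names = FALSE, quote = FALSE)
  write_psa_draws(psa, paths$sensitivity)
  write_tornado(psa, paths$tornado)
  info <- list(package = "aspcost",
               version = as.character(utils::packageVersion("aspcost")),
               seed = seed, iterations = scfg$iterations,
               pct_multivariate = scfg$pct_multivariate,
               n_episodes_read = nrow(cohort$episodes),
               n_eligible = nrow(eligible$episodes),
               inputs = as.list(unlist(scfg$inputs)))
  jsonlite::write_json(info, paths$run_info, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cba = cba, summaries = summaries, stats = stats_tab,
                 psa = psa, tornado = tor, paths = paths))
}
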