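#' Currency configuration
#'
#' The base currency is the Qatari riyal (QAR), pegged near 3.64 per US
#' dollar; results are presented in both currencies. An optional consumer
#' price index allows re-basing amounts recorded at older price years to the
#' target year.
#'
#' @param qar_per_usd exchange rate, QAR per USD (> 0).
#' @param cpi_index named numeric vector mapping year to index value.
#' @param target_year year to which [cpi_adjust()] re-bases.
#' @return an object of class `currency_config`.
#' @export
currency_config <- function(qar_per_usd = 3.64, cpi_index = NULL,
                            target_year = 2023) {
  if (!is.finite(qar_per_usd) || qar_per_usd <= 0) {
    stop("qar_per_usd must be > 0", call. = FALSE)
  }
  if (!is.null(cpi_index) && any(cpi_index <= 0)) {
    stop("cpi_index values must be > 0", call. = FALSE)
  }
  structure(list(qar_per_usd = qar_per_usd, cpi_index = cpi_index,
                 target_year = as.integer(target_year)),
            class = "currency_config")
}

#' Convert between QAR and USD
#'
#' @param amount amount in QAR (or USD for the inverse).
#' @param cfg a [currency_config()].
#' @return converted amount at full precision.
#' @export
qar_to_usd <- function(amount, cfg = currency_config()) {
  stopifnot(inherits(cfg, "currency_config"))
  amount / cfg$qar_per_usd
}

#' @rdname qar_to_usd
#' @export
usd_to_qar <- function(amount, cfg = currency_config()) {
  stopifnot(inherits(cfg, "currency_config"))
  amount * cfg$qar_per_usd
}

#' Re-base an amount to the target price year
#'
#' Multiplies by `index(target_year) / index(source_year)`.
#'
#' @param amount amount recorded at `source_year` prices.
#' @param source_year price year of `amount`.
#' @param cfg a [currency_config()] carrying the index.
#' @return amount at target-year prices.
#' @export
cpi_adjust <- function(amount, source_year, cfg) {
  stopifnot(inherits(cfg, "currency_config"))
  idx <- cfg$cpi_index
  src <- as.character(source_year)
  tgt <- as.character(cfg$target_year)
  if (is.null(idx) || !src %in% names(idx) || !tgt %in% names(idx)) {
    stop("cpi_index must contain both year ", src, " and year ", tgt,
         call. = FALSE)
  }
  amount * idx[[tgt]] / idx[[src]]
}

#' Per-patient amount
#'
#' Divides a period total by the period's own patient count, at full
#' precision (rounding only happens in reports).
#'
#' @param amount total amount.
#' @param n number of patients (>= 1).
#' @return per-patient amount.
#' @export
per_patient <- function(amount, n) {
  if (length(n) != 1 || !is.finite(n) || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  amount / n
}

#' Cost-benefit comparison of two program phases
#'
#' Aggregates two [period_summary()] objects into the study's cost-benefit
#' result. The sign convention is fixed: positive values favor the second
#' (developed) period. Category results:
#' \itemize{
#'   \item `saving_ddd`: preliminary minus developed antimicrobial cost;
#'   \item `saving_resource`: preliminary minus developed resource total
#'     (may be negative);
#'   \item `saving_total = saving_ddd + saving_resource`;
#'   \item `avoidance`: preliminary minus developed avoidance total;
#'   \item `operational_saving`: preliminary minus developed operational;
#'   \item `net_reduction = saving_total + avoidance + operational_saving`.
#' }
#' Per-patient counterparts divide each period by its own patient count
#' first and then difference; the net per-patient value is the sum of the
#' per-patient category differences, never the net total divided by a
#' pooled n.
#'
#' @param pre the preliminary-phase [period_summary()].
#' @param dev the developed-phase [period_summary()].
#' @return an object of class `asp_cba` with elements `total` and
#'   `per_patient` (each a named list of the six figures), `n`, `periods`,
#'   `ddd_saving` (in DDDs) and `sign_convention`.
#' @export
compare_periods <- function(pre, dev) {
  stopifnot(inherits(pre, "period_summary"), inherits(dev, "period_summary"))
  if (identical(pre$period, dev$period)) {
    stop("period labels must be distinct", call. = FALSE)
  }
  cat_diffs <- function(a, b) {
    saving_ddd <- a$antimicrobial_ddd_cost - b$antimicrobial_ddd_cost
    saving_resource <- a$resource_total - b$resource_total
    avoidance <- a$avoidance_total - b$avoidance_total
    operational <- a$operational - b$operational
    list(saving_ddd = saving_ddd,
         saving_resource = saving_resource,
         saving_total = saving_ddd + saving_resource,
         avoidance = avoidance,
         operational_saving = operational,
         net_reduction = saving_ddd + saving_resource + avoidance + operational)
  }
  scale_ledger <- function(l, n) {
    list(antimicrobial_ddd_cost = l$antimicrobial_ddd_cost / n,
         resource_total = l$resource_total / n,
         avoidance_total = l$avoidance_total / n,
         operational = l$operational / n)
  }
  total <- cat_diffs(pre$ledger, dev$ledger)
  pp <- cat_diffs(scale_ledger(pre$ledger, pre$n_patients),
                  scale_ledger(dev$ledger, dev$n_patients))
  structure(list(total = total, per_patient = pp,
                 n = c(preliminary = pre$n_patients,
                       developed = dev$n_patients),
                 periods = c(pre$period, dev$period),
                 ddd_saving = pre$ledger$ddd_total - dev$ledger$ddd_total,
                 sign_convention = "positive favors developed period"),
            class = "asp_cba")
}

.cba_rows <- c(saving_ddd = "Cost saving, antimicrobial consumption (DDD)",
               saving_resource = "Cost saving, resource utilization",
               saving_total = "Total cost saving",
               avoidance = "Cost avoidance",
               operational_saving = "Operational cost saving",
               net_reduction = "Net reduction in monetary spending")

#' Tabulate a cost-benefit result
#'
#' @param x an `asp_cba`.
#' @param cfg a [currency_config()] for the USD presentation.
#' @param ... unused.
#' @return data frame with total and per-patient figures in both
#'   currencies, rounded to whole units for presentation.
#' @export
as.data.frame.asp_cba <- function(x, cfg = currency_config(), ...) {
  keys <- names(.cba_rows)
  tot <- unlist(x$total[keys])
  pp <- unlist(x$per_patient[keys])
  data.frame(parameter = unname(.cba_rows),
             total_qar = report_round(tot),
             total_usd = report_round(qar_to_usd(tot, cfg)),
             per_patient_qar = report_round(pp),
             per_patient_usd = report_round(qar_to_usd(pp, cfg)),
             row.names = NULL)
}

#' @export
print.asp_cba <- function(x, cfg = currency_config(), ...) {
  cat(sprintf("Cost-benefit analysis: %s (n = %d) vs %s (n = %d)\n",
              x$periods[1], x$n[1], x$periods[2], x$n[2]))
  cat("Sign convention:", x$sign_convention, "\n\n")
  df <- as.data.frame(x, cfg)
  df$total <- sprintf("%s (USD %s)", format(df$total_qar, big.mark = ","),
                      format(df$total_usd, big.mark = ","))
  df$per_patient <- sprintf("%s (USD %s)",
                            format(df$per_patient_qar, big.mark = ","),
                            format(df$per_patient_usd, big.mark = ","))
  out <- df[, c("parameter", "total", "per_patient")]
  names(out) <- c("", "total QAR", "per patient QAR")
  print(out, row.names = FALSE, right = FALSE)
  cat(sprintf("\nAntimicrobial consumption saving: %.1f DDDs\n", x$ddd_saving))
  invisible(x)
}

#' @export
summary.asp_cba <- function(object, cfg = currency_config(), ...) {
  print(object, cfg)
  dec <- object$total$saving_total + object$total$avoidance +
    object$total$operational_saving
  cat(sprintf("Decomposition check: net = savings + avoidance + operational (%.6f)\n",
              object$total$net_reduction - dec))
  invisible(object)
}

#' Write the cost-benefit table to CSV
#'
#' A delimited counterpart of the printed cost-benefit table, with total
#' and per-patient columns in both currencies.
#'
#' @param x an `asp_cba`.
#' @param path output CSV path.
#' @param cfg a [currency_config()].
#' @return `path`, invisibly.
#' @export
write_cba_table <- function(x, path, cfg = currency_config()) {
  utils::write.csv(as.data.frame(x, cfg), path, row.names = FALSE)
  invisible(path)
}

#' Write a human-readable cost-benefit report (markdown)
#'
#' @inheritParams write_cba_table
#' @export
write_cba_report <- function(x, path, cfg = currency_config()) {
  df <- as.data.frame(x, cfg)
  lines <- c("# Cost-benefit analysis",
             "",
             sprintf("Periods: %s (n = %d) vs %s (n = %d). %s.",
                     x$periods[1], x$n[1], x$periods[2], x$n[2],
                     x$sign_convention),
             "",
             "| Parameter | Total QAR (USD) | Per patient QAR (USD) |",
             "|---|---|---|",
             sprintf("| %s | %s (USD %s) | %s (USD %s) |",
                     df$parameter,
                     format(df$total_qar, big.mark = ",", trim = TRUE),
                     format(df$total_usd, big.mark = ",", trim = TRUE),
                     format(df$per_patient_qar, big.mark = ",", trim = TRUE),
                     format(df$per_patient_usd, big.mark = ",", trim = TRUE)),
             "",
             sprintf("Antimicrobial consumption saving: %.1f DDDs.",
                     x$ddd_saving))
  writeLines(lines, path)
  invisible(path)
}

#' Write period summaries to CSV (resource-utilization table shape)
#'
#' One row per ledger line, one column per period, in the base currency.
#'
#' @param summaries list of [period_summary()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_period_summaries <- function(summaries, path) {
  cols <- lapply(summaries, function(s) {
    l <- s$ledger
    c(n_patients = s$n_patients, ddd_total = l$ddd_total,
      antimicrobial_cost = l$antimicrobial_ddd_cost,
      l$resource, resource_total = l$resource_total,
      avoidance = l$avoidance, avoidance_total = l$avoidance_total,
      operational = l$operational)
  })
  df <- data.frame(item = names(cols[[1]]))
  for (i in seq_along(summaries)) df[[summaries[[i]]$period]] <- unname(cols[[i]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
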