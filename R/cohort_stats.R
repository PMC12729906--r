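#' Normality-gated two-sample comparison of a continuous variable
#'
#' Applies the Shapiro-Wilk test to each sample at `normality_alpha`; when
#' both samples pass, the two-sample t-test is used (equal-variance Student
#' form by default; Welch via `var_equal = FALSE`), otherwise the
#' Mann-Whitney U (Wilcoxon rank-sum) test. The chosen test is recorded in
#' `test_name`.
#'
#' @param sample_a,sample_b numeric vectors with at least 3 observations
#'   each.
#' @param alpha significance level for the comparison (default 0.05).
#' @param var_equal use the equal-variance Student t-test (default TRUE).
#' @param normality_alpha per-sample significance level of the
#'   Shapiro-Wilk gate (default 0.05).
#' @return an object of class `asp_test`: `test_name`, `statistic`,
#'   `p_value`, `alpha`, `significant` (`p_value < alpha`), plus the gate's
#'   Shapiro-Wilk p-values in `details`.
#' @export
compare_continuous <- function(sample_a, sample_b, alpha = 0.05,
                               var_equal = TRUE, normality_alpha = 0.05) {
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    stop("both samples need at least 3 observations", call. = FALSE)
  }
  sw_a <- stats::shapiro.test(sample_a)$p.value
  sw_b <- stats::shapiro.test(sample_b)$p.value
  normal <- sw_a >= normality_alpha && sw_b >= normality_alpha
  if (normal) {
    ht <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
    name <- if (var_equal) "t-test" else "welch-t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                              exact = FALSE))
    name <- "mann-whitney-u"
  }
  structure(list(test_name = name,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value, alpha = alpha,
                 significant = ht$p.value < alpha,
                 details = list(shapiro_p = c(a = sw_a, b = sw_b))),
            class = "asp_test")
}

#' Contingency comparison of a categorical variable
#'
#' Pearson chi-square test (without continuity correction by default; the
#' Yates correction is available by flag and only affects borderline 2x2
#' p-values). For 2x2 tables with any expected count below 5, Fisher's
#' exact test is substituted. Expected counts are reported in `details`.
#'
#' @param table 2 x k matrix of nonnegative integer counts (rows =
#'   periods).
#' @param alpha significance level (default 0.05).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return an object of class `asp_test`.
#' @export
compare_categorical <- function(table, alpha = 0.05, correct = FALSE) {
  table <- as.matrix(table)
  .check_count(as.vector(table), "table")
  if (sum(table) == 0 || any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate contingency table: all row and column sums must be > 0",
         call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  use_fisher <- all(dim(table) == c(2, 2)) && any(expected < 5)
  if (use_fisher) {
    ht <- stats::fisher.test(table)
    name <- "fisher-exact"
    statistic <- unname(ht$estimate)
  } else {
    ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
    name <- "chi-square"
    statistic <- unname(ht$statistic)
  }
  structure(list(test_name = name, statistic = statistic,
                 p_value = ht$p.value, alpha = alpha,
                 significant = ht$p.value < alpha,
                 details = list(expected = expected)),
            class = "asp_test")
}

#' @export
print.asp_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Comparative statistics table for a two-period cohort
#'
#' Compares the two phases on the standard demographic and clinical
#' variables — age and initial length of stay (normality-gated continuous
#' comparisons), sex, C. difficile infection, 30-day death, 30-day
#' readmission, and resistance development (contingency comparisons) — and
#' returns a table shaped like the p-value columns of a cohort
#' characteristics table. Categorical rows whose table is degenerate (an
#' outcome absent in both arms) are reported with `NA` p-values.
#'
#' @param cohort an `asp_cohort` containing both periods.
#' @param alpha significance level (default 0.05).
#' @return data frame with columns `variable`, `test`, `statistic`,
#'   `p_value`, `significant`.
#' @export
compare_cohorts <- function(cohort, alpha = 0.05) {
  ep <- cohort$episodes
  pre <- ep[ep$period == "preliminary", ]
  dev <- ep[ep$period == "developed", ]
  if (!nrow(pre) || !nrow(dev)) {
    stop("cohort must contain both a preliminary and a developed period",
         call. = FALSE)
  }
  rows <- list()
  add <- function(variable, test) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable,
      test = if (is.null(test)) NA_character_ else test$test_name,
      statistic = if (is.null(test)) NA_real_ else test$statistic,
      p_value = if (is.null(test)) NA_real_ else test$p_value,
      significant = if (is.null(test)) NA else test$significant)
  }
  add("age_years", compare_continuous(pre$age_years, dev$age_years, alpha))
  add("los_initial_days",
      compare_continuous(pre$los_initial_days, dev$los_initial_days, alpha))
  cat_row <- function(variable, flag_pre, flag_dev) {
    tab <- rbind(c(sum(flag_pre), sum(!flag_pre)),
                 c(sum(flag_dev), sum(!flag_dev)))
    test <- tryCatch(compare_categorical(tab, alpha), error = function(e) NULL)
    add(variable, test)
  }
  cat_row("sex_male", pre$sex == "male", dev$sex == "male")
  cat_row("cdi", pre$cdi, dev$cdi)
  cat_row("death_30d", pre$death_30d, dev$death_30d)
  cat_row("readmitted_30d", pre$readmitted_30d, dev$readmitted_30d)
  cat_row("resistance_developed", pre$resistance_developed,
          dev$resistance_developed)
  do.call(rbind, rows)
}
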