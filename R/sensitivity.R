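#' Triangular sampling for bounded input uncertainty
#'
#' Draws from a symmetric triangular distribution with minimum
#' `base * (1 - pct)`, mode `base`, and maximum `base * (1 + pct)`, via the
#' inverse-CDF transform. `pct = 0` yields the degenerate point mass at
#' `base`. This is the only sampling distribution used by the probabilistic
#' sensitivity analysis.
#'
#' @param base base (mode) value.
#' @param pct fractional half-width of the uncertainty range (e.g. 0.10).
#' @param count number of draws (>= 1).
#' @param seed optional seed; the global RNG state is restored afterwards.
#' @return numeric vector of `count` draws.
#' @export
#' @examples
#' sample_triangular(100, 0.1, 5, seed = 1)
sample_triangular <- function(base, pct, count, seed = NULL) {
  if (count < 1) stop("count must be >= 1", call. = FALSE)
  if (pct < 0) stop("pct must be >= 0", call. = FALSE)
  .with_seed(seed, {
    u <- stats::runif(count)
    if (pct == 0) {
      rep(base, count)
    } else {
      a <- base * (1 - pct)
      b <- base * (1 + pct)
      m <- base
      fc <- (m - a) / (b - a)
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (m - a)),
             b - sqrt((1 - u) * (b - a) * (b - m)))
    }
  })
}

#' Declare an uncertain model input
#'
#' @param name input name (must match a name in the cost model's base
#'   assignment).
#' @param base_value base (mode) value.
#' @param pct_range fractional half-width of the triangular range.
#' @return an object of class `uncertain_input`.
#' @export
uncertain_input <- function(name, base_value, pct_range) {
  if (pct_range < 0) stop("pct_range must be >= 0", call. = FALSE)
  if (!is.finite(base_value)) stop("base_value must be finite", call. = FALSE)
  structure(list(name = name, base_value = base_value, pct_range = pct_range),
            class = "uncertain_input")
}

#' Deterministic cost model for sensitivity analysis
#'
#' Wraps a function mapping a full named input assignment to the study
#' outcome (net reduction in monetary spending, positive favoring the
#' developed period) together with the base-case values of its inputs.
#'
#' @param fn function taking a named numeric vector (one value per input)
#'   and returning the scalar outcome.
#' @param base named numeric vector of base-case input values.
#' @return an object of class `asp_cost_model`.
#' @export
cost_model <- function(fn, base) {
  stopifnot(is.function(fn), is.numeric(base), !is.null(names(base)))
  structure(list(fn = fn, base = base), class = "asp_cost_model")
}

#' Evaluate a cost model at its base case
#'
#' @param model an [cost_model()].
#' @return the base-case outcome.
#' @export
base_outcome <- function(model) {
  model$fn(model$base)
}

.resolve_inputs <- function(model, inputs, pct) {
  if (inherits(inputs, "uncertain_input")) inputs <- list(inputs)
  if (is.character(inputs)) {
    inputs <- lapply(inputs, function(nm) {
      if (!nm %in% names(model$base)) {
        stop("unknown model input: ", nm, call. = FALSE)
      }
      uncertain_input(nm, model$base[[nm]], pct)
    })
  }
  if (!length(inputs)) stop("at least one uncertain input is required",
                            call. = FALSE)
  for (u in inputs) {
    if (!inherits(u, "uncertain_input")) {
      stop("inputs must be names or uncertain_input objects", call. = FALSE)
    }
    if (!u$name %in% names(model$base)) {
      stop("unknown model input: ", u$name, call. = FALSE)
    }
  }
  inputs
}

.run_psa <- function(model, inputs, n_iterations, seed, mode) {
  draws <- .with_seed(seed, {
    m <- vapply(inputs, function(u) {
      sample_triangular(u$base_value, u$pct_range, n_iterations)
    }, numeric(n_iterations))
    if (n_iterations == 1) m <- matrix(m, nrow = 1)
    m
  })
  colnames(draws) <- vapply(inputs, `[[`, character(1), "name")
  assign_base <- model$base
  outcomes <- vapply(seq_len(n_iterations), function(i) {
    v <- assign_base
    v[colnames(draws)] <- draws[i, ]
    model$fn(v)
  }, numeric(1))
  base_y <- base_outcome(model)
  structure(list(draws = draws, outcomes = outcomes,
                 probability_in_favor = mean(outcomes > 0),
                 summary = c(mean = mean(outcomes),
                             p2.5 = unname(stats::quantile(outcomes, 0.025)),
                             p97.5 = unname(stats::quantile(outcomes, 0.975))),
                 base_outcome = base_y,
                 conclusion_stable = all(sign(outcomes) == sign(base_y)),
                 n_iterations = n_iterations, seed = seed, mode = mode),
            class = "asp_psa")
}

#' One-way Monte Carlo sensitivity analysis
#'
#' Varies a single input under triangular uncertainty (default +/- 20%)
#' while pinning every other input at its base value, re-evaluating the
#' cost model at each draw. The result is flagged `conclusion_stable` when
#' every outcome shares the base-case sign. A deterministic low/high
#' endpoint evaluation is available as `mode = "endpoints"`; the Monte
#' Carlo mode is the default.
#'
#' @param model an [cost_model()].
#' @param input a single input name or an [uncertain_input()].
#' @param pct fractional half-width when `input` is a name (default 0.20).
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param mode `"monte_carlo"` (default) or `"endpoints"`.
#' @return an object of class `asp_psa`.
#' @export
one_way <- function(model, input, pct = 0.20, n_iterations = 1000,
                    seed = NULL, mode = c("monte_carlo", "endpoints")) {
  mode <- match.arg(mode)
  inputs <- .resolve_inputs(model, input, pct)
  if (length(inputs) != 1) {
    stop("one_way varies exactly one input; use multivariate() for several",
         call. = FALSE)
  }
  if (mode == "endpoints") {
    u <- inputs[[1]]
    vals <- c(u$base_value * (1 - u$pct_range),
              u$base_value,
              u$base_value * (1 + u$pct_range))
    outcomes <- vapply(vals, function(v) {
      x <- model$base
      x[[u$name]] <- v
      model$fn(x)
    }, numeric(1))
    draws <- matrix(vals, ncol = 1, dimnames = list(NULL, u$name))
    base_y <- base_outcome(model)
    return(structure(list(draws = draws, outcomes = outcomes,
                          probability_in_favor = mean(outcomes > 0),
                          summary = c(mean = mean(outcomes),
                                      p2.5 = min(outcomes),
                                      p97.5 = max(outcomes)),
                          base_outcome = base_y,
                          conclusion_stable = all(sign(outcomes) == sign(base_y)),
                          n_iterations = length(vals), seed = seed,
                          mode = "endpoints"),
                     class = "asp_psa"))
  }
  .run_psa(model, inputs, n_iterations, seed, "one_way")
}

#' Multivariate (probabilistic) Monte Carlo sensitivity analysis
#'
#' Samples every declared input independently from its triangular range
#' (default +/- 10%) in each of `n_iterations` joint draws, re-evaluating
#' the cost model each time. Reports the outcome vector, the probability
#' that the outcome favors the developed period (outcomes strictly > 0;
#' ties count as not in favor), and a percentile summary.
#'
#' @param model an [cost_model()].
#' @param inputs character vector of input names (each varied by `pct`) or
#'   a list of [uncertain_input()] objects; defaults to all model inputs.
#' @param pct fractional half-width when `inputs` are names (default 0.10).
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed RNG seed.
#' @return an object of class `asp_psa`.
#' @export
multivariate <- function(model, inputs = names(model$base), pct = 0.10,
                         n_iterations = 1000, seed = NULL) {
  inputs <- .resolve_inputs(model, inputs, pct)
  .run_psa(model, inputs, n_iterations, seed, "multivariate")
}

#' Tornado ranking by standardized regression coefficients
#'
#' Regresses the standardized outcomes on the standardized input draws of a
#' probabilistic sensitivity result and returns the coefficients sorted by
#' absolute magnitude (descending; ties broken by input name). An input
#' whose draws have zero variance gets coefficient 0 with a warning.
#'
#' @param result an `asp_psa` with at least 2 iterations.
#' @return data frame with columns `input` and `coefficient`, ordered for a
#'   tornado bar plot.
#' @export
tornado <- function(result) {
  stopifnot(inherits(result, "asp_psa"))
  if (length(result$outcomes) < 2) {
    stop("tornado needs at least 2 iterations", call. = FALSE)
  }
  X <- result$draws
  sds <- apply(X, 2, stats::sd)
  live <- sds > 0
  if (any(!live)) {
    warning("zero-variance input(s) reported with coefficient 0: ",
            paste(colnames(X)[!live], collapse = ", "), call. = FALSE)
  }
  coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
  ysd <- stats::sd(result$outcomes)
  if (ysd > 0 && any(live)) {
    Z <- scale(X[, live, drop = FALSE])
    y <- as.numeric(scale(result$outcomes))
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Z), y)
    coefs[colnames(X)[live]] <- fit$coefficients[-1]
  }
  ord <- order(-abs(coefs), names(coefs))
  data.frame(input = names(coefs)[ord], coefficient = unname(coefs[ord]),
             row.names = NULL)
}

#' @export
print.asp_psa <- function(x, ...) {
  cat(sprintf("Sensitivity analysis (%s): %d iterations over %d input(s)\n",
              x$mode, x$n_iterations, ncol(x$draws)))
  cat(sprintf("  base-case outcome: %.0f\n", x$base_outcome))
  cat(sprintf("  outcome mean %.0f [2.5%%: %.0f, 97.5%%: %.0f]\n",
              x$summary[["mean"]], x$summary[["p2.5"]], x$summary[["p97.5"]]))
  cat(sprintf("  probability in favor of developed period: %.1f%%\n",
              100 * x$probability_in_favor))
  cat(sprintf("  conclusion stable (all outcomes share base-case sign): %s\n",
              x$conclusion_stable))
  invisible(x)
}

#' Tornado bar plot of a sensitivity result
#'
#' @param x an `asp_psa`.
#' @param ... passed to [graphics::barplot()].
#' @return the tornado data frame, invisibly.
#' @export
plot.asp_psa <- function(x, ...) {
  tor <- tornado(x)
  graphics::barplot(rev(tor$coefficient), names.arg = rev(tor$input),
                    horiz = TRUE, las = 1,
                    xlab = "standardized regression coefficient",
                    main = "Tornado ranking", ...)
  invisible(tor)
}

#' Write sensitivity outputs to CSV
#'
#' `write_psa_draws()` writes the joint draws and outcome vector (one row
#' per iteration); `write_tornado()` writes the ranked coefficients,
#' suitable for bar plotting.
#'
#' @param result an `asp_psa`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_draws <- function(result, path) {
  df <- as.data.frame(result$draws)
  df$outcome <- result$outcomes
  num <- names(df)
  for (cn in num) df[[cn]] <- .fmt_num(df[[cn]])
  utils::write.csv(cbind(iteration = seq_len(nrow(df)), df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_psa_draws
#' @export
write_tornado <- function(result, path) {
  tor <- tornado(result)
  tor$coefficient <- .fmt_num(tor$coefficient)
  utils::write.csv(tor, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconstruct the base-case cost model from two period summaries
#'
#' Builds the deterministic cost model used by the shipped sensitivity
#' analysis from the two phases' aggregate ledgers. Three multiplicative
#' inputs (base value 1) scale the bed-day-driven parts of the ledger:
#' \describe{
#'   \item{`hospitalization_cost`}{the bed-day price; scales the
#'     hospitalization, readmission and ADE extra-stay lines of both
#'     periods (all bed-day priced in the costing engine);}
#'   \item{`initial_los`}{the initial length of stay; scales the
#'     hospitalization lines of both periods;}
#'   \item{`ade_extra_days`}{the 2-day/1-day ADE extra-stay multipliers;
#'     scales the ADE lines of both periods.}
#' }
#' Antimicrobial, resource, CDI and operational lines are unaffected by
#' these inputs. The outcome is the net reduction in monetary spending
#' (positive favors the developed period), recomputed through
#' [compare_periods()] at every evaluation.
#'
#' @param pre,dev [period_summary()] objects for the two phases.
#' @return an [cost_model()] with base `c(hospitalization_cost = 1,
#'   initial_los = 1, ade_extra_days = 1)`.
#' @export
reconstruct_cost_model <- function(pre, dev) {
  stopifnot(inherits(pre, "period_summary"), inherits(dev, "period_summary"))
  scale_summary <- function(s, v) {
    l <- s$ledger
    avo <- l$avoidance
    avo[["hospitalization"]] <- avo[["hospitalization"]] *
      v[["hospitalization_cost"]] * v[["initial_los"]]
    avo[["readmission"]] <- avo[["readmission"]] * v[["hospitalization_cost"]]
    avo[["ade"]] <- avo[["ade"]] * v[["hospitalization_cost"]] *
      v[["ade_extra_days"]]
    period_summary(s$period, s$n_patients,
                   cost_ledger(antimicrobial_ddd_cost = l$antimicrobial_ddd_cost,
                               ddd_total = l$ddd_total,
                               resource = l$resource, avoidance = avo,
                               operational = l$operational))
  }
  fn <- function(v) {
    cba <- compare_periods(scale_summary(pre, v), scale_summary(dev, v))
    cba$total$net_reduction
  }
  cost_model(fn, c(hospitalization_cost = 1, initial_los = 1,
                   ade_extra_days = 1))
}
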