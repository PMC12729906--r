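test_that("triangular sampler covers its support with the closed-form moments", {
  expect_equal(sample_triangular(100, 0, 50, seed = 1), rep(100, 50))

  x <- sample_triangular(100, 0.1, 10000, seed = 2)
  expect_true(all(x >= 90 & x <= 110))
  # symmetric triangular: mean = mode, sd = half-width / sqrt(6)
  se_mean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 100), 3 * se_mean)
  sd_true <- 10 / sqrt(6)
  se_sd <- sd_true / sqrt(2 * length(x))
  expect_lt(abs(sd(x) - sd_true), 3 * se_sd)
  # symmetry: the empirical CDF at the mode approaches 1/2
  expect_lt(abs(mean(x <= 100) - 0.5), 3 * 0.5 / sqrt(length(x)))

  expect_identical(sample_triangular(5, 0.2, 20, seed = 9),
                   sample_triangular(5, 0.2, 20, seed = 9))
  expect_error(sample_triangular(1, 0.1, 0), "count")
  expect_error(sample_triangular(1, -0.1, 5), "pct")
})

test_that("one-way analysis pins other inputs and matches the linear closed form", {
  m <- cost_model(function(v) 3 * v[["a"]] + v[["b"]], c(a = 10, b = 5))
  expect_equal(base_outcome(m), 35)

  frozen <- one_way(m, uncertain_input("a", 10, 0), n_iterations = 50, seed = 1)
  expect_true(all(frozen$outcomes == 35))

  r <- one_way(m, "a", pct = 0.2, n_iterations = 500, seed = 3)
  # y = 3a + b with a in [8, 12] and b pinned at 5
  expect_true(all(r$outcomes >= 3 * 8 + 5 & r$outcomes <= 3 * 12 + 5))
  expect_true(r$conclusion_stable)
  expect_equal(ncol(r$draws), 1L)

  ends <- one_way(m, "a", pct = 0.2, mode = "endpoints")
  expect_equal(sort(ends$outcomes), c(29, 35, 41))

  expect_error(one_way(m, "zz"), "unknown model input")
  expect_error(one_way(m, c("a", "b")), "exactly one input")
})

test_that("multivariate analysis is deterministic given a seed and degenerate at pct 0", {
  m <- cost_model(function(v) 3 * v[["a"]] + v[["b"]], c(a = 10, b = 5))
  r1 <- multivariate(m, pct = 0.1, n_iterations = 200, seed = 42)
  r2 <- multivariate(m, pct = 0.1, n_iterations = 200, seed = 42)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$outcomes, r2$outcomes)
  expect_identical(tornado(r1), tornado(r2))

  d <- multivariate(m, pct = 0, n_iterations = 100, seed = 1)
  expect_true(all(d$outcomes == base_outcome(m)))
  expect_equal(d$probability_in_favor, 1)

  neg <- cost_model(function(v) -v[["a"]], c(a = 1))
  expect_equal(multivariate(neg, pct = 0.1, n_iterations = 100,
                            seed = 1)$probability_in_favor, 0)
  expect_error(multivariate(m, inputs = list()), "at least one")
})

test_that("independent inputs are uncorrelated within Monte Carlo error", {
  m <- cost_model(function(v) v[["a"]] + v[["b"]] + v[["c"]],
                  c(a = 1, b = 1, c = 1))
  r <- multivariate(m, pct = 0.1, n_iterations = 2000, seed = 7)
  cors <- cor(r$draws)
  off <- cors[upper.tri(cors)]
  expect_true(all(abs(off) < 3 / sqrt(2000)))
})

test_that("Monte Carlo outcome mean converges to the closed form for a linear model", {
  m <- cost_model(function(v) 2 * v[["x"]], c(x = 50))
  r <- multivariate(m, inputs = "x", pct = 0.1, n_iterations = 10000, seed = 5)
  # E[y] = 2 * 50; sd(y) = 2 * (5 / sqrt(6))
  se <- sd(r$outcomes) / sqrt(length(r$outcomes))
  expect_lt(abs(mean(r$outcomes) - 100), 3 * se)
})

test_that("tornado ranks standardized influence and handles degenerate inputs", {
  m <- cost_model(function(v) 3 * v[["a"]] + v[["b"]], c(a = 10, b = 10))
  r <- multivariate(m, pct = 0.1, n_iterations = 4000, seed = 11)
  tor <- tornado(r)
  expect_equal(tor$input, c("a", "b"))
  # equal bases and relative uncertainty: standardized coefficients ~ 3:1
  expect_lt(abs(tor$coefficient[1] / tor$coefficient[2] - 3), 0.3)

  single <- multivariate(m, inputs = "a", pct = 0.1, n_iterations = 500,
                         seed = 2)
  ts <- tornado(single)
  expect_equal(nrow(ts), 1L)
  expect_equal(abs(ts$coefficient), 1, tolerance = 1e-6)

  mixed <- multivariate(m, inputs = list(uncertain_input("a", 10, 0.1),
                                         uncertain_input("b", 10, 0)),
                        n_iterations = 200, seed = 3)
  expect_warning(tz <- tornado(mixed), "zero-variance")
  expect_equal(tz$coefficient[tz$input == "b"], 0)

  short <- multivariate(m, pct = 0.1, n_iterations = 1, seed = 1)
  expect_error(tornado(short), "at least 2")
})

test_that("the reconstructed two-phase model recovers its base case and scales as declared", {
  s <- printed_summaries()
  m <- reconstruct_cost_model(s$pre, s$dev)
  cba <- compare_periods(s$pre, s$dev)
  expect_equal(base_outcome(m), cba$total$net_reduction)

  # doubling the bed-day price scales hospitalization and ADE lines of the
  # net; the antimicrobial/resource/CDI/operational parts stay fixed
  v <- c(hospitalization_cost = 2, initial_los = 1, ade_extra_days = 1)
  hosp_diff <- 16827888 - 4567221
  ade_diff <- 1086868 - 1379108
  fixed <- cba$total$net_reduction - hosp_diff - ade_diff
  expect_equal(m$fn(v), fixed + 2 * hosp_diff + 2 * ade_diff)

  v <- c(hospitalization_cost = 1, initial_los = 0.5, ade_extra_days = 1)
  expect_equal(m$fn(v), fixed + 0.5 * hosp_diff + ade_diff)

  v <- c(hospitalization_cost = 1, initial_los = 1, ade_extra_days = 3)
  expect_equal(m$fn(v), fixed + hosp_diff + 3 * ade_diff)
})
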