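test_that("encoding probability follows the thresholded exponential", {
  p <- psychometric_params(t0_s = 0.020, v_per_s = 20)
  expect_equal(encoding_probability(p, 0.020), 0)
  expect_equal(encoding_probability(p, 0.010), 0)
  expect_equal(encoding_probability(p, 0.070), 1 - exp(-1), tolerance = 1e-12)
  fast <- psychometric_params(t0_s = 0, v_per_s = 1e9)
  expect_equal(encoding_probability(fast, 0.012), 1)
  expect_error(encoding_probability(p, -0.01), "non-negative")
})

test_that("the psychometric function mixes encoding with uniform guessing", {
  p <- psychometric_params(t0_s = 0.020, v_per_s = 20, chance = 1 / 12)
  # below and at the temporal threshold accuracy is exactly chance
  expect_equal(evaluate_psychometric(p, 0.010), 1 / 12)
  expect_equal(evaluate_psychometric(p, 0.020), 1 / 12)
  expect_equal(evaluate_psychometric(p, 0.070),
               (1 - exp(-1)) + exp(-1) / 12, tolerance = 1e-12)
  expect_equal(evaluate_psychometric(p, 0.070), 0.66278, tolerance = 1e-4)
})

test_that("the psychometric function is monotone and bounded", {
  set.seed(101)
  t <- seq(0, 0.5, by = 0.005)
  for (i in 1:25) {
    t0 <- runif(1, 0, 0.15); v <- runif(1, 1, 100); ch <- runif(1, 0.02, 0.5)
    par <- psychometric_params(t0, v, ch)
    y <- evaluate_psychometric(par, t)
    expect_true(all(diff(y) >= 0))                       # nondecreasing in t
    expect_true(all(y >= ch & y <= 1))                   # <= 1 up to rounding
    expect_lt(evaluate_psychometric(par, t0 + 0.02), 1)  # strictly below 1
    y_fast <- evaluate_psychometric(psychometric_params(t0, v * 2, ch), t)
    expect_true(all(y_fast - y >= -1e-12))               # nondecreasing in v
    y_late <- evaluate_psychometric(psychometric_params(t0 + 0.01, v, ch), t)
    expect_true(all(y_late - y <= 1e-12))                # nonincreasing in t0
    expect_equal(evaluate_psychometric(par, 100), 1, tolerance = 1e-9)
  }
})

test_that("the negative log-likelihood matches direct summation", {
  par <- psychometric_params(0.020, 20, 1 / 12)
  data <- tibble::tibble(duration_s = 0.070, n_trials = 25L, n_correct = 20L)
  p <- (1 - exp(-1)) + exp(-1) / 12
  direct <- -(20 * log(p) + 5 * log(1 - p))
  expect_equal(neg_log_likelihood(par, data), direct, tolerance = 1e-12)
  expect_equal(direct, 13.661, tolerance = 1e-3)

  # chance-flat branch below threshold
  flat <- tibble::tibble(duration_s = c(0.005, 0.010), n_trials = 30L,
                         n_correct = c(3L, 2L))
  expect_equal(neg_log_likelihood(psychometric_params(0.05, 20, 1 / 12), flat),
               -(5 * log(1 / 12) + 55 * log(11 / 12)), tolerance = 1e-12)

  # p -> 1 limit: perfect data at huge speed has vanishing NLL
  perfect <- tibble::tibble(duration_s = 0.1, n_trials = 50L, n_correct = 50L)
  expect_lt(neg_log_likelihood(psychometric_params(0.01, 1e4, 1 / 12), perfect),
            1e-6)
  # and it stays finite for imperfect data at huge speed (log-space tail)
  miss <- tibble::tibble(duration_s = 0.1, n_trials = 50L, n_correct = 49L)
  expect_true(is.finite(neg_log_likelihood(psychometric_params(0.01, 5e3, 1 / 12),
                                           miss)))
  expect_error(neg_log_likelihood(par, tibble::tibble(duration_s = 0.1,
                                                      n_trials = 0L,
                                                      n_correct = 0L)),
               "positive trial count")
})

test_that("multi-start ML fitting matches the exhaustive grid oracle", {
  set.seed(202)
  chance <- 1 / 12
  fixtures <- list(oracle_counts(0.020, 25, chance, 200),
                   oracle_counts(0.045, 12, chance, 120),
                   oracle_counts(0.008, 60, chance, 80))
  for (data in fixtures) {
    fit <- fit_psychometric(data, chance = chance)
    grid <- oracle_grid_min(data, chance)
    expect_lte(fit$nll, grid$nll + 1e-6)
    expect_lt(abs(fit$params$t0_s - grid$t0), 0.004)
    expect_true(fit$converged)
  }
})

test_that("fitting recovers generating parameters from dense data", {
  set.seed(303)
  truth <- psychometric_params(0.020, 25, 1 / 12)
  data <- oracle_counts(0.020, 25, 1 / 12, 2000)
  fit <- fit_psychometric(data)
  expect_lt(abs(fit$params$t0_s - 0.020), 0.003)
  expect_lt(abs(fit$params$v_per_s - 25) / 25, 0.10)

  # self-consistency: exact model proportions converted to huge-n counts
  p <- evaluate_psychometric(truth, data$duration_s)
  exact <- tibble::tibble(duration_s = data$duration_s, n_trials = 1e6L,
                          n_correct = as.integer(round(1e6 * p)))
  fit2 <- fit_psychometric(exact)
  expect_lt(abs(fit2$nll - neg_log_likelihood(truth, exact)), 1e-3)
})

test_that("chance-level data are flagged as unconverged, not an error", {
  set.seed(404)
  flat <- tibble::tibble(duration_s = CANONICAL_DURATIONS_MS / 1000,
                         n_trials = 100L,
                         n_correct = rbinom(11, 100, 1 / 12))
  fit <- fit_psychometric(flat)
  expect_false(fit$converged)
  expect_true("v_per_s" %in% fit$at_bound)
})

test_that("aggregate parameters are the arithmetic means of the fits", {
  a <- psychometric_params(0.01, 20); b <- psychometric_params(0.03, 40)
  expect_equal(aggregate_params(list(a)), a)
  agg <- aggregate_params(list(a, b))
  expect_equal(agg$t0_s, 0.02)
  expect_equal(agg$v_per_s, 30)
  set.seed(7)
  many <- replicate(9, psychometric_params(runif(1, 0, 0.1), runif(1, 5, 80)),
                    simplify = FALSE)
  agg9 <- aggregate_params(many)
  expect_equal(agg9$t0_s, mean(sapply(many, `[[`, "t0_s")))
  expect_equal(agg9$v_per_s, mean(sapply(many, `[[`, "v_per_s")))
  expect_error(aggregate_params(list(a, psychometric_params(0.01, 20, 0.5))),
               "chance")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(psychometric_params(-0.01, 20), "non-negative")
  expect_error(psychometric_params(0.02, 0), "positive")
  expect_error(psychometric_params(0.02, 20, 0), "chance")
  expect_error(psychometric_params(0.02, 20, 1), "chance")
})
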