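test_that("paired and one-sample t tests match the closed form", {
  res <- paired_t_test(c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$d_z, 2, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)

  x <- c(5, 7, 9, 6); y <- c(4, 5, 10, 5)
  pr <- paired_t_test(x, y)
  d <- x - y
  expect_equal(pr$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_equal(pr$d_z, pr$t / sqrt(4), tolerance = 1e-12)

  null <- paired_t_test(c(-1, 0, 1))
  expect_equal(null$t, 0)
  expect_equal(null$d_z, 0)
  expect_equal(null$p, 1)

  degen <- paired_t_test(c(2, 2, 2), c(1, 1, 1))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$t))
})

test_that("d_z equals t over sqrt(n) for every reported pair", {
  printed <- rbind(c(10.248, 3.416), c(-8.667, -2.889), c(2.868, 0.956),
                   c(7.281, 2.427), c(-5.7879, -1.929), c(3.661, 1.220),
                   c(207.63, 69.21))
  half_ulp <- c(rep(0.0005, 6), 0.005)  # three vs two printed decimals
  for (i in seq_len(nrow(printed)))
    expect_lte(abs(printed[i, 1] / sqrt(9) - printed[i, 2]), half_ulp[i] + 1e-12)
  # identity holds on computed results too
  set.seed(59)
  x <- rnorm(9, 1); res <- paired_t_test(x)
  expect_equal(res$d_z, res$t / 3, tolerance = 1e-12)
})

test_that("the JZS Bayes factor behaves like a default Bayes factor should", {
  # symmetric in the sign of t, reciprocal with BF01
  expect_equal(jzs_bf10(2.5, 9), jzs_bf10(-2.5, 9), tolerance = 1e-10)
  expect_equal(jzs_bf10(3.1, 12) * jzs_bf01(3.1, 12), 1, tolerance = 1e-10)
  # no evidence for the alternative at t = 0
  expect_lt(jzs_bf10(0, 9), 1)
  # strictly increasing in |t| at fixed n and prior scale
  ts <- seq(0, 12, by = 0.5)
  bfs <- sapply(ts, jzs_bf10, n = 9)
  expect_true(all(diff(bfs) > 0))
  # stable in the extreme-evidence regime
  huge <- jzs_bf10(250, 9)
  expect_true(is.finite(huge) && huge > 1e12)
  expect_error(jzs_bf10(NaN, 9), "finite")
})

test_that("the JZS integral agrees with an independent noncentral-t quadrature", {
  # oracle: integrate the likelihood ratio over the Cauchy effect-size prior
  oracle_bf <- function(t, n, r = 0.707) {
    nu <- n - 1
    f <- function(delta) {
      # dt(ncp=) warns about its final-digit precision far in the tails;
      # those regions contribute nothing to the integral
      y <- suppressWarnings(
        exp(dt(t, nu, ncp = sqrt(n) * delta, log = TRUE) -
              dt(t, nu, log = TRUE)) * dcauchy(delta, scale = r))
      y[!is.finite(y)] <- 0
      y
    }
    # the likelihood ratio is negligible outside a wide window around t/sqrt(n)
    integrate(f, -50, 50, rel.tol = 1e-10, subdivisions = 400L)$value
  }
  for (t in c(0.5, 2.868, 3.661, 7.281))
    expect_equal(jzs_bf10(t, 9), oracle_bf(t, 9), tolerance = 1e-5)
  expect_equal(jzs_bf10(2.2, 15, prior_scale_r = 1),
               oracle_bf(2.2, 15, r = 1), tolerance = 1e-5)
})

test_that("the 2x2 repeated-measures ANOVA matches the aov oracle", {
  set.seed(61)
  grid <- expand.grid(observer = sprintf("s%02d", 1:9),
                      A = c("location", "identity"),
                      B = c("first", "second"), stringsAsFactors = FALSE)
  grid$value <- rnorm(nrow(grid)) + 0.8 * (grid$A == "location") +
    0.3 * (grid$B == "first") + rep(rnorm(9, sd = 2), times = 4)
  res <- rm_anova_2x2(grid, value = "value", observer = "observer",
                      factor_a = "A", factor_b = "B")
  oracle <- oracle_rm_anova(grid, "value", "observer", "A", "B")
  expect_equal(res$F, unname(oracle$F), tolerance = 1e-9)
  expect_equal(res$p, unname(oracle$p), tolerance = 1e-9)
  expect_equal(res$eta_g_sq, unname(oracle$eta_g_sq), tolerance = 1e-9)

  # conservation: component sums of squares add up to the total
  ss <- attr(res, "ss")
  expect_equal(sum(ss[setdiff(names(ss), "total")]), ss[["total"]],
               tolerance = 1e-9)
})

test_that("degenerate ANOVA inputs behave as documented", {
  grid <- expand.grid(observer = sprintf("s%d", 1:5),
                      A = c("a1", "a2"), B = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  # no condition variance at all: all effects vanish
  grid$value <- rep(1:5, times = 4)
  res <- rm_anova_2x2(grid, value = "value", observer = "observer",
                      factor_a = "A", factor_b = "B")
  expect_equal(res$F, rep(0, 3))
  # additive subject offsets dominate: generalized eta squared near zero
  set.seed(67)
  grid$value <- rep(seq(0, 40, by = 10), times = 4) + rnorm(20, sd = 0.01)
  res2 <- rm_anova_2x2(grid, value = "value", observer = "observer",
                       factor_a = "A", factor_b = "B")
  expect_true(all(res2$eta_g_sq < 1e-4))
  expect_error(rm_anova_2x2(grid[-1, ], value = "value", observer = "observer",
                            factor_a = "A", factor_b = "B"), "balanced")
})

test_that("Holm adjustment follows the step-down rule and brackets Bonferroni", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15))
  expect_equal(holm_adjust(c(0.04, 0.01, 0.03)), c(0.06, 0.03, 0.06))
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    h <- holm_adjust(p)
    expect_true(all(h >= p - 1e-15))
    expect_true(all(h <= pmin(length(p) * p, 1) + 1e-15))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("within-subject CIs remove observer offsets and match hand computation", {
  # three observers x two conditions, worked through step by step
  m <- rbind(c(10, 12), c(20, 23), c(30, 31))
  norm <- m - rowMeans(m) + mean(m)            # Cousineau normalization
  v <- apply(norm, 2, var) * 2 / (2 - 1)       # Morey correction, M = 2
  hand_hw <- qt(0.975, 2) * sqrt(v / 3)
  ci <- within_subject_ci(m)
  expect_equal(ci$half_width, unname(hand_hw), tolerance = 1e-12)
  expect_equal(ci$mean, colMeans(m))

  # invariant to adding any per-observer constant
  ci_shift <- within_subject_ci(m + c(100, -50, 7))
  expect_equal(ci$half_width, ci_shift$half_width, tolerance = 1e-12)

  # identical profiles up to offsets: zero half-widths
  flat <- rbind(c(1, 2, 3), c(11, 12, 13), c(5, 6, 7))
  expect_equal(within_subject_ci(flat)$half_width, rep(0, 3))

  # M = 2 identity: the paired-difference CI half-width over sqrt(2) in each
  # condition (normalization halves the difference, the Morey factor is 2)
  d <- m[, 1] - m[, 2]
  paired_hw <- qt(0.975, 2) * sd(d) / sqrt(3)
  expect_equal(ci$half_width, rep(paired_hw / sqrt(2), 2), tolerance = 1e-12)

  expect_error(within_subject_ci(m[, 1, drop = FALSE]), "M = 1")
})

test_that("the accuracy advantage averages within observers then across them", {
  toy <- tibble::tibble(
    observer_id = "o1",
    duration_ms = rep(c(50, 100), each = 20),
    loc_correct = c(rep(TRUE, 16), rep(FALSE, 4), rep(TRUE, 12), rep(FALSE, 8)),
    id_correct = c(rep(TRUE, 12), rep(FALSE, 8), rep(TRUE, 10), rep(FALSE, 10)))
  res <- mean_accuracy_difference(toy)
  expect_equal(res$mean_difference, ((0.8 - 0.6) + (0.6 - 0.5)) / 2,
               tolerance = 1e-12)

  same <- dplyr::mutate(toy, id_correct = loc_correct)
  expect_equal(mean_accuracy_difference(same)$mean_difference, 0)

  # a location-advantage cohort yields a positive advantage
  obs <- make_cohort(4, seed = 73)
  tr <- simulate_experiment(obs, design_spec(trials_per_cell = 50, seed = 79))
  expect_gt(mean_accuracy_difference(tr)$mean_difference, 0.05)
})
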