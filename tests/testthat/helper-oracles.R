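# Independent oracles used across the suite. These re-derive quantities from
# first principles (direct formulas, exhaustive grids, stats::aov) and never
# call the code paths they are checking.

# direct evaluation of the guessing-mixture psychometric function
oracle_prob <- function(t0, v, chance, t) {
  ifelse(t < t0, chance, 1 - exp(-v * (t - t0)) * (1 - chance))
}

# direct binomial NLL (plain sum, no log-space tricks)
oracle_nll <- function(t0, v, chance, data) {
  p <- oracle_prob(t0, v, chance, data$duration_s)
  -sum(data$n_correct * log(p) + (data$n_trials - data$n_correct) * log(1 - p))
}

# exhaustive grid search over the fitting box: t0 step 1 ms, v step 0.5 /s
oracle_grid_min <- function(data, chance,
                            t0_grid = seq(0, 0.150, by = 0.001),
                            v_grid = seq(0.5, 500, by = 0.5)) {
  best <- Inf; best_par <- c(NA, NA)
  for (t0 in t0_grid) {
    dt <- pmax(data$duration_s - t0, 0)
    pm <- 1 - exp(-outer(dt, v_grid)) * (1 - chance)
    nll <- -colSums(data$n_correct * log(pm) +
                      (data$n_trials - data$n_correct) * log(1 - pm))
    i <- which.min(nll)
    if (nll[i] < best) { best <- nll[i]; best_par <- c(t0, v_grid[i]) }
  }
  list(nll = best, t0 = best_par[1], v = best_par[2])
}

# binomial counts drawn from the oracle curve (independent of the simulator)
oracle_counts <- function(t0, v, chance, n_per_duration,
                          durations_s = c(12, 24, 35, 47, 59, 71, 82, 106,
                                          129, 176, 224) / 1000) {
  p <- oracle_prob(t0, v, chance, durations_s)
  tibble::tibble(duration_s = durations_s,
                 n_trials = n_per_duration,
                 n_correct = stats::rbinom(length(durations_s), n_per_duration, p))
}

# repeated-measures 2x2 ANOVA through stats::aov with an Error stratum,
# plus generalized eta squared assembled from the stratum sums of squares
oracle_rm_anova <- function(data, value, observer, factor_a, factor_b) {
  d <- data.frame(y = data[[value]], s = factor(data[[observer]]),
                  A = factor(data[[factor_a]]), B = factor(data[[factor_b]]))
  fit <- stats::aov(y ~ A * B + Error(s / (A * B)), data = d)
  sm <- summary(fit)
  pick <- function(stratum, row) {
    tab <- sm[[stratum]][[1]]
    tab[trimws(rownames(tab)) == row, , drop = FALSE]
  }
  ss <- c(subjects = pick("Error: s", "Residuals")[["Sum Sq"]],
          A = pick("Error: s:A", "A")[["Sum Sq"]],
          As = pick("Error: s:A", "Residuals")[["Sum Sq"]],
          B = pick("Error: s:B", "B")[["Sum Sq"]],
          Bs = pick("Error: s:B", "Residuals")[["Sum Sq"]],
          AB = pick("Error: s:A:B", "A:B")[["Sum Sq"]],
          ABs = pick("Error: s:A:B", "Residuals")[["Sum Sq"]])
  denom_subj <- ss[["subjects"]] + ss[["As"]] + ss[["Bs"]] + ss[["ABs"]]
  list(F = c(A = pick("Error: s:A", "A")[["F value"]],
             B = pick("Error: s:B", "B")[["F value"]],
             AB = pick("Error: s:A:B", "A:B")[["F value"]]),
       p = c(A = pick("Error: s:A", "A")[["Pr(>F)"]],
             B = pick("Error: s:B", "B")[["Pr(>F)"]],
             AB = pick("Error: s:A:B", "A:B")[["Pr(>F)"]]),
       eta_g_sq = c(A = ss[["A"]] / (ss[["A"]] + denom_subj),
                    B = ss[["B"]] / (ss[["B"]] + denom_subj),
                    AB = ss[["AB"]] / (ss[["AB"]] + denom_subj)))
}

# small location-advantage cohort used by several end-to-end tests
make_cohort <- function(n = 9, seed = 42, rho = 0) {
  generate_observers(n,
                     t0_range_ms = c(10, 25), v_range_per_s = c(25, 40),
                     t0_range_ms_identity = c(25, 40),
                     v_range_per_s_identity = c(10, 25),
                     rho = rho, seed = seed)
}
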