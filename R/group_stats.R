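# Group-level inferential layer: paired/one-sample t with Cohen's d_z and a
# JZS Bayes factor, 2x2 repeated-measures ANOVA with generalized eta squared,
# Holm correction, and Cousineau-Morey within-subject confidence intervals.

#' Paired or one-sample t test with Cohen's d_z and a JZS Bayes factor
#'
#' For paired data the test runs on the differences `x - y`; with `y` omitted
#' it is a one-sample test against zero. Cohen's d_z is the within-subject
#' effect size `mean(d) / sd(d)`, identically `t / sqrt(n)`. The Bayes factor
#' is the default JZS BF10 from [jzs_bf10()].
#'
#' @param x Numeric vector.
#' @param y Optional numeric vector of the same length (paired comparison).
#' @param prior_scale_r Cauchy prior scale forwarded to [jzs_bf10()].
#'
#' @return An object of class `group_test_result`: list with `t`, `df`, `p`,
#'   `d_z`, `bf10`, `n`, `mean_diff`, `degenerate`. When the differences have
#'   zero variance the test is degenerate: `degenerate = TRUE` and `t`, `p`,
#'   `d_z`, `bf10` are `NA` (no finite statistic exists).
#' @export
paired_t_test <- function(x, y = NULL, prior_scale_r = 0.707) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (!is.null(y)) {
    stopifnot(is.numeric(y), length(y) == length(x))
    d <- x - y
  } else d <- x
  if (anyNA(d)) stop("Missing values in the paired differences.", call. = FALSE)
  n <- length(d)
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, df = n - 1L, p = NA_real_,
                          d_z = NA_real_, bf10 = NA_real_, n = n,
                          mean_diff = mean(d), degenerate = TRUE),
                     class = "group_test_result"))
  }
  ht <- stats::t.test(d, mu = 0)
  t_stat <- unname(ht$statistic)
  structure(list(t = t_stat, df = n - 1L, p = ht$p.value,
                 d_z = t_stat / sqrt(n),
                 bf10 = jzs_bf10(t_stat, n, prior_scale_r),
                 n = n, mean_diff = mean(d), degenerate = FALSE),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("Degenerate t test (zero-variance differences), n = %d, mean = %.4g\n",
                x$n, x$mean_diff))
  } else {
    cat(sprintf("t(%d) = %.3f, p = %.4g, d_z = %.3f, BF10 = %.4g\n",
                x$df, x$t, x$p, x$d_z, x$bf10))
  }
  invisible(x)
}

#' Default JZS Bayes factor for a one-sample or paired t statistic
#'
#' Evidence for a nonzero standardized effect under a Cauchy(0, `r`) prior,
#' against the point null. Computed as the Zellner-Siow mixture-of-g
#' integral: the ratio of the marginal likelihood of `t` under the prior to
#' its likelihood under the null, with the scale mixture over `g` integrated
#' numerically on the log-`g` scale. The null likelihood is folded into the
#' integrand so only likelihood *ratios* are exponentiated; with an
#' additional max-shift the computation is stable for `|t|` well beyond 250
#' (where BF10 exceeds 1e12). BF01 is the reciprocal ([jzs_bf01()]).
#'
#' The BF depends on `t` only through `t^2`, so the sign of `t` is
#' irrelevant.
#'
#' @param t Observed t statistic (finite).
#' @param n Sample size (number of pairs); `df = n - 1`. Must be >= 2.
#' @param prior_scale_r Cauchy prior scale on the standardized effect;
#'   default 0.707.
#' @param rel_tol Relative tolerance of the quadrature.
#'
#' @return A positive scalar, BF10.
#' @export
jzs_bf10 <- function(t, n, prior_scale_r = 0.707, rel_tol = 1e-8) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("`t` must be a single finite number.", call. = FALSE)
  stopifnot(n >= 2L, prior_scale_r > 0)
  nu <- n - 1
  r2 <- prior_scale_r^2
  # log of [marginal likelihood at g / null likelihood] * prior(g), u = log(g)
  log_ratio <- function(u) {
    g <- exp(u)
    a <- 1 + n * r2 * g
    -0.5 * log(a) +
      ((nu + 1) / 2) * (log1p(t^2 / nu) - log1p(t^2 / (nu * a))) +
      (-0.5 * log(2 * pi) - 0.5 * u - 1 / (2 * g))  # InvGamma(1/2,1/2) + Jacobian
  }
  grid <- seq(-30, 30, length.out = 601)
  lv <- log_ratio(grid)
  shift <- max(lv[is.finite(lv)])
  f <- function(u) {
    y <- exp(log_ratio(u) - shift)
    y[!is.finite(y)] <- 0
    y
  }
  int <- stats::integrate(f, -60, 60, rel.tol = rel_tol, subdivisions = 500L)
  exp(shift) * int$value
}

#' @rdname jzs_bf10
#' @return `jzs_bf01()`: the reciprocal Bayes factor (evidence for the null).
#' @export
jzs_bf01 <- function(t, n, prior_scale_r = 0.707, rel_tol = 1e-8) {
  1 / jzs_bf10(t, n, prior_scale_r, rel_tol)
}

#' 2x2 repeated-measures ANOVA with generalized eta squared
#'
#' Standard fully-within decomposition for a balanced 2x2 design with one
#' value per observer per cell: each effect's mean square is tested against
#' its own subject-by-effect interaction mean square (df 1 and n - 1;
#' sphericity is moot with two levels). Generalized eta squared follows the
#' fully-within convention: every subject-related variance component
#' (subjects and all subject-by-effect interactions) enters the denominator,
#' so values are comparable across designs.
#'
#' @param data Data frame with one row per observer x cell.
#' @param value,observer,factor_a,factor_b Column names (strings).
#'
#' @return An object of class `anova_result`: a tibble with one row per
#'   effect (`A`, `B`, `A:B`) holding `F`, `df_num`, `df_den`, `p`,
#'   `eta_g_sq`, plus attributes `ss` (all sums of squares) and `factors`.
#' @export
rm_anova_2x2 <- function(data, value = "value", observer = "observer",
                         factor_a = "A", factor_b = "B") {
  stopifnot(is.data.frame(data),
            all(c(value, observer, factor_a, factor_b) %in% names(data)))
  y <- data[[value]]
  s <- factor(data[[observer]])
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  if (nlevels(a) != 2L || nlevels(b) != 2L)
    stop("Both within-subject factors must have exactly 2 levels.", call. = FALSE)
  n <- nlevels(s)
  if (n < 2L) stop("Need at least 2 observers.", call. = FALSE)
  tab <- table(s, a, b)
  if (any(tab != 1L))
    stop("Design must be complete and balanced: exactly one value per observer per cell.",
         call. = FALSE)

  gm <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_as <- tapply(y, list(a, s), mean)
  m_bs <- tapply(y, list(b, s), mean)

  ss_s <- 4 * sum((m_s - gm)^2)
  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, 2)) - outer(rep(1, 2), m_b) + gm)^2)
  ss_as <- 2 * sum((m_as - outer(m_a, rep(1, n)) - outer(rep(1, 2), m_s) + gm)^2)
  ss_bs <- 2 * sum((m_bs - outer(m_b, rep(1, n)) - outer(rep(1, 2), m_s) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs

  err_subj <- ss_s + ss_as + ss_bs + ss_abs
  row <- function(effect, ss_eff, ss_err) {
    # a literally-zero effect sum of squares is reported as F = 0 even when
    # the error stratum is also empty (fully degenerate input)
    f <- if (ss_eff == 0) 0 else (ss_eff / 1) / (ss_err / (n - 1))
    tibble::tibble(effect = effect, F = f, df_num = 1L, df_den = n - 1L,
                   p = stats::pf(f, 1, n - 1, lower.tail = FALSE),
                   eta_g_sq = ss_eff / (ss_eff + err_subj))
  }
  res <- dplyr::bind_rows(row("A", ss_a, ss_as),
                          row("B", ss_b, ss_bs),
                          row("A:B", ss_ab, ss_abs))
  attr(res, "ss") <- c(subjects = ss_s, A = ss_a, B = ss_b, `A:B` = ss_ab,
                       `A:subjects` = ss_as, `B:subjects` = ss_bs,
                       `A:B:subjects` = ss_abs, total = ss_tot)
  attr(res, "factors") <- c(A = factor_a, B = factor_b)
  class(res) <- c("anova_result", class(res))
  res
}

#' Holm step-down multiple-comparison adjustment
#'
#' Wraps the standard step-down Holm procedure: p values are adjusted as the
#' running maximum of `(m - rank + 1) * p`, capped at 1, and returned in the
#' input order. Uniformly more powerful than Bonferroni while controlling the
#' family-wise error rate.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#'
#' @return Adjusted p values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals), length(pvals) >= 1L)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1].", call. = FALSE)
  stats::p.adjust(pvals, method = "holm")
}

#' Within-subject (Cousineau-Morey) confidence intervals
#'
#' Condition CIs appropriate for within-subject designs: each observer's mean
#' is removed (and the grand mean restored) before the per-condition variance
#' is computed, then the normalized variance is multiplied by the Morey bias
#' correction `M / (M - 1)` for `M` conditions. Half-widths use the t
#' critical value with `n - 1` df. Between-subject offsets therefore do not
#' inflate the intervals; adding any per-observer constant leaves them
#' unchanged.
#'
#' @param values Numeric matrix, observers in rows, conditions in columns
#'   (>= 2 of each), complete.
#' @param level Confidence level, default 0.95.
#' @param method `"cousineau-morey"` (default) or `"between"` (the plain
#'   between-subject CI, for comparison).
#'
#' @return A tibble with `condition`, `mean`, `half_width`, and the `level`
#'   as an attribute.
#' @export
within_subject_ci <- function(values, level = 0.95,
                              method = c("cousineau-morey", "between")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  n <- nrow(values); m <- ncol(values)
  if (m < 2L) stop("Need at least 2 conditions (the correction is undefined for M = 1).",
                   call. = FALSE)
  if (n < 2L) stop("Need at least 2 observers.", call. = FALSE)
  if (anyNA(values)) stop("The observer x condition table must be complete.", call. = FALSE)
  cond <- colnames(values)
  if (is.null(cond)) cond <- paste0("c", seq_len(m))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  if (method == "cousineau-morey") {
    norm <- values - rowMeans(values) + mean(values)
    v <- apply(norm, 2, stats::var) * m / (m - 1)
  } else {
    v <- apply(values, 2, stats::var)
  }
  out <- tibble::tibble(condition = cond,
                        mean = colMeans(values),
                        half_width = tcrit * sqrt(v / n))
  attr(out, "level") <- level
  out
}

#' Mean location-over-identity accuracy advantage
#'
#' For each observer and exposure duration, the difference between location
#' and identity report accuracy; averaged over durations within observer and
#' then over observers. Works on dual-report trials (both correctness flags
#' on each row) and on blocked data (each feature contributes its own rows).
#' A duration missing either feature for an observer is dropped for that
#' observer with a warning.
#'
#' @param trials Trial table with `observer_id`, `duration_ms`,
#'   `loc_correct`, `id_correct`.
#'
#' @return A list with `mean_difference` (grand mean, proportion),
#'   `per_observer` (tibble of per-observer mean differences), and
#'   `per_cell` (observer x duration differences).
#' @export
mean_accuracy_difference <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("observer_id", "duration_ms", "loc_correct", "id_correct") %in%
                  names(trials)))
  acc <- function(col) {
    trials |>
      dplyr::filter(!is.na(.data[[col]])) |>
      dplyr::group_by(.data$observer_id, .data$duration_ms) |>
      dplyr::summarise(acc = mean(.data[[col]]), .groups = "drop")
  }
  cells <- dplyr::inner_join(acc("loc_correct"), acc("id_correct"),
                             by = c("observer_id", "duration_ms"),
                             suffix = c("_loc", "_id")) |>
    dplyr::mutate(diff = .data$acc_loc - .data$acc_id)
  n_loc <- nrow(acc("loc_correct")); n_id <- nrow(acc("id_correct"))
  if (nrow(cells) < max(n_loc, n_id))
    warning("Some observer x duration cells lack one feature's accuracy; dropped.",
            call. = FALSE)
  if (nrow(cells) == 0L)
    stop("No observer x duration cell has both features' accuracy.", call. = FALSE)
  per_obs <- cells |>
    dplyr::group_by(.data$observer_id) |>
    dplyr::summarise(mean_diff = mean(.data$diff), .groups = "drop")
  list(mean_difference = mean(per_obs$mean_diff),
       per_observer = per_obs,
       per_cell = cells)
}
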