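# Stochastic-independence analysis of dual-feature reports: per observer and
# exposure duration, the observed joint probabilities of the four
# (location correct/wrong) x (identity correct/wrong) outcomes are compared
# with the probabilities predicted from the observed marginals under
# independence, and their agreement is summarised per observer as a Pearson
# correlation.

#' Observed joint report-outcome probabilities
#'
#' Tallies, for every observer x exposure duration, the relative frequencies
#' of the four joint outcomes of a dual-report trial: both features correct
#' (`p_cc`), location only (`p_cw`), identity only (`p_wc`), neither
#' (`p_ww`). The first index is the location report, the second the identity
#' report.
#'
#' @param trials Dual-report trial table; rows missing either correctness
#'   flag are rejected.
#'
#' @return A tibble with `observer_id`, `duration_s`, `p_cc`, `p_cw`,
#'   `p_wc`, `p_ww`, `n_trials`; one row per observer x duration cell.
#' @export
observed_joint <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("observer_id", "duration_ms", "loc_correct", "id_correct") %in%
                  names(trials)))
  if (anyNA(trials$loc_correct) || anyNA(trials$id_correct))
    stop("The independence analysis needs dual-report trials with both correctness flags.",
         call. = FALSE)
  trials |>
    dplyr::group_by(.data$observer_id, duration_s = .data$duration_ms / 1000) |>
    dplyr::summarise(
      p_cc = mean(.data$loc_correct & .data$id_correct),
      p_cw = mean(.data$loc_correct & !.data$id_correct),
      p_wc = mean(!.data$loc_correct & .data$id_correct),
      p_ww = mean(!.data$loc_correct & !.data$id_correct),
      n_trials = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(.data$observer_id, .data$duration_s)
}

#' Joint probabilities predicted under stochastic independence
#'
#' From each cell's observed marginals — `a = p_cc + p_cw` (location
#' correct) and `b = p_cc + p_wc` (identity correct) — the four joint
#' probabilities a stochastically independent pair of reports would produce:
#' `(ab, a(1-b), (1-a)b, (1-a)(1-b))`. The marginals of the predicted table
#' equal the observed marginals exactly and each row sums to 1.
#'
#' @param observed A table from [observed_joint()].
#'
#' @return A tibble of the same shape with predicted `p_cc`, `p_cw`,
#'   `p_wc`, `p_ww`.
#' @export
predicted_joint <- function(observed) {
  stopifnot(is.data.frame(observed),
            all(c("p_cc", "p_cw", "p_wc", "p_ww") %in% names(observed)))
  tot <- observed$p_cc + observed$p_cw + observed$p_wc + observed$p_ww
  if (any(abs(tot - 1) > 1e-12))
    stop("Observed joint probabilities must sum to 1 in every cell.", call. = FALSE)
  a <- observed$p_cc + observed$p_cw
  b <- observed$p_cc + observed$p_wc
  out <- observed
  out$p_cc <- a * b
  out$p_cw <- a * (1 - b)
  out$p_wc <- (1 - a) * b
  out$p_ww <- (1 - a) * (1 - b)
  out
}

#' Per-observer correlation of observed and predicted joint probabilities
#'
#' For each observer, the Pearson correlation over the stacked vector of all
#' duration x outcome-cell probability pairs. Under stochastic independence
#' this correlation approaches 1 as trial counts grow. By default all four
#' joint cells enter the vector; `cells = "diagonal"` restricts it to the
#' both-correct and both-wrong cells as a sensitivity variant.
#'
#' @param observed,predicted Matched tables ([observed_joint()],
#'   [predicted_joint()]): same observers and durations.
#' @param cells `"all"` (default) or `"diagonal"`.
#'
#' @return A tibble with `observer_id` and `r`. An observer with zero
#'   variance in either vector gets `r = NA` with a warning (excluded from
#'   the group test downstream).
#' @export
observer_correlation <- function(observed, predicted, cells = c("all", "diagonal")) {
  cells <- match.arg(cells)
  key <- c("observer_id", "duration_s")
  stopifnot(all(key %in% names(observed)), all(key %in% names(predicted)))
  if (!identical(observed[key], predicted[key]))
    stop("Observed and predicted tables must cover identical observer x duration cells.",
         call. = FALSE)
  cols <- if (cells == "all") c("p_cc", "p_cw", "p_wc", "p_ww") else c("p_cc", "p_ww")
  long_obs <- tidyr::pivot_longer(observed[c(key, cols)], dplyr::all_of(cols),
                                  names_to = "cell", values_to = "observed_p")
  long_pred <- tidyr::pivot_longer(predicted[c(key, cols)], dplyr::all_of(cols),
                                   names_to = "cell", values_to = "predicted_p")
  both <- dplyr::bind_cols(long_obs, predicted_p = long_pred$predicted_p)
  out <- both |>
    dplyr::group_by(.data$observer_id) |>
    dplyr::summarise(
      r = if (stats::sd(.data$observed_p) == 0 || stats::sd(.data$predicted_p) == 0)
        NA_real_ else stats::cor(.data$observed_p, .data$predicted_p),
      .groups = "drop")
  if (anyNA(out$r))
    warning("Zero-variance probability vector(s); correlation undefined for ",
            paste(out$observer_id[is.na(out$r)], collapse = ", "), call. = FALSE)
  out
}

#' Group test of the independence correlations
#'
#' One-sample t test of the per-observer observed-vs-predicted correlations
#' against zero, with Cohen's d_z and the JZS Bayes factor (see
#' [paired_t_test()]). `NA` correlations are excluded with a warning.
#'
#' @param rs Numeric vector of per-observer correlations (>= 2 valid values).
#'
#' @return A `group_test_result`.
#' @export
independence_group_test <- function(rs) {
  if (anyNA(rs)) {
    warning("Dropping ", sum(is.na(rs)), " undefined correlation(s).", call. = FALSE)
    rs <- rs[!is.na(rs)]
  }
  if (length(rs) < 2L)
    stop("Need at least 2 valid correlations for the group test.", call. = FALSE)
  if (any(abs(rs) > 1)) stop("Correlations must lie in [-1, 1].", call. = FALSE)
  paired_t_test(rs)
}

#' Full stochastic-independence analysis of a dual-report trial table
#'
#' Convenience wrapper chaining [observed_joint()], [predicted_joint()],
#' [observer_correlation()] and [independence_group_test()].
#'
#' @inheritParams observed_joint
#' @inheritParams observer_correlation
#'
#' @return A list of class `independence_result`: `observed`, `predicted`,
#'   `per_observer_r` (tibble), `mean_r`, `sd_r`, `group_test`, `cells`.
#' @export
independence_analysis <- function(trials, cells = c("all", "diagonal")) {
  cells <- match.arg(cells)
  obs <- observed_joint(trials)
  pred <- predicted_joint(obs)
  rs <- observer_correlation(obs, pred, cells = cells)
  structure(list(observed = obs,
                 predicted = pred,
                 per_observer_r = rs,
                 mean_r = mean(rs$r, na.rm = TRUE),
                 sd_r = stats::sd(rs$r, na.rm = TRUE),
                 group_test = independence_group_test(rs$r),
                 cells = cells),
            class = "independence_result")
}

#' @export
print.independence_result <- function(x, ...) {
  cat(sprintf("Stochastic independence: mean r = %.4f (SD = %.4f) over %d observers\n",
              x$mean_r, x$sd_r, nrow(x$per_observer_r)))
  print(x$group_test)
  invisible(x)
}
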