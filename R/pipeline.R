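# End-to-end orchestration: validate a trial table, run the dual-report
# (independence + per-order fits + ANOVA) or blocked-report (per-feature
# fits) analysis, and serialise the result bundle to JSON/CSV reports.

#' Analysis configuration
#'
#' @param mode `"exp1"` (dual report: independence analysis, per-order and
#'   pooled fits, 2x2 ANOVA) or `"exp2"` (blocked report: per-feature fits).
#' @param chance Guessing probability, default 1/12.
#' @param control Fitting controls ([fit_control()]).
#' @param independence_cells Cell convention for [observer_correlation()].
#' @param ci_level Confidence level for within-subject CIs.
#' @param prior_scale_r Cauchy prior scale for the Bayes factors.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("exp1", "exp2"), chance = 1 / 12,
                            control = fit_control(),
                            independence_cells = c("all", "diagonal"),
                            ci_level = 0.95, prior_scale_r = 0.707) {
  structure(list(mode = match.arg(mode), chance = chance, control = control,
                 independence_cells = match.arg(independence_cells),
                 ci_level = ci_level, prior_scale_r = prior_scale_r),
            class = "analysis_config")
}

log_info <- function(log, fmt, ...) {
  line <- sprintf(paste0("INFO: ", fmt), ...)
  message(line)
  c(log, line)
}
log_warn <- function(log, fmt, ...) {
  line <- sprintf(paste0("WARN: ", fmt), ...)
  warning(sub("^WARN: ", "", line), call. = FALSE)
  c(log, line)
}

fit_one_cell <- function(trials, feature, chance, control) {
  counts <- aggregate_counts(trials, feature)
  fit_psychometric(counts, chance = chance, control = control)
}

#' Run the full analysis on a trial table
#'
#' Dual-report mode (`exp1`) requires both correctness flags on every trial
#' and both report orders; it runs the stochastic-independence analysis,
#' fits the psychometric function per observer x feature x report order and
#' pooled over order, tests the location-identity contrasts on the pooled
#' `t0`, `v` and on the accuracy advantage (paired/one-sample t, Cohen's
#' d_z, JZS BF10), runs the 2x2 (feature x report order) repeated-measures
#' ANOVA on `t0` and on `v` with Holm-corrected pairwise follow-ups across
#' the feature contrast, and computes within-subject CIs. Blocked mode
#' (`exp2`) requires exactly one report per trial and runs the per-feature
#' fits, the same contrasts, and the CIs.
#'
#' Observers whose fit fails in any required cell are excluded from the
#' group statistics with a warning; exclusions are recorded in the bundle
#' log, so rows in = rows analysed + rows excluded at every stage.
#'
#' @param trials A validated trial table ([read_trials()] or
#'   [simulate_experiment()]).
#' @param config An [analysis_config()].
#'
#' @return A list of class `report_bundle`; see [write_report()].
#' @export
run_analysis <- function(trials, config = analysis_config()) {
  stopifnot(is.data.frame(trials), inherits(config, "analysis_config"))
  log <- character(0)
  log <- log_info(log, "mode=%s rows_in=%d observers=%d", config$mode,
                  nrow(trials), length(unique(trials$observer_id)))

  has_loc <- !is.na(trials$loc_correct)
  has_id <- !is.na(trials$id_correct)
  if (config$mode == "exp1") {
    if (!all(has_loc & has_id))
      stop("exp1 mode needs dual-report trials with both correctness flags on every row.",
           call. = FALSE)
    if (!all(c("location_first", "identity_first") %in% trials$report_order))
      stop("exp1 mode needs both report orders present.", call. = FALSE)
  } else {
    if (any(has_loc & has_id))
      stop("exp2 mode expects blocked trials (exactly one report per trial); ",
           "found dual-report rows.", call. = FALSE)
    if (!any(has_loc) || !any(has_id))
      stop("exp2 mode needs blocked trials for both features.", call. = FALSE)
  }
  observers <- sort(unique(trials$observer_id))
  if (length(observers) < 2L)
    stop("Need at least 2 observers for the group statistics.", call. = FALSE)

  conditions <- if (config$mode == "exp1")
    c("location_first", "identity_first", "pooled") else "blocked"

  fits <- list(); excluded <- character(0)
  for (obs_id in observers) {
    obs_trials <- trials[trials$observer_id == obs_id, ]
    ok <- TRUE
    for (feature in c("location", "identity")) {
      for (cond in conditions) {
        sub <- switch(cond,
                      pooled = , blocked = obs_trials,
                      obs_trials[obs_trials$report_order == cond, ])
        fit <- tryCatch(fit_one_cell(sub, feature, config$chance, config$control),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          log <- log_warn(log, "fit failed for %s/%s/%s: %s; observer excluded",
                          obs_id, feature, cond, conditionMessage(fit))
          ok <- FALSE
        } else {
          fits[[length(fits) + 1L]] <- tibble::tibble(
            observer_id = obs_id, feature = feature, condition = cond,
            t0_s = fit$params$t0_s, v_per_s = fit$params$v_per_s,
            nll = fit$nll, converged = fit$converged,
            at_bound = paste(fit$at_bound, collapse = ";"),
            n_trials = sum(!is.na(sub[[if (feature == "location")
              "loc_correct" else "id_correct"]])))
        }
      }
    }
    if (!ok) excluded <- c(excluded, obs_id)
  }
  fits <- dplyr::bind_rows(fits)
  fits <- fits[!fits$observer_id %in% excluded, ]
  kept <- setdiff(observers, excluded)
  if (length(kept) < 2L)
    stop("Fewer than 2 observers with complete fits; cannot run group statistics.",
         call. = FALSE)
  log <- log_info(log, "fits=%d observers_kept=%d excluded=%d",
                  nrow(fits), length(kept), length(excluded))
  kept_trials <- trials[trials$observer_id %in% kept, ]

  main_cond <- if (config$mode == "exp1") "pooled" else "blocked"
  wide <- function(par, cond = main_cond) {
    sub <- fits[fits$condition == cond, ]
    m <- tidyr::pivot_wider(sub[c("observer_id", "feature", par)],
                            names_from = "feature", values_from = dplyr::all_of(par))
    m[order(m$observer_id), ]
  }
  t0_w <- wide("t0_s"); v_w <- wide("v_per_s")
  acc <- mean_accuracy_difference(kept_trials)
  contrasts <- list(
    t0_location_vs_identity = paired_t_test(t0_w$location, t0_w$identity,
                                            prior_scale_r = config$prior_scale_r),
    v_location_vs_identity = paired_t_test(v_w$location, v_w$identity,
                                           prior_scale_r = config$prior_scale_r),
    accuracy_location_vs_identity = paired_t_test(
      acc$per_observer$mean_diff[order(acc$per_observer$observer_id)],
      prior_scale_r = config$prior_scale_r))
  log <- log_info(log, "contrasts=%d accuracy_advantage=%.4f",
                  length(contrasts), acc$mean_difference)

  independence <- NULL; anova <- NULL; posthoc <- NULL
  if (config$mode == "exp1") {
    independence <- independence_analysis(kept_trials,
                                          cells = config$independence_cells)
    log <- log_info(log, "independence mean_r=%.4f over %d observers",
                    independence$mean_r, nrow(independence$per_observer_r))
    cell_fits <- fits[fits$condition != "pooled", ]
    anova <- list(
      t0 = rm_anova_2x2(cell_fits, value = "t0_s", observer = "observer_id",
                        factor_a = "feature", factor_b = "condition"),
      v = rm_anova_2x2(cell_fits, value = "v_per_s", observer = "observer_id",
                       factor_a = "feature", factor_b = "condition"))
    posthoc <- holm_posthoc_2x2(cell_fits, prior_scale_r = config$prior_scale_r)
    log <- log_info(log, "anova: v order effect F(1,%d)=%.3f", length(kept) - 1,
                    anova$v$F[anova$v$effect == "B"])
  }

  ci_input <- function(w) {
    m <- as.matrix(w[c("location", "identity")])
    rownames(m) <- w$observer_id
    m
  }
  acc_wide <- kept_trials |>
    (\(tr) dplyr::bind_rows(
      dplyr::filter(tr, !is.na(.data$loc_correct)) |>
        dplyr::group_by(.data$observer_id, .data$duration_ms) |>
        dplyr::summarise(acc = mean(.data$loc_correct), .groups = "drop") |>
        dplyr::mutate(feature = "location"),
      dplyr::filter(tr, !is.na(.data$id_correct)) |>
        dplyr::group_by(.data$observer_id, .data$duration_ms) |>
        dplyr::summarise(acc = mean(.data$id_correct), .groups = "drop") |>
        dplyr::mutate(feature = "identity")))() |>
    tidyr::pivot_wider(names_from = c("feature", "duration_ms"),
                       values_from = "acc", names_sep = "_")
  cis <- list(
    t0 = within_subject_ci(ci_input(t0_w), level = config$ci_level),
    v = within_subject_ci(ci_input(v_w), level = config$ci_level),
    accuracy = within_subject_ci(as.matrix(acc_wide[-1]), level = config$ci_level))

  aggregate <- fits[fits$condition == main_cond, ] |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(t0_s = mean(.data$t0_s), v_per_s = mean(.data$v_per_s),
                     .groups = "drop")

  structure(list(mode = config$mode, config = config, fits = fits,
                 aggregate = aggregate, independence = independence,
                 contrasts = contrasts, anova = anova, posthoc = posthoc,
                 cis = cis, accuracy = acc, observers = kept,
                 excluded = excluded, log = log),
            class = "report_bundle")
}

# Holm-corrected pairwise follow-ups across the feature contrast of the 2x2
# (the four location-vs-identity cell comparisons), run for t0 and v
holm_posthoc_2x2 <- function(cell_fits, prior_scale_r = 0.707) {
  orders <- c("location_first", "identity_first")
  out <- list()
  for (par in c("t0_s", "v_per_s")) {
    grid <- expand.grid(loc_order = orders, id_order = orders,
                        stringsAsFactors = FALSE)
    tests <- purrr::pmap(grid, function(loc_order, id_order) {
      x <- cell_fits[cell_fits$feature == "location" &
                       cell_fits$condition == loc_order, ]
      y <- cell_fits[cell_fits$feature == "identity" &
                       cell_fits$condition == id_order, ]
      x <- x[order(x$observer_id), ]; y <- y[order(y$observer_id), ]
      tt <- paired_t_test(x[[par]], y[[par]], prior_scale_r = prior_scale_r)
      tibble::tibble(parameter = par,
                     comparison = sprintf("location@%s vs identity@%s",
                                          loc_order, id_order),
                     t = tt$t, df = tt$df, p = tt$p, d_z = tt$d_z,
                     bf10 = tt$bf10)
    })
    block <- dplyr::bind_rows(tests)
    block$p_holm <- holm_adjust(block$p)
    out[[par]] <- block
  }
  dplyr::bind_rows(out)
}

bundle_json <- function(bundle) {
  gt <- function(x) if (is.null(x)) NULL else
    list(t = x$t, df = x$df, p = x$p, d_z = x$d_z, bf10 = x$bf10,
         n = x$n, mean_diff = x$mean_diff, degenerate = x$degenerate)
  an <- function(a) if (is.null(a)) NULL else
    lapply(stats::setNames(seq_len(nrow(a)), a$effect), function(i)
      list(F = a$F[i], df_num = a$df_num[i], df_den = a$df_den[i],
           p = a$p[i], eta_g_sq = a$eta_g_sq[i]))
  list(
    mode = bundle$mode,
    observers = bundle$observers,
    excluded = bundle$excluded,
    aggregate_params = bundle$aggregate,
    accuracy_advantage = list(
      mean_difference = bundle$accuracy$mean_difference,
      per_observer = bundle$accuracy$per_observer),
    contrasts = lapply(bundle$contrasts, gt),
    independence = if (!is.null(bundle$independence)) list(
      mean_r = bundle$independence$mean_r,
      sd_r = bundle$independence$sd_r,
      per_observer_r = bundle$independence$per_observer_r,
      group_test = gt(bundle$independence$group_test),
      cells = bundle$independence$cells),
    anova = if (!is.null(bundle$anova))
      list(t0 = an(bundle$anova$t0), v = an(bundle$anova$v)),
    log = bundle$log)
}

#' Serialise a report bundle to disk
#'
#' Writes a deterministic file set: `report.json` (full summary),
#' `fits.csv`, `contrasts.csv`, `cis.csv`, `independence_cells.csv` (only
#' in dual-report mode; its absence is noted in the manifest), `posthoc.csv`
#' (dual-report mode), and `log.txt`. Identical bundles produce identical
#' bytes: no timestamps or environment details are embedded.
#'
#' @param bundle A `report_bundle` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#'
#' @return A manifest tibble (`file`, `bytes`, `present`), invisibly the
#'   same files on disk.
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0)
    stop("Output directory is not writable: ", out_dir, call. = FALSE)

  paths <- list()
  jsonlite::write_json(bundle_json(bundle), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  paths$report.json <- TRUE

  readr::write_csv(bundle$fits, file.path(out_dir, "fits.csv"))
  paths$fits.csv <- TRUE

  contrasts_df <- dplyr::bind_rows(purrr::imap(bundle$contrasts, function(x, nm)
    tibble::tibble(comparison = nm, t = x$t, df = x$df, p = x$p,
                   d_z = x$d_z, bf10 = x$bf10)))
  readr::write_csv(contrasts_df, file.path(out_dir, "contrasts.csv"))
  paths$contrasts.csv <- TRUE

  cis_df <- dplyr::bind_rows(purrr::imap(bundle$cis, function(x, nm)
    dplyr::mutate(x, quantity = nm, .before = 1)))
  readr::write_csv(cis_df, file.path(out_dir, "cis.csv"))
  paths$cis.csv <- TRUE

  if (!is.null(bundle$independence)) {
    long <- function(tab, which) {
      tab |>
        tidyr::pivot_longer(c("p_cc", "p_cw", "p_wc", "p_ww"),
                            names_to = "cell", values_to = paste0(which, "_p")) |>
        dplyr::mutate(duration_ms = 1000 * .data$duration_s) |>
        dplyr::select("observer_id", "duration_ms", "cell",
                      dplyr::ends_with("_p"))
    }
    cells <- dplyr::inner_join(long(bundle$independence$observed, "observed"),
                               long(bundle$independence$predicted, "predicted"),
                               by = c("observer_id", "duration_ms", "cell"))
    readr::write_csv(cells, file.path(out_dir, "independence_cells.csv"))
    paths$independence_cells.csv <- TRUE
  } else paths$independence_cells.csv <- FALSE

  if (!is.null(bundle$posthoc)) {
    readr::write_csv(bundle$posthoc, file.path(out_dir, "posthoc.csv"))
    paths$posthoc.csv <- TRUE
  } else paths$posthoc.csv <- FALSE

  writeLines(bundle$log, file.path(out_dir, "log.txt"))
  paths$log.txt <- TRUE

  manifest <- tibble::tibble(
    file = names(paths),
    present = unlist(paths),
    bytes = vapply(names(paths), function(f) {
      p <- file.path(out_dir, f)
      if (file.exists(p)) file.size(p) else NA_real_
    }, numeric(1)))
  manifest
}
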