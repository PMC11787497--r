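#' Psychometric parameter set
#'
#' Bundles the two TVA parameters of a single observer x feature x condition
#' psychometric function together with the fixed guessing probability.
#'
#' @param t0_s Temporal perception threshold in seconds: the minimum exposure
#'   duration before visual processing starts. Below it, report accuracy
#'   equals `chance`. Must be >= 0.
#' @param v_per_s Visual processing speed in objects per second: the
#'   exponential rate at which encoding probability approaches 1 beyond
#'   `t0_s`. Must be > 0.
#' @param chance Probability of a correct uniform guess; 1/12 for the
#'   12-alternative letter/location designs. Must be strictly in (0, 1).
#'
#' @return An object of class `psychometric_params` (a named list).
#' @export
psychometric_params <- function(t0_s, v_per_s, chance = 1 / 12) {
  stopifnot(is.numeric(t0_s), length(t0_s) == 1L, is.finite(t0_s),
            is.numeric(v_per_s), length(v_per_s) == 1L, is.finite(v_per_s),
            is.numeric(chance), length(chance) == 1L)
  if (t0_s < 0) stop("`t0_s` must be non-negative (seconds).", call. = FALSE)
  if (v_per_s <= 0) stop("`v_per_s` must be positive (objects/second).", call. = FALSE)
  if (chance <= 0 || chance >= 1) stop("`chance` must lie strictly in (0, 1).", call. = FALSE)
  structure(list(t0_s = t0_s, v_per_s = v_per_s, chance = chance),
            class = "psychometric_params")
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf("TVA psychometric parameters: t0 = %.1f ms, v = %.2f /s, chance = %.4f\n",
              1000 * x$t0_s, x$v_per_s, x$chance))
  invisible(x)
}

#' Probability that a feature is encoded into visual working memory
#'
#' The exponential encoding race: nothing is encoded before the temporal
#' threshold `t0`; beyond it, the probability of successful encoding rises as
#' `1 - exp(-v * (t - t0))`.
#'
#' @param params A [psychometric_params()] object.
#' @param t Exposure duration(s) in seconds; non-negative, vectorised.
#'
#' @return Encoding probabilities in `[0, 1)`, same length as `t`.
#' @export
encoding_probability <- function(params, t) {
  stopifnot(inherits(params, "psychometric_params"), is.numeric(t))
  if (any(t < 0)) stop("Exposure durations `t` must be non-negative.", call. = FALSE)
  dt <- pmax(t - params$t0_s, 0)
  -expm1(-params$v_per_s * dt)
}

#' TVA psychometric function: probability of a correct report
#'
#' Report accuracy as a mixture of encoding and guessing: chance below the
#' temporal threshold; beyond it, `p_enc + (1 - p_enc) * chance`, an
#' exponential approach towards perfect performance. Continuous at `t = t0`.
#'
#' @inheritParams encoding_probability
#'
#' @return Probabilities in `[chance, 1)`, same length as `t`.
#' @export
evaluate_psychometric <- function(params, t) {
  p_enc <- encoding_probability(params, t)
  p_enc + (1 - p_enc) * params$chance
}

#' Per-duration binomial counts from trial-level data
#'
#' Collapses a trial table to the sufficient statistic of the binomial
#' likelihood: number of trials and number correct at each exposure duration.
#'
#' @param trials A trial table (see [simulate_experiment()] / [read_trials()]).
#' @param feature `"location"` or `"identity"`: which correctness column to
#'   tally (`loc_correct` / `id_correct`). Rows where that column is `NA`
#'   (e.g. the other feature's blocked trials) are dropped.
#'
#' @return A tibble with `duration_s`, `n_trials`, `n_correct`, ordered by
#'   duration.
#' @export
aggregate_counts <- function(trials, feature = c("location", "identity")) {
  feature <- match.arg(feature)
  col <- if (feature == "location") "loc_correct" else "id_correct"
  stopifnot(is.data.frame(trials), all(c("duration_ms", col) %in% names(trials)))
  trials |>
    dplyr::filter(!is.na(.data[[col]])) |>
    dplyr::group_by(duration_s = .data$duration_ms / 1000) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_correct = sum(.data[[col]]),
                     .groups = "drop") |>
    dplyr::arrange(.data$duration_s)
}

check_counts <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("duration_s", "n_trials", "n_correct") %in% names(data)))
  if (any(data$duration_s <= 0)) stop("Durations must be positive.", call. = FALSE)
  if (any(data$n_correct < 0 | data$n_correct > data$n_trials))
    stop("Counts must satisfy 0 <= n_correct <= n_trials.", call. = FALSE)
  data <- data[data$n_trials > 0, , drop = FALSE]
  if (nrow(data) == 0L) stop("No durations with a positive trial count.", call. = FALSE)
  data
}

#' Negative log-likelihood of per-duration binomial counts
#'
#' The binomial deviance kernel `-sum(k * log p + (n - k) * log(1 - p))`
#' (binomial coefficients omitted), with `p` the psychometric function at each
#' duration. Computed with the tail `1 - p = exp(-v (t - t0)) (1 - chance)`
#' evaluated in log space, so it stays finite even when `v * (t - t0)` is
#' large. Rows with zero trials are skipped.
#'
#' @inheritParams encoding_probability
#' @param data A data frame of counts as returned by [aggregate_counts()].
#'
#' @return A finite scalar (chance > 0 bounds `p` away from 0 and 1).
#' @export
neg_log_likelihood <- function(params, data) {
  data <- check_counts(data)
  dt <- pmax(data$duration_s - params$t0_s, 0)
  log_tail <- -params$v_per_s * dt + log1p(-params$chance)   # log(1 - p)
  log_p <- log1p(-exp(log_tail))                             # log(p)
  -sum(data$n_correct * log_p + (data$n_trials - data$n_correct) * log_tail)
}

#' Fitting controls for [fit_psychometric()]
#'
#' @param t0_bounds Search box for `t0` in seconds.
#' @param v_bounds Search box for `v` in objects/second.
#' @param t0_starts,v_starts Coarse multi-start grid (seconds, /s).
#' @param n_refine How many of the best grid starts get a local refinement.
#' @param reltol Relative convergence tolerance of the simplex refinement.
#' @param bound_tol Relative distance below which a fitted parameter is
#'   flagged as sitting on a search bound.
#'
#' @return A list of settings.
#' @export
fit_control <- function(t0_bounds = c(0, 0.150),
                        v_bounds = c(0.5, 500),
                        t0_starts = seq(0, 0.120, by = 0.010),
                        v_starts = c(5, 10, 20, 40, 80, 160),
                        n_refine = 3L,
                        reltol = 1e-10,
                        bound_tol = 1e-3) {
  stopifnot(t0_bounds[1] >= 0, diff(t0_bounds) > 0,
            v_bounds[1] > 0, diff(v_bounds) > 0, n_refine >= 1L)
  list(t0_bounds = t0_bounds, v_bounds = v_bounds,
       t0_starts = t0_starts, v_starts = v_starts,
       n_refine = as.integer(n_refine), reltol = reltol, bound_tol = bound_tol)
}

#' Maximum-likelihood fit of the TVA psychometric function
#'
#' Minimises [neg_log_likelihood()] over `(t0, v)` inside the control's search
#' box. A coarse grid of starting points is evaluated first; the best
#' `n_refine` starts are refined by Nelder-Mead (the likelihood has a kink in
#' `t0` where the threshold crosses a sampled duration, so a derivative-free
#' simplex is used). `v` is optimised on the log scale; excursions outside the
#' box are pulled back by a quadratic penalty. Ties between candidate optima
#' are broken by lower NLL, then lower `t0`.
#'
#' Data whose accuracy is at chance for every duration carry no information
#' about the parameters; the optimiser then runs `v` into its lower bound and
#' the fit is returned with `converged = FALSE` and `"v_per_s"` in
#' `at_bound` rather than raising an error.
#'
#' @param data Per-duration counts (see [aggregate_counts()]); at least three
#'   distinct durations with trials are required.
#' @param chance Guessing probability, fixed (never estimated); default 1/12.
#' @param control A [fit_control()] list.
#'
#' @return An object of class `fit_result`: a list with `params`
#'   ([psychometric_params()]), `nll`, `converged`, `n_starts`, `at_bound`.
#' @export
fit_psychometric <- function(data, chance = 1 / 12, control = fit_control()) {
  data <- check_counts(data)
  if (length(unique(data$duration_s)) < 3L)
    stop("Need at least 3 distinct durations with trials to fit (t0, v).", call. = FALSE)

  t0_lo <- control$t0_bounds[1]; t0_hi <- control$t0_bounds[2]
  lv_lo <- log(control$v_bounds[1]); lv_hi <- log(control$v_bounds[2])

  nll_at <- function(t0, v)
    neg_log_likelihood(psychometric_params(t0, v, chance), data)

  # objective on (t0, log v); clamp into the box with a quadratic penalty so
  # the simplex can probe past a bound without blowing up
  objective <- function(par) {
    t0 <- par[1]; lv <- par[2]
    t0c <- min(max(t0, t0_lo), t0_hi)
    lvc <- min(max(lv, lv_lo), lv_hi)
    pen <- 1e6 * ((t0 - t0c)^2 + (lv - lvc)^2)
    nll_at(t0c, exp(lvc)) + pen
  }

  starts <- expand.grid(t0 = control$t0_starts, v = control$v_starts)
  starts <- starts[starts$t0 >= t0_lo & starts$t0 <= t0_hi &
                   starts$v >= control$v_bounds[1] & starts$v <= control$v_bounds[2], ]
  start_nll <- mapply(nll_at, starts$t0, starts$v)
  ord <- order(start_nll, starts$t0)
  keep <- utils::head(ord, control$n_refine)

  cand <- lapply(keep, function(i) {
    opt <- stats::optim(c(starts$t0[i], log(starts$v[i])), objective,
                        method = "Nelder-Mead",
                        control = list(reltol = control$reltol, maxit = 2000L))
    t0 <- min(max(opt$par[1], t0_lo), t0_hi)
    v <- exp(min(max(opt$par[2], lv_lo), lv_hi))
    list(t0 = t0, v = v, nll = nll_at(t0, v), ok = opt$convergence == 0L)
  })
  nlls <- vapply(cand, `[[`, numeric(1), "nll")
  t0s <- vapply(cand, `[[`, numeric(1), "t0")
  best <- cand[[order(nlls, t0s)[1]]]

  at_bound <- character(0)
  if (min(best$t0 - t0_lo, t0_hi - best$t0) <= control$bound_tol * (t0_hi - t0_lo))
    at_bound <- c(at_bound, "t0_s")
  if (min(log(best$v) - lv_lo, lv_hi - log(best$v)) <= control$bound_tol * (lv_hi - lv_lo))
    at_bound <- c(at_bound, "v_per_s")
  v_floor <- "v_per_s" %in% at_bound && log(best$v) - lv_lo <= control$bound_tol * (lv_hi - lv_lo)

  structure(list(params = psychometric_params(best$t0, best$v, chance),
                 nll = best$nll,
                 converged = best$ok && !v_floor,
                 n_starts = nrow(starts),
                 at_bound = at_bound),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("TVA fit: t0 = %.2f ms, v = %.2f /s (NLL = %.4f, %s%s)\n",
              1000 * x$params$t0_s, x$params$v_per_s, x$nll,
              if (x$converged) "converged" else "NOT converged",
              if (length(x$at_bound)) paste0("; at bound: ",
                                             paste(x$at_bound, collapse = ", ")) else ""))
  invisible(x)
}

#' Aggregate-observer parameters
#'
#' The descriptive group-level psychometric curve: arithmetic means of the
#' individually fitted `t0` and `v`, with the common guessing probability
#' carried through.
#'
#' @param fits A non-empty list of [psychometric_params()] (or `fit_result`)
#'   objects sharing one `chance` value.
#'
#' @return A single [psychometric_params()] object.
#' @export
aggregate_params <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  ps <- lapply(fits, function(f) if (inherits(f, "fit_result")) f$params else f)
  stopifnot(all(vapply(ps, inherits, logical(1), "psychometric_params")))
  chances <- vapply(ps, `[[`, numeric(1), "chance")
  if (length(unique(chances)) != 1L)
    stop("All fits must share the same `chance` value.", call. = FALSE)
  psychometric_params(mean(vapply(ps, `[[`, numeric(1), "t0_s")),
                      mean(vapply(ps, `[[`, numeric(1), "v_per_s")),
                      chances[1])
}
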