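# Synthetic trial generator emulating masked single-target report designs:
# dual report (both features reported each trial, order counterbalanced) and
# blocked report (one feature per block). Encoding events follow the TVA
# psychometric function; non-encoded features are guessed uniformly.

#' Canonical letter set of the masked-report paradigm
#' @export
LETTER_SET <- strsplit("ABFGHJLMRSTX", "")[[1]]

#' Canonical exposure durations (ms)
#'
#' The eleven target durations of the masked-report designs.
#' @export
CANONICAL_DURATIONS_MS <- c(12, 24, 35, 47, 59, 71, 82, 106, 129, 176, 224)

#' Observer specification for simulation
#'
#' @param observer_id Character id.
#' @param params_location,params_identity [psychometric_params()] for the two
#'   features.
#' @param dependence_rho Coupling in `[0, 1]` between the two features'
#'   encoding events: 0 = independent (the generative assumption of the
#'   analysis), 1 = comonotone (a single shared uniform decides both).
#'   Intermediate values mix the two regimes; the marginals are unaffected.
#'   This knob exists purely to exercise the independence analysis; it has no
#'   counterpart in real data.
#'
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(observer_id, params_location, params_identity,
                          dependence_rho = 0) {
  stopifnot(is.character(observer_id), length(observer_id) == 1L,
            inherits(params_location, "psychometric_params"),
            inherits(params_identity, "psychometric_params"))
  if (!is.numeric(dependence_rho) || length(dependence_rho) != 1L ||
      dependence_rho < 0 || dependence_rho > 1)
    stop("`dependence_rho` must be a single value in [0, 1].", call. = FALSE)
  structure(list(observer_id = observer_id,
                 params_location = params_location,
                 params_identity = params_identity,
                 dependence_rho = dependence_rho),
            class = "observer_spec")
}

#' Design specification for simulation
#'
#' @param durations_ms Strictly increasing exposure durations in ms; defaults
#'   to the canonical eleven.
#' @param trials_per_cell Trials per duration x (report-order or block) cell;
#'   25 reproduces the dual-report sessions (11 x 2 x 25 = 550 trials), 50
#'   the blocked sessions (11 x 50 = 550).
#' @param mode `"dual_report"`, `"blocked_location"` or `"blocked_identity"`.
#' @param n_locations,n_letters Numbers of alternatives (>= 2); guessing is
#'   uniform, so chance = 1/n per feature.
#' @param n_sessions Homogeneous sessions per observer (no learning/fatigue
#'   structure; the model pools them).
#' @param seed Master seed; per-observer substreams are derived from it so
#'   that adding observers does not perturb earlier observers' trials.
#'
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(durations_ms = CANONICAL_DURATIONS_MS,
                        trials_per_cell = 25L,
                        mode = c("dual_report", "blocked_location", "blocked_identity"),
                        n_locations = 12L, n_letters = 12L,
                        n_sessions = 1L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(durations_ms), length(durations_ms) >= 1L,
            all(durations_ms > 0))
  if (is.unsorted(durations_ms, strictly = TRUE))
    stop("`durations_ms` must be strictly increasing.", call. = FALSE)
  if (trials_per_cell < 1L) stop("`trials_per_cell` must be >= 1.", call. = FALSE)
  if (n_locations < 2L || n_letters < 2L)
    stop("`n_locations` and `n_letters` must be >= 2.", call. = FALSE)
  structure(list(durations_ms = durations_ms,
                 trials_per_cell = as.integer(trials_per_cell),
                 mode = mode,
                 n_locations = as.integer(n_locations),
                 n_letters = as.integer(n_letters),
                 n_sessions = as.integer(n_sessions),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Draw a coupled pair of encoding events
#'
#' With probability `rho` one shared uniform is compared against both
#' encoding probabilities (comonotone coupling); otherwise two independent
#' uniforms are used. Either way the marginals are exactly `p_loc_enc` and
#' `p_id_enc`; `rho = 0` makes the events independent, `rho = 1` comonotone
#' (joint success probability `min(p_loc_enc, p_id_enc)`).
#'
#' Vectorised over equal-length probability vectors; draws from the current
#' R random stream.
#'
#' @param p_loc_enc,p_id_enc Encoding probabilities in `[0, 1]`.
#' @param rho Coupling weight in `[0, 1]`.
#'
#' @return A two-column logical matrix `cbind(encoded_loc, encoded_id)`.
#' @export
encode_event_pair <- function(p_loc_enc, p_id_enc, rho) {
  if (any(p_loc_enc < 0 | p_loc_enc > 1) || any(p_id_enc < 0 | p_id_enc > 1))
    stop("Encoding probabilities must lie in [0, 1].", call. = FALSE)
  if (length(rho) != 1L || rho < 0 || rho > 1)
    stop("`rho` must be a single value in [0, 1].", call. = FALSE)
  n <- max(length(p_loc_enc), length(p_id_enc))
  p1 <- rep_len(p_loc_enc, n); p2 <- rep_len(p_id_enc, n)
  shared <- stats::runif(n) < rho
  u_shared <- stats::runif(n)
  u1 <- ifelse(shared, u_shared, stats::runif(n))
  u2 <- ifelse(shared, u_shared, stats::runif(n))
  cbind(encoded_loc = u1 < p1, encoded_id = u2 < p2)
}

#' Draw a cohort of simulated observers
#'
#' Observer parameters are drawn uniformly within the given ranges from a
#' seeded stream, so a cohort is reproducible from its seed.
#'
#' @param n Number of observers (>= 1).
#' @param t0_range_ms Range (ms) for both features' temporal thresholds.
#' @param v_range_per_s Range (/s) for both features' processing speeds.
#' @param chance Guessing probability shared by both features.
#' @param rho Encoding-event coupling passed to every observer.
#' @param seed Seed for the parameter draws.
#' @param t0_range_ms_identity,v_range_per_s_identity Optional separate ranges
#'   for the identity feature (defaults: same as location), used to build
#'   cohorts with a systematic location advantage.
#'
#' @return A list of [observer_spec()] objects.
#' @export
generate_observers <- function(n, t0_range_ms, v_range_per_s, chance = 1 / 12,
                               rho = 0, seed = 1L,
                               t0_range_ms_identity = t0_range_ms,
                               v_range_per_s_identity = v_range_per_s) {
  stopifnot(n >= 1L)
  check_range <- function(r, what) {
    if (length(r) != 2L || any(!is.finite(r)) || r[2] < r[1])
      stop(sprintf("`%s` must be a finite non-inverted range.", what), call. = FALSE)
  }
  check_range(t0_range_ms, "t0_range_ms"); check_range(v_range_per_s, "v_range_per_s")
  check_range(t0_range_ms_identity, "t0_range_ms_identity")
  check_range(v_range_per_s_identity, "v_range_per_s_identity")
  with_preserved_rng({
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      draw <- function(r) stats::runif(1, r[1], r[2])
      observer_spec(
        observer_id = sprintf("obs%02d", i),
        params_location = psychometric_params(draw(t0_range_ms) / 1000,
                                              draw(v_range_per_s), chance),
        params_identity = psychometric_params(draw(t0_range_ms_identity) / 1000,
                                              draw(v_range_per_s_identity), chance),
        dependence_rho = rho)
    })
  })
}

# run `expr` without disturbing the caller's random stream
with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Simulate a masked-report experiment
#'
#' Generates one trial table per the design: targets drawn uniformly over
#' locations and letters, per-feature encoding events drawn through
#' [encode_event_pair()] with probabilities from each observer's psychometric
#' parameters, encoded features reported correctly and non-encoded features
#' guessed uniformly over all alternatives (so accuracy given no encoding is
#' `1/n`). In dual-report mode the report order alternates over the two
#' counterbalanced cells; in blocked modes only the blocked feature's report
#' columns are filled.
#'
#' @param observers A non-empty list of [observer_spec()] objects.
#' @param design A [design_spec()].
#'
#' @return A tibble with one row per trial: `observer_id`, `experiment`
#'   (1 for dual report, 2 for blocked), `session`, `duration_ms`,
#'   `target_location`, `target_letter`, `report_order`, `reported_location`,
#'   `reported_letter`, `loc_correct`, `id_correct` (0-based indices; `NA`
#'   report columns in blocked modes). Row count is exactly
#'   `n_observers * n_sessions * n_durations * trials_per_cell * (2 in dual
#'   mode, else 1)`.
#' @export
simulate_experiment <- function(observers, design) {
  if (!is.list(observers) || length(observers) == 0L)
    stop("`observers` must be a non-empty list of observer_spec objects.", call. = FALSE)
  stopifnot(all(vapply(observers, inherits, logical(1), "observer_spec")),
            inherits(design, "design_spec"))
  dual <- design$mode == "dual_report"
  with_preserved_rng({
    out <- purrr::imap(observers, function(obs, idx) {
      # independent substream per observer: earlier observers' trials are
      # invariant to cohort size
      set.seed((design$seed %% 100003L) * 20011L + idx * 104729L)
      simulate_one_observer(obs, design, dual)
    })
    dplyr::bind_rows(out)
  })
}

simulate_one_observer <- function(obs, design, dual) {
  cells <- expand.grid(
    session = seq_len(design$n_sessions),
    duration_ms = design$durations_ms,
    report_order = if (dual) c("location_first", "identity_first") else "not_applicable",
    stringsAsFactors = FALSE)
  n_per_cell <- design$trials_per_cell
  n <- nrow(cells) * n_per_cell
  duration_ms <- rep(cells$duration_ms, each = n_per_cell)
  t_s <- duration_ms / 1000

  target_location <- sample.int(design$n_locations, n, replace = TRUE) - 1L
  target_letter <- sample.int(design$n_letters, n, replace = TRUE) - 1L

  enc <- encode_event_pair(encoding_probability(obs$params_location, t_s),
                           encoding_probability(obs$params_identity, t_s),
                           obs$dependence_rho)
  guess_loc <- sample.int(design$n_locations, n, replace = TRUE) - 1L
  guess_let <- sample.int(design$n_letters, n, replace = TRUE) - 1L
  reported_location <- ifelse(enc[, "encoded_loc"], target_location, guess_loc)
  reported_letter <- ifelse(enc[, "encoded_id"], target_letter, guess_let)

  if (design$mode == "blocked_location") reported_letter <- NA_integer_
  if (design$mode == "blocked_identity") reported_location <- NA_integer_

  tibble::tibble(
    observer_id = obs$observer_id,
    experiment = if (dual) 1L else 2L,
    session = rep(cells$session, each = n_per_cell),
    duration_ms = duration_ms,
    target_location = target_location,
    target_letter = target_letter,
    report_order = rep(cells$report_order, each = n_per_cell),
    reported_location = as.integer(reported_location),
    reported_letter = as.integer(reported_letter),
    loc_correct = reported_location == target_location,
    id_correct = reported_letter == target_letter)
}
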