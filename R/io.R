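# Trial-table I/O. Canonical CSV columns: observer_id, experiment, session,
# duration_ms, target_location, target_letter, report_order,
# reported_location, reported_letter (0-based indices into the 12 locations
# and the letter set ABFGHJLMRSTX). Booleans are written as 0/1, absent
# values as empty fields; correctness flags are derived, not stored.

TRIAL_COLUMNS <- c("observer_id", "experiment", "session", "duration_ms",
                   "target_location", "target_letter", "report_order",
                   "reported_location", "reported_letter")

#' Write a trial table to CSV
#'
#' @param trials Trial table ([simulate_experiment()] output or compatible).
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(is.data.frame(trials), all(TRIAL_COLUMNS %in% names(trials)))
  readr::write_csv(trials[TRIAL_COLUMNS], path, na = "")
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads the canonical trials CSV, optionally renaming foreign column names
#' first (so externally deposited datasets can be loaded without editing the
#' file). Exposure durations are snapped to the nearest canonical value when
#' within 0.5 ms of one, feature indices are range-checked, and the
#' correctness flags are recomputed from target and report; if the file also
#' carries `loc_correct`/`id_correct` columns they are cross-checked against
#' the recomputed flags and any contradiction is a hard error naming the
#' offending rows.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's names, e.g. `c(observer_id = "subject", duration_ms =
#'   "soa")`.
#' @param n_locations,n_letters Numbers of alternatives for index validation.
#' @param canonical_durations_ms Durations (ms) to snap to;
#'   [CANONICAL_DURATIONS_MS] by default. `NULL` disables snapping.
#'
#' @return A validated trial tibble with recomputed `loc_correct` and
#'   `id_correct`.
#' @export
read_trials <- function(path, column_map = NULL,
                        n_locations = 12L, n_letters = 12L,
                        canonical_durations_ms = CANONICAL_DURATIONS_MS) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    stopifnot(is.character(column_map), !is.null(names(column_map)))
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src))
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    names(raw)[match(unname(column_map), names(raw))] <- names(column_map)
  }
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("Missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  trials <- tibble::as_tibble(raw)
  trials$observer_id <- as.character(trials$observer_id)
  for (col in c("experiment", "session", "target_location", "target_letter",
                "reported_location", "reported_letter"))
    trials[[col]] <- as.integer(trials[[col]])

  if (!is.null(canonical_durations_ms)) {
    idx <- vapply(trials$duration_ms,
                  function(d) which.min(abs(canonical_durations_ms - d)),
                  integer(1))
    near <- abs(canonical_durations_ms[idx] - trials$duration_ms) <= 0.5
    trials$duration_ms[near] <- canonical_durations_ms[idx][near]
  }

  bad_order <- !trials$report_order %in% c("location_first", "identity_first",
                                           "not_applicable")
  if (any(bad_order))
    stop("Invalid report_order in row(s): ",
         paste(utils::head(which(bad_order), 10), collapse = ", "), call. = FALSE)

  check_idx <- function(col, n) {
    v <- trials[[col]]
    bad <- !is.na(v) & (v < 0L | v >= n)
    if (any(bad))
      stop(sprintf("%s out of range [0, %d) in row(s): %s", col, n,
                   paste(utils::head(which(bad), 10), collapse = ", ")),
           call. = FALSE)
  }
  check_idx("target_location", n_locations); check_idx("reported_location", n_locations)
  check_idx("target_letter", n_letters); check_idx("reported_letter", n_letters)

  loc_correct <- trials$reported_location == trials$target_location
  id_correct <- trials$reported_letter == trials$target_letter
  for (flag in c("loc_correct", "id_correct")) {
    given <- raw[[flag]]
    recomputed <- if (flag == "loc_correct") loc_correct else id_correct
    if (!is.null(given)) {
      given <- as.logical(as.integer(given))
      clash <- which(!is.na(given) & !is.na(recomputed) & given != recomputed)
      if (length(clash))
        stop(sprintf("Stored %s contradicts target/report indices in row(s): %s",
                     flag, paste(utils::head(clash, 10), collapse = ", ")),
             call. = FALSE)
    }
  }
  trials$loc_correct <- loc_correct
  trials$id_correct <- id_correct
  trials
}
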