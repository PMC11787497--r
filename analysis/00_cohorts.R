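# Shared cohort definitions for the analysis drivers. Sourced, not run.
#
# Nine simulated observers per experiment, with a built-in location
# advantage: location thresholds 10-25 ms vs identity 25-40 ms, location
# speeds 25-40 /s vs identity 10-25 /s, independent encoding (rho = 0).
# Trial counts mirror the two masked-report designs: dual report = 4
# sessions x 11 durations x 2 orders x 25 trials; blocked report = 2
# sessions per feature x 11 durations x 50 trials.

library(tvadual)

COHORT_SEED <- 2024L

study_observers <- function(rho = 0, seed = COHORT_SEED) {
  generate_observers(9,
                     t0_range_ms = c(10, 25), v_range_per_s = c(25, 40),
                     t0_range_ms_identity = c(25, 40),
                     v_range_per_s_identity = c(10, 25),
                     rho = rho, seed = seed)
}

dual_report_trials <- function(observers, seed = COHORT_SEED + 1L) {
  simulate_experiment(observers,
                      design_spec(trials_per_cell = 25, mode = "dual_report",
                                  n_sessions = 4, seed = seed))
}

blocked_trials <- function(observers, seed = COHORT_SEED + 2L) {
  dplyr::bind_rows(
    simulate_experiment(observers,
                        design_spec(trials_per_cell = 50,
                                    mode = "blocked_location",
                                    n_sessions = 2, seed = seed)),
    simulate_experiment(observers,
                        design_spec(trials_per_cell = 50,
                                    mode = "blocked_identity",
                                    n_sessions = 2, seed = seed + 1L)))
}
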