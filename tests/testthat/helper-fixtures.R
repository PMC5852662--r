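# Shared fixtures: small simulated cohorts and reduced analysis settings.
# Problem sizes are scaled down from the full study conditions (250-triplet
# sequences, 4 blocks, 100 decoding repeats) so the whole suite stays fast;
# the statistical structure is unchanged.

small_config <- function(..., seed = 1) {
  defaults <- list(n_participants = 6, n_blocks = 2, n_triplets = 100,
                   min_cell = 10, repeats = 3, n_perm = 100, seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

simulate_small_cohort <- function(cfg, conditions = NULL) {
  seeds <- cohort_seeds(cfg$seed, cfg$n_participants)
  lapply(seq_len(cfg$n_participants), function(i) {
    set.seed(seeds[i])
    part <- simulate_participant(cfg, i, conditions = conditions)
    list(part = part,
         epochs = participant_epochs(part, cfg),
         reports = report_percentages(part))
  })
}

# a deterministic alternating report stream
fixed_reports <- function(times, percepts, duration = 30,
                          condition = "neutral", delta_f = 6) {
  structure(list(
    presses = data.frame(time = times, percept = percepts,
                         stringsAsFactors = FALSE),
    condition = condition, delta_f = delta_f, sequence_duration = duration
  ), class = "report_stream")
}
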