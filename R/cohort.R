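#' Full pipeline configuration
#'
#' Collects every tunable of the simulation and analysis chain. Defaults
#' reproduce the study conditions: 23 analyzed participants, 4 blocks of 5
#' sequences (two neutral, never consecutive, plus attempt integration,
#' attend high, attend low), delta-f alternating between 4 and 6 semitones,
#' 250-triplet sequences, 1.5 s press guard, 55-epoch minimum cell count,
#' 1000 permutations at alpha 0.05, 5-fold x 100-repeat decoding with
#' C = 1, and the 216-288 ms percept window.
#'
#' @param n_participants Cohort size.
#' @param n_blocks Blocks per participant.
#' @param n_triplets Triplets per sequence.
#' @param h_freq High-tone frequency (Hz).
#' @param delta_fs The two frequency separations (semitones).
#' @param percept A [percept_params()].
#' @param neural A [neural_params()].
#' @param guard Press guard (s).
#' @param min_cell Minimum epochs per neutral delta-f x percept cell.
#' @param window_ms Percept window (ms post triplet onset).
#' @param n_perm,alpha Cluster-permutation settings.
#' @param folds,repeats,cost Decoder settings.
#' @param lowpass,lowpass_transition,highpass,highpass_transition,resample
#'   Preprocessing settings (Hz).
#' @param report_bias Biased-reporter switch. `FALSE` (default): reports are
#'   accurate by construction. `TRUE` or a positive number: in non-neutral
#'   conditions the button presses follow the intention multipliers while
#'   the percept driving the neural signal keeps its neutral dynamics, so
#'   reports are shifted with no corresponding neural change. A numeric
#'   value is an exponent applied to the intention multipliers of the
#'   reported stream (`2` gives a reporter claiming near-complete
#'   compliance); `TRUE` is equivalent to `1`.
#' @param seed Master seed; all randomness derives from it.
#' @return List of class `pipeline_config`.
#' @export
cohort_config <- function(n_participants = 23, n_blocks = 4,
                          n_triplets = 250, h_freq = 1017,
                          delta_fs = c(4, 6),
                          percept = percept_params(),
                          neural = neural_params(),
                          guard = 1.5, min_cell = 55,
                          window_ms = c(216, 288),
                          n_perm = 1000, alpha = 0.05,
                          folds = 5, repeats = 100, cost = 1,
                          lowpass = 30, lowpass_transition = 6.667,
                          highpass = 0.278, highpass_transition = 0.556,
                          resample = 250,
                          report_bias = FALSE, seed = 1) {
  if (n_participants < 1) stop("need at least one participant", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Sequence schedule for one participant
#'
#' Each block holds five sequences: two neutral (never consecutive), one
#' attempt integration, one attend high, one attend low. The within-block
#' instruction order is drawn once per participant, used for the first two
#' blocks and reversed for the remaining blocks; delta-f alternates from
#' sequence to sequence throughout the session, with the starting delta-f
#' alternating across participants. This guarantees every instruction
#' condition occurs at both delta-fs.
#'
#' @param config A [cohort_config()].
#' @param participant Participant index (1-based).
#' @return Data.frame with `block`, `seq_in_block`, `condition`, `delta_f`.
#' @export
participant_schedule <- function(config, participant) {
  conds <- c("neutral", "neutral", "attempt_integration",
             "attend_high", "attend_low")
  repeat {
    o <- sample(conds)
    pos <- which(o == "neutral")
    if (diff(pos) > 1L) break
  }
  orders <- lapply(seq_len(config$n_blocks), function(b) {
    if (b <= 2) o else rev(o)
  })
  condition <- unlist(orders)
  n_seq <- length(condition)
  start <- config$delta_fs[(participant - 1L) %% 2L + 1L]
  other <- setdiff(config$delta_fs, start)
  delta_f <- rep(c(start, other), length.out = n_seq)
  data.frame(block = rep(seq_len(config$n_blocks), each = 5L),
             seq_in_block = rep(seq_len(5L), config$n_blocks),
             condition = condition, delta_f = delta_f,
             stringsAsFactors = FALSE)
}

#' Simulate one participant's session
#'
#' Draws the participant's percept bias and neural response template, then
#' simulates every scheduled sequence: stimulus timeline, percept phases
#' and reports, and (optionally) the continuous source waveform. With
#' `report_bias` set in the config, non-neutral sequences carry two phase
#' streams: neutral-dynamics phases drive the neural signal while the
#' reported presses follow the instructed multipliers.
#'
#' @param config A [cohort_config()].
#' @param participant Participant index.
#' @param synthesize If FALSE, skip waveform synthesis (behavioral-only
#'   runs are much faster).
#' @param conditions Conditions for which waveforms are synthesized
#'   (default all); restricting to `"neutral"` speeds up runs that only
#'   need the neutral analyses.
#' @return List with `participant`, `template`, `seg_bias`, `schedule`, and
#'   `sequences`: a list of per-sequence lists (`timeline`, `phases`,
#'   `reports`, `recording` or NULL).
#' @export
simulate_participant <- function(config, participant, synthesize = TRUE,
                                 conditions = NULL) {
  sched <- participant_schedule(config, participant)
  seg_bias <- stats::rnorm(1, 0, config$percept$between_participant_sd)
  pp <- config$percept
  pp$seg_bias <- seg_bias
  template <- participant_template(config$neural)
  sequences <- vector("list", nrow(sched))
  for (s in seq_len(nrow(sched))) {
    cond <- sched$condition[s]
    df <- sched$delta_f[s]
    tl <- build_stimulus_timeline(config$n_triplets, config$h_freq, df,
                                  sequence_id = sprintf("p%02d_s%02d",
                                                        participant, s))
    duration <- tl$duration
    bias <- as.numeric(config$report_bias)
    if (bias > 0 && cond != "neutral") {
      true_sim <- simulate_phase_sequence(pp, "neutral", df, duration)
      pp_bias <- pp
      pp_bias$intention_multipliers <- lapply(pp$intention_multipliers,
                                              function(m) m^bias)
      rep_sim <- simulate_phase_sequence(pp_bias, cond, df, duration)
      phases <- true_sim$phases
      attr(phases, "condition") <- cond
      reports <- rep_sim$reports
      reports$condition <- cond
    } else {
      sim <- simulate_phase_sequence(pp, cond, df, duration)
      phases <- sim$phases
      reports <- sim$reports
    }
    rec <- if (synthesize && (is.null(conditions) || cond %in% conditions)) {
      synthesize_recording(tl, phases, config$neural, template)
    }
    sequences[[s]] <- list(timeline = tl, phases = phases, reports = reports,
                           recording = rec, condition = cond, delta_f = df)
  }
  list(participant = participant, template = template, seg_bias = seg_bias,
       schedule = sched, sequences = sequences)
}

#' Preprocess and epoch a simulated participant
#'
#' @param part Result of [simulate_participant()] (with recordings).
#' @param config The same [cohort_config()].
#' @return An `epoch_set` combining all sequences, with condition, delta-f
#'   and percept labels per retained epoch.
#' @export
participant_epochs <- function(part, config) {
  seqs <- Filter(function(sq) !is.null(sq$recording), part$sequences)
  sets <- lapply(seqs, function(sq) {
    epoch_sequence(sq$recording, sq$timeline, sq$reports,
                   guard = config$guard,
                   lowpass = config$lowpass,
                   lowpass_transition = config$lowpass_transition,
                   highpass = config$highpass,
                   highpass_transition = config$highpass_transition,
                   resample = config$resample)
  })
  bind_epochs(sets)
}

#' Seed stream for a cohort
#'
#' @param seed Master seed.
#' @param n Number of per-participant seeds.
#' @return Integer vector of sub-seeds (each below 2^31).
#' @export
cohort_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Write a simulated cohort to disk
#'
#' Per participant, writes one events table (tones and presses, TSV) and
#' one float32 recording with JSON sidecar per sequence, under
#' `out_dir/participant_XX/`. Refuses to touch an existing non-empty
#' directory unless `overwrite` is set. Byte-identical output for identical
#' `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, the vector of participant directories.
#' @export
generate_cohort <- function(config, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty; use overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- cohort_seeds(config$seed, config$n_participants)
  dirs <- character(config$n_participants)
  for (i in seq_len(config$n_participants)) {
    set.seed(seeds[i])
    part <- simulate_participant(config, i)
    pdir <- file.path(out_dir, sprintf("participant_%02d", i))
    dir.create(pdir, showWarnings = FALSE)
    for (s in seq_along(part$sequences)) {
      sq <- part$sequences[[s]]
      ev <- events_from_sequence(sq$timeline, sq$reports)
      write_events(ev, file.path(pdir, sprintf("seq_%02d_events.tsv", s)))
      write_recording(sq$recording,
                      file.path(pdir, sprintf("seq_%02d", s)),
                      seed = seeds[i])
    }
    utils::write.table(part$schedule,
                       file.path(pdir, "schedule.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    dirs[i] <- pdir
  }
  invisible(dirs)
}
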