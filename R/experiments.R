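#' Null calibration experiments
#'
#' These drivers measure the statistical calibration of the analysis chain
#' on synthetic data generated with the percept effect switched off, so
#' that percept labels are assigned independently of the neural signal.
#'
#' `null_cluster_fpr()` simulates cohorts in which both percept conditions
#' have identical signal distributions, runs the cluster-based permutation
#' test on the percept-conditional evoked means of each cohort, and returns
#' the fraction of cohorts whose cluster p falls below `alpha` - the
#' empirical family-wise false-positive rate, which should match the
#' nominal level.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n_participants Participants per cohort.
#' @param n_perm Permutations per cluster test.
#' @param alpha Nominal significance level.
#' @param n_triplets Triplets per simulated sequence.
#' @param n_sequences Neutral sequences per participant.
#' @param config Base [cohort_config()] whose percept/neural parameters are
#'   used (the segregation effect amplitude is forced to zero).
#' @param seed Master seed.
#' @return List with `fpr`, `p_values`, `n_cohorts`.
#' @export
null_cluster_fpr <- function(n_cohorts = 200, n_participants = 12,
                             n_perm = 100, alpha = 0.05, n_triplets = 100,
                             n_sequences = 1, config = cohort_config(),
                             seed = 1) {
  np <- config$neural
  np$segregation_effect_amplitude <- 0
  set.seed(seed)
  cohort_seeds_ <- sample.int(.Machine$integer.max - 1L, n_cohorts)
  p_values <- numeric(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    set.seed(cohort_seeds_[k])
    seg <- int <- NULL
    for (i in seq_len(n_participants)) {
      em <- simulate_null_participant_means(config, np, n_triplets,
                                            n_sequences)
      seg <- rbind(seg, em$segregated)
      int <- rbind(int, em$integrated)
    }
    p_values[k] <- cluster_permutation_test(seg, int, n_perm = n_perm,
                                            alpha = alpha)$p
  }
  list(fpr = mean(p_values <= alpha), p_values = p_values,
       n_cohorts = n_cohorts)
}

# one participant's percept-conditional means under the null; a participant
# whose short sequence yields no retained epochs of one percept is redrawn
# (label-signal independence makes the redraw immaterial under the null)
simulate_null_participant_means <- function(config, np, n_triplets,
                                            n_sequences) {
  template <- participant_template(np)
  for (attempt in 1:50) {
    pp <- config$percept
    pp$seg_bias <- stats::rnorm(1, 0, pp$between_participant_sd)
    sets <- lapply(seq_len(n_sequences), function(s) {
      df <- config$delta_fs[(s - 1L) %% length(config$delta_fs) + 1L]
      tl <- build_stimulus_timeline(n_triplets, config$h_freq, df)
      sim <- simulate_phase_sequence(pp, "neutral", df, tl$duration)
      rec <- synthesize_recording(tl, sim$phases, np, template)
      epoch_sequence(rec, tl, sim$reports, guard = config$guard,
                     lowpass = config$lowpass,
                     lowpass_transition = config$lowpass_transition,
                     highpass = config$highpass,
                     highpass_transition = config$highpass_transition,
                     resample = config$resample)
    })
    ep <- bind_epochs(sets)
    if (all(table(factor(ep$labels,
                         c("integrated", "segregated"))) >= 2)) {
      # collapse over delta-f within percept (equal weight across the
      # sequences' delta-fs is immaterial under the null)
      return(list(
        integrated = colMeans(ep$data[ep$labels == "integrated", ,
                                      drop = FALSE]),
        segregated = colMeans(ep$data[ep$labels == "segregated", ,
                                      drop = FALSE])))
    }
  }
  stop("could not obtain both percept classes in 50 attempts", call. = FALSE)
}

#' @rdname null_cluster_fpr
#'
#' @description `null_decoder_accuracy()` trains the balanced subsampled
#' linear-SVM decoder on synthetic neutral epochs whose labels carry no
#' signal (zero percept-effect amplitude, optionally with labels shuffled
#' on top) and returns per-participant and mean cross-validated accuracies,
#' which should sit at the 50% chance level.
#'
#' @param folds,repeats,cost Decoder settings (see [train_decoders()]).
#' @param shuffle Also randomly permute the percept labels before training.
#' @param n_blocks Blocks of neutral sequences to simulate per participant
#'   (2 neutral sequences each).
#' @return For `null_decoder_accuracy()`: list with `mean_accuracy`,
#'   `accuracy` (per participant), `n_participants`.
#' @export
null_decoder_accuracy <- function(n_participants = 20, folds = 5,
                                  repeats = 100, cost = 1, n_triplets = 100,
                                  n_blocks = 2, shuffle = FALSE,
                                  config = cohort_config(), seed = 1) {
  np <- config$neural
  np$segregation_effect_amplitude <- 0
  cfg <- config
  cfg$neural <- np
  cfg$n_triplets <- n_triplets
  cfg$n_blocks <- n_blocks
  seeds <- cohort_seeds(seed, 20L * n_participants)
  acc <- numeric(n_participants)
  k <- 0L
  for (i in seq_len(n_participants)) {
    # redraw a participant whose short session leaves a percept class too
    # small to cross-validate (immaterial under the null)
    repeat {
      k <- k + 1L
      set.seed(seeds[k])
      part <- simulate_participant(cfg, i, conditions = "neutral")
      ep <- participant_epochs(part, cfg)
      ok <- all(vapply(sort(unique(ep$delta_f)), function(d) {
        tab <- table(factor(ep$labels[ep$delta_f == d],
                            c("integrated", "segregated")))
        min(tab) >= folds
      }, logical(1)))
      if (ok) break
    }
    per_df <- vapply(sort(unique(ep$delta_f)), function(d) {
      sel <- ep$delta_f == d
      labels <- ep$labels[sel]
      if (shuffle) labels <- sample(labels)
      train_decoders(ep$data[sel, , drop = FALSE], labels,
                     folds = folds, repeats = repeats,
                     cost = cost)$cv_accuracy
    }, numeric(1))
    acc[i] <- mean(per_df)
  }
  list(mean_accuracy = mean(acc), accuracy = acc,
       n_participants = n_participants)
}

#' Repeated calibrated-cohort cluster detection
#'
#' Simulates calibrated cohorts (default neural parameters, nonzero percept
#' effect), runs the percept cluster test on each, and reports how often a
#' significant positive cluster overlapping the expected latency window is
#' found, together with the window effect sizes.
#'
#' @param n_runs Number of cohort simulations.
#' @param n_participants Cohort size before the minimum-cell gate.
#' @param n_blocks,n_triplets Problem size per participant.
#' @param n_perm,alpha Cluster-test settings.
#' @param min_cell Minimum epochs per neutral delta-f x percept cell.
#' @param config Base configuration.
#' @param seed Master seed.
#' @return Data.frame, one row per run: `n_gated`, `cluster_p`,
#'   `sig_overlap` (significant positive cluster overlapping the window),
#'   `d_z`, `d_av`, `window_t`.
#' @export
calibrated_cluster_runs <- function(n_runs = 25, n_participants = 23,
                                    n_blocks = 2, n_triplets = 250,
                                    n_perm = 200, alpha = 0.05,
                                    min_cell = 10,
                                    config = cohort_config(), seed = 1) {
  cfg <- config
  cfg$n_blocks <- n_blocks
  cfg$n_triplets <- n_triplets
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  win <- cfg$window_ms
  fs <- cfg$resample
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    pseeds <- sample.int(.Machine$integer.max - 1L, n_participants)
    seg <- int <- NULL
    for (i in seq_len(n_participants)) {
      set.seed(pseeds[i])
      part <- simulate_participant(cfg, i, conditions = "neutral")
      ep <- participant_epochs(part, cfg)
      if (!min_cell_count_gate(ep$labels, ep$delta_f, min_cell)$included) next
      em <- percept_evoked_means(ep)
      seg <- rbind(seg, em$percept_means$segregated)
      int <- rbind(int, em$percept_means$integrated)
    }
    cl <- cluster_permutation_test(seg, int, n_perm = n_perm, alpha = alpha)
    lat <- (seq_len(ncol(seg)) - 1) / fs * 1000
    sig_overlap <- FALSE
    if (nrow(cl$clusters) > 0) {
      pos <- cl$clusters[cl$clusters$sign > 0 & cl$clusters$p <= alpha, ,
                         drop = FALSE]
      sig_overlap <- any(lat[pos$end] >= win[1] & lat[pos$start] <= win[2])
    }
    we <- window_effect(seg, int, win, fs)
    out[[r]] <- data.frame(n_gated = nrow(seg), cluster_p = cl$p,
                           sig_overlap = sig_overlap, d_z = we$test$d,
                           d_av = we$test$d_av, window_t = we$test$t)
  }
  do.call(rbind, out)
}

#' Self-consistency of the response-bias tests
#'
#' Simulates full cohorts (all instruction conditions), with reports either
#' accurate by construction or deliberately biased (reports shifted toward
#' the instructed percept while the neural signal keeps neutral dynamics),
#' and runs both expected-vs-observed comparisons.
#'
#' @param n_runs Cohort simulations per mode.
#' @param n_participants,n_blocks,n_triplets,min_cell,repeats Problem size.
#' @param report_bias Passed to [cohort_config()] (`FALSE` for the accurate
#'   reporter; a positive exponent for the biased one).
#' @param config Base configuration.
#' @param seed Master seed.
#' @return Data.frame, one row per run: `uni_p`, `dec_p` (bias-test
#'   p-values), `uni_c1_t`, `dec_c1_t` (intention-contrast t statistics),
#'   `n_gated`, `mean_accuracy`.
#' @export
bias_consistency_runs <- function(n_runs = 25, n_participants = 12,
                                  n_blocks = 2, n_triplets = 200,
                                  min_cell = 20, repeats = 2,
                                  report_bias = FALSE,
                                  config = cohort_config(), seed = 1) {
  cfg <- config
  cfg$n_participants <- n_participants
  cfg$n_blocks <- n_blocks
  cfg$n_triplets <- n_triplets
  cfg$min_cell <- min_cell
  cfg$repeats <- repeats
  cfg$report_bias <- report_bias
  cfg$n_perm <- min(cfg$n_perm, 100)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg$seed <- run_seeds[r]
    seeds <- cohort_seeds(cfg$seed, cfg$n_participants)
    cohort <- vector("list", cfg$n_participants)
    for (i in seq_len(cfg$n_participants)) {
      set.seed(seeds[i])
      part <- simulate_participant(cfg, i)
      cohort[[i]] <- list(epochs = participant_epochs(part, cfg),
                          reports = report_percentages(part))
    }
    uni <- analyze_univariate(cohort, cfg)
    dec <- analyze_decoding(cohort, cfg)
    out[[r]] <- data.frame(
      uni_p = uni$bias_test$test$p, dec_p = dec$bias_test$test$p,
      uni_c1_t = uni$contrasts$c1$test$t, dec_c1_t = dec$contrasts$c1$test$t,
      n_gated = length(uni$included),
      mean_accuracy = mean(dec$acc_by_participant$cv_accuracy))
  }
  do.call(rbind, out)
}
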