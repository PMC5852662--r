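#' Per-sequence behavioral summary for a simulated participant
#'
#' @param part Result of [simulate_participant()].
#' @return Data.frame with one row per sequence: condition, delta_f,
#'   qualifies (inclusion criteria), pct_seg, and geometric-mean-ready
#'   phase durations in list-columns `dur_initial`, `dur_subint`,
#'   `dur_seg` (completed phases only).
#' @export
participant_behavior <- function(part) {
  rows <- lapply(seq_along(part$sequences), function(s) {
    sq <- part$sequences[[s]]
    ph <- segment_phases(sq$reports)
    comp <- ph[ph$completed, , drop = FALSE]
    data.frame(
      participant = part$participant, sequence = s,
      condition = sq$condition, delta_f = sq$delta_f,
      qualifies = sequence_meets_criteria(ph),
      pct_seg = percent_segregation(sq$reports),
      dur_initial = I(list(comp$duration[comp$class == "initial_integrated"])),
      dur_subint = I(list(comp$duration[comp$class == "subsequent_integrated"])),
      dur_seg = I(list(comp$duration[comp$class == "segregated"])),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Behavioral analysis over a cohort
#'
#' Pools sequences at the sequence level within each participant x delta-f
#' x condition cell (qualifying sequences only), computes cell means on the
#' transformed scales (logit for percentage segregation, log for phase
#' durations), excludes participants with any empty cell, and runs the
#' standard tests: delta-f x task repeated-measures ANOVAs with Huynh-Feldt
#' correction on each measure, and per-task paired t tests of phase
#' durations against the neutral condition.
#'
#' @param behavior Row-bound [participant_behavior()] tables.
#' @param ci_boot Bootstrap resamples for eta-squared CIs.
#' @return List with `cells` (participant x delta_f x condition means),
#'   `excluded` (participant ids), `anova` (per measure), `task_tests`
#'   (per task x phase class vs neutral), `pct_seg_contrasts`.
#' @export
analyze_behavior <- function(behavior, ci_boot = 0) {
  b <- behavior[behavior$qualifies, , drop = FALSE]
  cell_rows <- list()
  for (p in unique(behavior$participant)) {
    for (d in unique(behavior$delta_f)) {
      for (cond in unique(behavior$condition)) {
        sel <- b$participant == p & b$delta_f == d & b$condition == cond
        if (!any(sel)) {
          cell_rows[[length(cell_rows) + 1L]] <- data.frame(
            participant = p, delta_f = d, condition = cond,
            pct_seg = NA_real_, dur_initial = NA_real_,
            dur_subint = NA_real_, dur_seg = NA_real_)
          next
        }
        gm <- function(col) {
          v <- unlist(b[[col]][sel])
          if (length(v) == 0) NA_real_ else transformed_condition_means(v, "log")
        }
        cell_rows[[length(cell_rows) + 1L]] <- data.frame(
          participant = p, delta_f = d, condition = cond,
          pct_seg = transformed_condition_means(b$pct_seg[sel], "logit"),
          dur_initial = gm("dur_initial"),
          dur_subint = gm("dur_subint"),
          dur_seg = gm("dur_seg"))
      }
    }
  }
  cells <- do.call(rbind, cell_rows)
  incomplete <- unique(cells$participant[!stats::complete.cases(cells)])
  cells_ok <- cells[!(cells$participant %in% incomplete), , drop = FALSE]
  if (length(unique(cells_ok$participant)) < 3) {
    stop("too few participants with complete behavioral cells", call. = FALSE)
  }

  measures <- c("pct_seg", "dur_initial", "dur_subint", "dur_seg")
  transforms <- c(pct_seg = "logit", dur_initial = "log",
                  dur_subint = "log", dur_seg = "log")
  tx <- function(v, tr) if (tr == "logit") stats::qlogis(v / 100) else log(v)
  anovas <- lapply(measures, function(m) {
    d <- cells_ok
    d$y <- tx(d[[m]], transforms[[m]])
    d$delta_f <- factor(d$delta_f)
    d$condition <- factor(d$condition)
    list(delta_f = rm_anova_hf(d, "y", "participant",
                               c("delta_f", "condition"), effect = "delta_f",
                               ci_boot = ci_boot),
         condition = rm_anova_hf(d, "y", "participant",
                                 c("delta_f", "condition"),
                                 effect = "condition", ci_boot = ci_boot))
  })
  names(anovas) <- measures

  # per-task phase-duration comparisons against neutral (log scale,
  # delta-f equally weighted)
  per_cell <- function(m) {
    d <- cells_ok
    d$y <- tx(d[[m]], transforms[[m]])
    agg <- stats::aggregate(y ~ participant + condition, d, mean)
    stats::reshape(agg, idvar = "participant", timevar = "condition",
                   direction = "wide")
  }
  tasks <- c("attempt_integration", "attend_high", "attend_low")
  task_tests <- list()
  for (m in c("dur_initial", "dur_subint", "dur_seg")) {
    wide <- per_cell(m)
    for (task in tasks) {
      task_tests[[paste(task, m, sep = ".")]] <-
        paired_t_with_d(wide[[paste0("y.", task)]], wide$y.neutral)
    }
  }

  # intention contrasts on logit percentage segregation
  wide <- per_cell("pct_seg")
  seg_mean <- (wide$y.attend_high + wide$y.attend_low) / 2
  pct_seg_contrasts <- list(
    seg_vs_int = paired_t_with_d(seg_mean, wide$y.attempt_integration),
    toward_seg_vs_toward_int = paired_t_with_d(
      seg_mean - wide$y.neutral, wide$y.neutral - wide$y.attempt_integration),
    high_vs_low = paired_t_with_d(wide$y.attend_high, wide$y.attend_low)
  )

  list(cells = cells, excluded = incomplete, anova = anovas,
       task_tests = task_tests, pct_seg_contrasts = pct_seg_contrasts)
}

#' Reported percentage of segregation per condition cell
#'
#' Raw (untransformed) proportions, suitable for weighting neural means in
#' the expected-vs-observed analyses.
#'
#' @param part Result of [simulate_participant()].
#' @return Data.frame: participant, delta_f, condition, `p_seg` (0-1) and
#'   `pct_seg` (0-100).
#' @export
report_percentages <- function(part) {
  rows <- lapply(part$sequences, function(sq) {
    data.frame(participant = part$participant, delta_f = sq$delta_f,
               condition = sq$condition,
               pct = percent_segregation(sq$reports),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(pct ~ participant + delta_f + condition, d, mean)
  agg$p_seg <- agg$pct / 100
  agg$pct_seg <- agg$pct
  agg$pct <- NULL
  agg
}

#' Percentage of retained epochs whose report label is segregated
#'
#' The reported-percept composition of the epoched data, per delta-f and
#' condition. This is the weighting used by the expected-vs-observed bias
#' tests: because it is measured on exactly the epochs that enter the
#' observed neural means, the "accurate reporter" hypothesis predicts equal
#' expected and observed values with no sampling mismatch (behavioral
#' percentages, in contrast, also count perceptual phases too short to
#' contribute any retained epoch).
#'
#' @param epochs An `epoch_set` of retained, labeled epochs.
#' @param participant Participant id to attach.
#' @return Data.frame: `participant`, `delta_f`, `condition`, `p_seg`
#'   (0-1), `pct_seg` (0-100).
#' @export
epoch_label_percentages <- function(epochs, participant) {
  d <- data.frame(delta_f = epochs$delta_f, condition = epochs$condition,
                  seg = epochs$labels == "segregated")
  agg <- stats::aggregate(seg ~ delta_f + condition, d, mean)
  data.frame(participant = participant, delta_f = agg$delta_f,
             condition = agg$condition, p_seg = agg$seg,
             pct_seg = 100 * agg$seg)
}

#' Univariate neural analysis over a cohort
#'
#' Applies the minimum-cell gate, computes percept-conditional neutral
#' evoked means per participant (delta-f equally weighted), runs the
#' cluster-based permutation test on segregated vs. integrated means, the
#' window-specific paired test, the four instruction-task contrasts on
#' window means, and the report-weighted expected-vs-observed bias test.
#'
#' @param cohort List of per-participant lists, each with `epochs` (an
#'   `epoch_set`) and `reports` (a [report_percentages()] data.frame).
#' @param config A [cohort_config()].
#' @param bias_weights Percentages used to weight the neutral percept means
#'   in the bias test: `"epoch_labels"` (default, see
#'   [epoch_label_percentages()]) or `"behavioral"`.
#' @return List with `included`, `cluster`, `window` (window_effect),
#'   `contrasts`, `bias_test`, and the per-participant matrices.
#' @export
analyze_univariate <- function(cohort, config,
                               bias_weights = c("epoch_labels", "behavioral")) {
  bias_weights <- match.arg(bias_weights)
  gated <- Filter(function(pt) {
    neu <- pt$epochs$condition == "neutral"
    min_cell_count_gate(pt$epochs$labels[neu], pt$epochs$delta_f[neu],
                        config$min_cell)$included
  }, cohort)
  if (length(gated) < 2) stop("fewer than two participants pass the gate",
                              call. = FALSE)
  fs <- config$resample
  win <- config$window_ms

  seg <- int <- NULL
  nwm_rows <- list(); obs_rows <- list(); rep_rows <- list()
  for (pt in gated) {
    ep <- pt$epochs
    neu <- ep$condition == "neutral"
    em <- percept_evoked_means(subset_epochs(ep, neu))
    seg <- rbind(seg, em$percept_means$segregated)
    int <- rbind(int, em$percept_means$integrated)
    pid <- pt$reports$participant[1]
    for (d in sort(unique(ep$delta_f))) for (pc in c("integrated", "segregated")) {
      nwm_rows[[length(nwm_rows) + 1L]] <- data.frame(
        participant = pid, delta_f = d, percept = pc,
        value = window_mean(em$cell_means[[paste(d, pc, sep = ".")]], win, fs))
    }
    for (cond in c("attempt_integration", "attend_high", "attend_low")) {
      for (d in sort(unique(ep$delta_f))) {
        sel <- ep$condition == cond & ep$delta_f == d
        obs_rows[[length(obs_rows) + 1L]] <- data.frame(
          participant = pid, delta_f = d, condition = cond,
          value = window_mean(colMeans(ep$data[sel, , drop = FALSE]), win, fs))
      }
    }
    rep_rows[[length(rep_rows) + 1L]] <- if (bias_weights == "epoch_labels") {
      epoch_label_percentages(ep, pid)
    } else {
      pt$reports
    }
  }
  cluster <- cluster_permutation_test(seg, int, n_perm = config$n_perm,
                                      alpha = config$alpha)
  window <- window_effect(seg, int, win, fs)

  observed <- do.call(rbind, obs_rows)
  # delta-f equally weighted window values per condition
  obs_by_cond <- stats::aggregate(value ~ participant + condition, observed,
                                  mean)
  contrasts <- task_contrasts(obs_by_cond)

  reports <- do.call(rbind, rep_rows)
  bias_test <- expected_nonneutral_response(
    do.call(rbind, nwm_rows),
    reports[reports$condition != "neutral",
            c("participant", "delta_f", "condition", "p_seg")],
    observed)

  list(included = vapply(gated, function(pt) pt$reports$participant[1],
                         numeric(1)),
       seg = seg, int = int, cluster = cluster, window = window,
       contrasts = contrasts, observed_window = observed,
       bias_test = bias_test)
}

#' Multivariate (decoding) analysis over a cohort
#'
#' Per gated participant and delta-f, trains the balanced subsampled
#' linear-SVM ensemble on neutral epochs, computes Haufe-corrected feature
#' weights (normalized per participant, then averaged over delta-f),
#' classifies all non-neutral epochs, and runs the group tests: accuracy
#' vs. chance, the four task contrasts on percentages classified as
#' segregated, and the accuracy-adjusted expected-difference bias test.
#'
#' @param cohort As in [analyze_univariate()].
#' @param config A [cohort_config()].
#' @param bias_weights As in [analyze_univariate()].
#' @return List with `accuracy` (per participant x delta-f), `acc_test`,
#'   `patterns` (group-mean corrected weights), `classified`, `contrasts`,
#'   `bias_test`.
#' @export
analyze_decoding <- function(cohort, config,
                             bias_weights = c("epoch_labels", "behavioral")) {
  bias_weights <- match.arg(bias_weights)
  gated <- Filter(function(pt) {
    neu <- pt$epochs$condition == "neutral"
    min_cell_count_gate(pt$epochs$labels[neu], pt$epochs$delta_f[neu],
                        config$min_cell)$included
  }, cohort)
  if (length(gated) < 2) stop("fewer than two participants pass the gate",
                              call. = FALSE)

  acc_rows <- list(); cls_rows <- list(); rep_rows <- list()
  patterns <- NULL
  for (pt in gated) {
    ep <- pt$epochs
    pid <- pt$reports$participant[1]
    pat_by_df <- NULL
    for (d in sort(unique(ep$delta_f))) {
      neu <- ep$condition == "neutral" & ep$delta_f == d
      x <- ep$data[neu, , drop = FALSE]
      ens <- train_decoders(x, ep$labels[neu], folds = config$folds,
                            repeats = config$repeats, cost = config$cost)
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        participant = pid, delta_f = d, cv_accuracy = ens$cv_accuracy)
      hw <- haufe_correct(ens, x)
      hw <- hw / sqrt(sum(hw^2))          # unit norm per participant/delta-f
      pat_by_df <- rbind(pat_by_df, hw)
      for (cond in c("attempt_integration", "attend_high", "attend_low")) {
        sel <- ep$condition == cond & ep$delta_f == d
        cls_rows[[length(cls_rows) + 1L]] <- data.frame(
          participant = pid, delta_f = d, condition = cond,
          pct_seg = classify_epochs(ens, ep$data[sel, , drop = FALSE]))
      }
    }
    patterns <- rbind(patterns, colMeans(pat_by_df))
    rep_rows[[length(rep_rows) + 1L]] <- if (bias_weights == "epoch_labels") {
      epoch_label_percentages(ep, pid)
    } else {
      pt$reports
    }
  }
  accuracy <- do.call(rbind, acc_rows)
  classified <- do.call(rbind, cls_rows)
  reports <- do.call(rbind, rep_rows)

  acc_by_p <- stats::aggregate(cv_accuracy ~ participant, accuracy, mean)
  acc_test <- paired_t_with_d(acc_by_p$cv_accuracy - 50)

  cls_by_cond <- stats::aggregate(pct_seg ~ participant + condition,
                                  classified, mean)
  names(cls_by_cond)[names(cls_by_cond) == "pct_seg"] <- "value"
  contrasts <- task_contrasts(cls_by_cond)

  bias_test <- adjusted_expected_difference(
    reports[reports$condition != "neutral",
            c("participant", "delta_f", "condition", "pct_seg")],
    accuracy, classified)

  list(accuracy = accuracy, acc_by_participant = acc_by_p,
       acc_test = acc_test, patterns = patterns, classified = classified,
       contrasts = contrasts, bias_test = bias_test)
}

#' Subset an epoch set by a logical mask
#'
#' @param ep An `epoch_set`.
#' @param sel Logical or integer index over retained epochs.
#' @return The reduced `epoch_set`.
#' @export
subset_epochs <- function(ep, sel) {
  ep$data <- ep$data[sel, , drop = FALSE]
  ep$onsets <- ep$onsets[sel]
  ep$delta_f <- ep$delta_f[sel]
  ep$labels <- ep$labels[sel]
  ep$condition <- ep$condition[sel]
  ep
}

#' Run the full simulate-to-report pipeline
#'
#' Simulates the cohort (seeded), preprocesses and epochs every sequence,
#' then runs the behavioral, univariate and decoding analyses and collates
#' a report. Identical `(config)` input yields an identical report.
#'
#' @param config A [cohort_config()].
#' @param out_dir If non-NULL, writes `report.json` and `report.md` there.
#' @param verbose Print stage progress.
#' @return The report list (settings, behavior, univariate, decoding).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stage <- function(...) if (verbose) message(sprintf(...))
  seeds <- cohort_seeds(config$seed, config$n_participants)
  cohort <- vector("list", config$n_participants)
  behavior <- list()
  stage("simulating %d participants", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    set.seed(seeds[i])
    part <- simulate_participant(config, i)
    behavior[[i]] <- participant_behavior(part)
    cohort[[i]] <- list(epochs = participant_epochs(part, config),
                        reports = report_percentages(part))
  }
  stage("behavioral analysis")
  behav <- analyze_behavior(do.call(rbind, behavior))
  stage("univariate analysis")
  set.seed(seeds[1] %% 1000003L + 7L)
  uni <- analyze_univariate(cohort, config)
  stage("decoding analysis")
  set.seed(seeds[1] %% 1000033L + 13L)
  dec <- analyze_decoding(cohort, config)

  report <- list(
    settings = list(seed = config$seed,
                    n_participants = config$n_participants,
                    n_triplets = config$n_triplets,
                    guard_s = config$guard, min_cell = config$min_cell,
                    window_ms = config$window_ms, n_perm = config$n_perm,
                    alpha = config$alpha, folds = config$folds,
                    repeats = config$repeats, cost = config$cost),
    behavior = behav, univariate = uni, decoding = dec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  }
  report
}

#' Flat numeric summary of a pipeline report
#'
#' @param report A [run_pipeline()] report.
#' @return Nested list of plain numbers suitable for JSON.
#' @export
report_summary <- function(report) {
  pt <- function(x) list(t = x$t, df = x$df, p = x$p, d = x$d,
                         d_ci = x$d_ci, d_av = x$d_av,
                         mean_diff = x$mean_diff)
  list(
    settings = report$settings,
    behavior = list(
      pct_seg_delta_f_F = report$behavior$anova$pct_seg$delta_f$F,
      pct_seg_delta_f_p = report$behavior$anova$pct_seg$delta_f$p,
      pct_seg_condition_F = report$behavior$anova$pct_seg$condition$F,
      pct_seg_condition_p = report$behavior$anova$pct_seg$condition$p,
      seg_vs_int = pt(report$behavior$pct_seg_contrasts$seg_vs_int),
      high_vs_low = pt(report$behavior$pct_seg_contrasts$high_vs_low)),
    univariate = list(
      cluster_p = report$univariate$cluster$p,
      cluster_mass = report$univariate$cluster$max_cluster_mass,
      window_test = pt(report$univariate$window$test),
      main_contrast = pt(report$univariate$contrasts$c1$test),
      high_vs_low = pt(report$univariate$contrasts$c4$test),
      bias_test = pt(report$univariate$bias_test$test)),
    decoding = list(
      mean_accuracy = mean(report$decoding$acc_by_participant$cv_accuracy),
      acc_test = pt(report$decoding$acc_test),
      main_contrast = pt(report$decoding$contrasts$c1$test),
      high_vs_low = pt(report$decoding$contrasts$c4$test),
      bias_test = pt(report$decoding$bias_test$test))
  )
}

report_markdown <- function(report) {
  s <- report_summary(report)
  f <- function(x, d = 3) formatC(x, digits = d, format = "g")
  c("# Pipeline report",
    "",
    sprintf("Seed %s, %s participants, %s triplets/sequence.",
            s$settings$seed, s$settings$n_participants,
            s$settings$n_triplets),
    "",
    "## Behavior",
    sprintf("- %% segregation, delta-f effect: F = %s, p = %s",
            f(s$behavior$pct_seg_delta_f_F), f(s$behavior$pct_seg_delta_f_p)),
    sprintf("- %% segregation, task effect: F = %s, p = %s",
            f(s$behavior$pct_seg_condition_F),
            f(s$behavior$pct_seg_condition_p)),
    "",
    "## Univariate",
    sprintf("- cluster p = %s (mass %s)", f(s$univariate$cluster_p),
            f(s$univariate$cluster_mass)),
    sprintf("- window test: t = %s, p = %s, d_av = %s",
            f(s$univariate$window_test$t), f(s$univariate$window_test$p),
            f(s$univariate$window_test$d_av)),
    sprintf("- intention contrast: t = %s, p = %s",
            f(s$univariate$main_contrast$t), f(s$univariate$main_contrast$p)),
    sprintf("- expected-vs-observed: t = %s, p = %s",
            f(s$univariate$bias_test$t), f(s$univariate$bias_test$p)),
    "",
    "## Decoding",
    sprintf("- mean accuracy = %s%%", f(s$decoding$mean_accuracy)),
    sprintf("- intention contrast: t = %s, p = %s",
            f(s$decoding$main_contrast$t), f(s$decoding$main_contrast$p)),
    sprintf("- adjusted expected-difference test: t = %s, p = %s",
            f(s$decoding$bias_test$t), f(s$decoding$bias_test$p)))
}
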