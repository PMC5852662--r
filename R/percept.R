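#' Parameters of the bistable percept-phase process
#'
#' Perceptual phases alternate between integrated and segregated hearing,
#' with a longer initial integrated phase. Phase durations are log-normal
#' (the analysis log-transforms durations, implying approximate
#' log-normality); their log-means depend on phase class and frequency
#' separation, and instruction conditions multiply durations of the
#' intended/unintended percept. A per-participant segregation bias (drawn
#' with SD `between_participant_sd` on the log scale) lengthens segregated
#' and shortens integrated phases, or vice versa.
#'
#' Default log-means encode the qualitative orderings of the behavioral
#' results: larger frequency separation gives shorter integrated and longer
#' segregated phases; intention multipliers are stronger for attempted
#' segregation than attempted integration.
#'
#' @param mu_log Named list per delta-f (`"4"`, `"6"`), each a named numeric
#'   vector with entries `initial_integrated`, `subsequent_integrated`,
#'   `segregated` (log-seconds).
#' @param sigma_log Within-participant log-SD of phase durations.
#' @param intention_multipliers Named list per condition; each a vector with
#'   entries `integrated` and `segregated` multiplying phase durations.
#' @param between_participant_sd Log-scale SD of the participant segregation
#'   bias.
#' @param first_report_latency Time (s) after sequence start at which the
#'   ongoing first percept is reported.
#' @param p_first_integrated Probability that the first phase is integrated.
#' @param seg_bias Participant-level log-scale segregation bias (usually set
#'   by the cohort generator, not by hand).
#' @return A list of class `percept_params`.
#' @export
percept_params <- function(
    mu_log = list(
      "4" = c(initial_integrated = log(15), subsequent_integrated = log(7.5),
              segregated = log(5.4)),
      "6" = c(initial_integrated = log(10), subsequent_integrated = log(5.4),
              segregated = log(7.5))),
    sigma_log = 0.60,
    intention_multipliers = list(
      neutral             = c(integrated = 1,        segregated = 1),
      attempt_integration = c(integrated = 1.35,     segregated = 1 / 1.35),
      attend_high         = c(integrated = 1 / 1.75, segregated = 1.75),
      attend_low          = c(integrated = 1 / 1.75, segregated = 1.75)),
    between_participant_sd = 0.35,
    first_report_latency = 2,
    p_first_integrated = 1,
    seg_bias = 0) {
  stopifnot(sigma_log >= 0, between_participant_sd >= 0)
  if (any(unlist(intention_multipliers) <= 0)) {
    stop("intention multipliers must be positive", call. = FALSE)
  }
  structure(list(mu_log = mu_log, sigma_log = sigma_log,
                 intention_multipliers = intention_multipliers,
                 between_participant_sd = between_participant_sd,
                 first_report_latency = first_report_latency,
                 p_first_integrated = p_first_integrated,
                 seg_bias = seg_bias),
            class = "percept_params")
}

#' Simulate one sequence of perceptual phases and its report stream
#'
#' Draws alternating percept phases until the sequence duration is covered,
#' truncating the last phase (flagged incomplete). A button press is emitted
#' at each phase onset after the first; the percept of the first phase is
#' reported `first_report_latency` seconds after sequence start (omitted if
#' a switch occurs before that latency).
#'
#' @param params A [percept_params()].
#' @param condition One of `"neutral"`, `"attempt_integration"`,
#'   `"attend_high"`, `"attend_low"`.
#' @param delta_f 4 or 6 (semitones).
#' @param duration Sequence duration in seconds.
#' @return A list with `phases` (a `phase_table` data.frame: class, onset,
#'   duration, completed) and `reports` (a `report_stream`).
#' @export
simulate_phase_sequence <- function(params, condition = "neutral",
                                    delta_f = 6, duration = 150) {
  stopifnot(inherits(params, "percept_params"), duration > 0)
  mu <- params$mu_log[[as.character(delta_f)]]
  if (is.null(mu)) stop("no phase-duration parameters for this delta_f",
                        call. = FALSE)
  mult <- params$intention_multipliers[[condition]]
  if (is.null(mult)) stop("unknown condition: ", condition, call. = FALSE)

  first_integrated <- stats::runif(1) < params$p_first_integrated
  classes <- character(0); onsets <- numeric(0); durs <- numeric(0)
  t <- 0
  k <- 0L
  percept_int <- first_integrated
  while (t < duration) {
    k <- k + 1L
    if (percept_int) {
      cls <- if (k == 1L && first_integrated) "initial_integrated"
             else "subsequent_integrated"
      lmu <- mu[[cls]] + log(mult[["integrated"]]) - params$seg_bias
    } else {
      cls <- "segregated"
      lmu <- mu[["segregated"]] + log(mult[["segregated"]]) + params$seg_bias
    }
    d <- exp(stats::rnorm(1, lmu, params$sigma_log))
    classes <- c(classes, cls); onsets <- c(onsets, t); durs <- c(durs, d)
    t <- t + d
    percept_int <- !percept_int
  }
  completed <- rep(TRUE, k)
  completed[k] <- FALSE
  durs[k] <- duration - onsets[k]

  phases <- data.frame(class = classes, onset = onsets, duration = durs,
                       completed = completed, stringsAsFactors = FALSE)
  attr(phases, "condition") <- condition
  attr(phases, "delta_f") <- delta_f
  attr(phases, "duration") <- duration
  class(phases) <- c("phase_table", "data.frame")

  list(phases = phases,
       reports = reports_from_phases(phases, params$first_report_latency))
}

#' Derive the button-press stream implied by a phase table
#'
#' @param phases A `phase_table` (see [simulate_phase_sequence()]).
#' @param first_report_latency Latency (s) of the first report.
#' @return A `report_stream`: list with `presses` (data.frame time, percept),
#'   `condition`, `delta_f`, `sequence_duration`.
#' @export
reports_from_phases <- function(phases, first_report_latency = 2) {
  percept_of <- function(cls) {
    ifelse(cls == "segregated", "segregated", "integrated")
  }
  times <- numeric(0); percepts <- character(0)
  n <- nrow(phases)
  if (n >= 2L) {
    times <- phases$onset[-1L]
    percepts <- percept_of(phases$class[-1L])
  }
  first_t <- phases$onset[1L] + first_report_latency
  if (length(times) == 0L || first_t < times[1L]) {
    times <- c(first_t, times)
    percepts <- c(percept_of(phases$class[1L]), percepts)
  }
  keep <- times <= attr(phases, "duration")
  structure(list(
    presses = data.frame(time = times[keep], percept = percepts[keep],
                         stringsAsFactors = FALSE),
    condition = attr(phases, "condition"),
    delta_f = attr(phases, "delta_f"),
    sequence_duration = attr(phases, "duration")
  ), class = "report_stream")
}

#' @export
print.report_stream <- function(x, ...) {
  cat(sprintf("<report_stream> %d presses, condition %s, delta_f %s, %g s\n",
              nrow(x$presses), x$condition, x$delta_f, x$sequence_duration))
  invisible(x)
}
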