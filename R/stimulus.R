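#' Stimulus timelines for HLH- triplet sequences
#'
#' Builds the temporal skeleton of one streaming sequence: repeating
#' high-low-high tone triplets in which each tone lasts 100 ms, tones within
#' a triplet are separated by 50 ms of silence, and 200 ms of silence
#' separates consecutive triplets, so the triplet period is exactly 600 ms.
#' The low-tone frequency sits `delta_f` semitones below the high tone.
#'
#' @param n_triplets Number of HLH- triplets (>= 1).
#' @param h_freq High-tone frequency in Hz (default 1017 Hz, the value used
#'   for neural recording sessions to avoid line-noise harmonics).
#' @param delta_f Frequency separation in semitones (> 0); the study used 4
#'   and 6 semitones.
#' @param sequence_id Optional identifier carried through to events tables.
#'
#' @return An object of class `stimulus_timeline`: a list with
#'   `n_triplets`, `triplet_onsets` (s), `tone_onsets` (n x 3 matrix, s),
#'   `tone_freqs` (n x 3 matrix, Hz, columns H, L, H), `delta_f`, `h_freq`,
#'   `duration` (s) and `sequence_id`.
#' @export
#' @examples
#' tl <- build_stimulus_timeline(250, 1017, 6)
#' tl$duration            # 150 s
#' tl$tone_freqs[1, 2]    # low tone, ~719.1 Hz
build_stimulus_timeline <- function(n_triplets, h_freq = 1017, delta_f = 6,
                                    sequence_id = "seq") {
  if (!is.numeric(n_triplets) || length(n_triplets) != 1L ||
      n_triplets < 1 || n_triplets != round(n_triplets)) {
    stop("`n_triplets` must be a positive integer", call. = FALSE)
  }
  if (h_freq <= 0) stop("`h_freq` must be positive", call. = FALSE)
  if (delta_f <= 0) stop("`delta_f` must be positive", call. = FALSE)
  n_triplets <- as.integer(n_triplets)

  triplet_period <- 0.600
  tone_offsets <- c(0, 0.150, 0.300)  # tone 100 ms + gap 50 ms within triplet
  triplet_onsets <- (seq_len(n_triplets) - 1L) * triplet_period
  tone_onsets <- outer(triplet_onsets, tone_offsets, "+")
  l_freq <- h_freq * 2^(-delta_f / 12)
  tone_freqs <- matrix(rep(c(h_freq, l_freq, h_freq), each = n_triplets),
                       nrow = n_triplets)
  structure(
    list(
      sequence_id = sequence_id,
      n_triplets = n_triplets,
      triplet_onsets = triplet_onsets,
      tone_onsets = tone_onsets,
      tone_freqs = tone_freqs,
      tone_duration = 0.100,
      delta_f = delta_f,
      h_freq = h_freq,
      duration = n_triplets * triplet_period
    ),
    class = "stimulus_timeline"
  )
}

#' Filler interlude between streaming sequences
#'
#' Returns the event table of the 40 s filler that separated experimental
#' sequences: 5005 ms silence, a 100 ms timing tone, 1900 ms silence, 33
#' random-frequency 100 ms tones with 50 ms gaps (frequencies drawn
#' log-uniformly between 200 and 2000 Hz, to disrupt memory of the previous
#' sequence), 22945 ms silence, a second 100 ms timing tone, and a final
#' 5000 ms silence.
#'
#' @param timing_tone_freq Frequency of the two timing tones in Hz.
#' @param rng_seed Optional integer seed for the random tone frequencies.
#' @return A data.frame with columns `onset` (s), `duration` (s),
#'   `event_type` ("tone"), and `value` (frequency, Hz). Silences are
#'   implicit between events. The total span is returned as attribute
#'   `"duration"`.
#' @export
build_filler_timeline <- function(timing_tone_freq = 250, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tone_dur <- 0.100
  gap <- 0.050
  onsets <- numeric(0)
  freqs <- numeric(0)

  t <- 5.005
  onsets <- c(onsets, t); freqs <- c(freqs, timing_tone_freq)
  t <- t + tone_dur + 1.900
  rand_freqs <- exp(stats::runif(33, log(200), log(2000)))
  for (k in seq_len(33)) {
    onsets <- c(onsets, t); freqs <- c(freqs, rand_freqs[k])
    t <- t + tone_dur + gap
  }
  # last tone is followed by 22945 ms silence, not by the 50 ms gap
  t <- t - gap + 22.945
  onsets <- c(onsets, t); freqs <- c(freqs, timing_tone_freq)
  t <- t + tone_dur + 5.000

  out <- data.frame(
    onset = onsets,
    duration = tone_dur,
    event_type = "tone",
    value = freqs,
    stringsAsFactors = FALSE
  )
  attr(out, "duration") <- t
  out
}
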