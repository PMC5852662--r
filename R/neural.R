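#' Parameters of the synthetic evoked source waveform
#'
#' Each tone in an HLH- triplet evokes a gamma-shaped deflection peaking
#' ~55 ms after tone onset (amplitudes decreasing across the triplet,
#' mimicking adaptation). When the governing percept is segregated, a
#' raised-cosine positivity confined to 216-288 ms after triplet onset
#' (66-138 ms after the L tone) is added. Additive noise is a mixture of
#' 1/f-shaped and white Gaussian noise.
#'
#' Per-participant templates jitter deflection latency and amplitude, scale
#' the segregation effect, and flip its sign in a minority of individuals
#' (modeling listeners whose percept signature opposes the group direction).
#' Overall response amplitude varies much more between participants than the
#' percept effect does, so group effect sizes standardized by condition SDs
#' are small even when the effect is consistent.
#'
#' Default amplitudes and noise are calibrated so that a full-scale cohort
#' shows a neutral decoding accuracy near 53%, a window effect size (d,
#' average-variance convention) near 0.32, and a significant positive
#' cluster over 216-288 ms.
#'
#' @param kernel_peak_latencies Peak latency (ms) of the deflection after
#'   each tone onset.
#' @param kernel_amplitudes Deflection amplitudes (source units) for the
#'   three tones.
#' @param kernel_shape Gamma shape parameter of the deflection.
#' @param segregation_effect_window Window (ms post triplet onset) of the
#'   added positivity.
#' @param segregation_effect_amplitude Peak amplitude of the positivity.
#' @param latency_jitter_sd Between-participant SD of a common latency shift
#'   (ms).
#' @param amplitude_gain_halfwidth_log Half-width of the log-uniform
#'   between-participant overall response gain (gains span roughly
#'   `exp(+/- halfwidth)`), reflecting the wide but bounded spread of
#'   reconstructed source amplitudes across individuals.
#' @param effect_jitter_sd Between-participant SD of the multiplicative
#'   segregation-effect gain (around 1).
#' @param sign_flip_probability Probability that a participant's
#'   segregation effect is sign-reversed.
#' @param noise_spectrum_exponent Exponent of the 1/f^a noise component.
#' @param noise_sd Total noise SD (source units, at the 1000 Hz synthesis
#'   rate).
#' @param noise_white_fraction Fraction of noise variance that is white.
#' @return A list of class `neural_params`.
#' @export
neural_params <- function(kernel_peak_latencies = c(55, 55, 55),
                          kernel_amplitudes = c(1, 0.85, 0.7),
                          kernel_shape = 3,
                          segregation_effect_window = c(216, 288),
                          segregation_effect_amplitude = 0.15,
                          latency_jitter_sd = 5,
                          amplitude_gain_halfwidth_log = 1.3,
                          effect_jitter_sd = 0.25,
                          sign_flip_probability = 0.15,
                          noise_spectrum_exponent = 1,
                          noise_sd = 1.0,
                          noise_white_fraction = 0.5) {
  params <- as.list(environment())
  w <- segregation_effect_window
  if (w[1] < 0 || w[2] >= 600 || w[1] >= w[2]) {
    stop("segregation window must lie within [0, 600) ms", call. = FALSE)
  }
  if (sign_flip_probability < 0 || sign_flip_probability > 1) {
    stop("sign_flip_probability must be in [0, 1]", call. = FALSE)
  }
  structure(params, class = "neural_params")
}

#' Draw a per-participant response template
#'
#' @param neural A [neural_params()].
#' @return List with `latency_shift_ms`, `gain` (overall response gain),
#'   `effect_gain` (segregation-effect gain, possibly negative for
#'   sign-flipped individuals).
#' @export
participant_template <- function(neural) {
  flip <- if (stats::runif(1) < neural$sign_flip_probability) -1 else 1
  list(
    latency_shift_ms = stats::rnorm(1, 0, neural$latency_jitter_sd),
    gain = exp(stats::runif(1, -neural$amplitude_gain_halfwidth_log,
                            neural$amplitude_gain_halfwidth_log)),
    effect_gain = flip * abs(1 + stats::rnorm(1, 0, neural$effect_jitter_sd))
  )
}

# deterministic evoked kernel for one 600 ms triplet, sampled at `fs`
triplet_kernel <- function(neural, template, fs = 1000) {
  n <- round(0.600 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  y <- numeric(n)
  tone_onsets_ms <- c(0, 150, 300)
  shape <- neural$kernel_shape
  for (k in 1:3) {
    peak <- neural$kernel_peak_latencies[k] + template$latency_shift_ms
    peak <- max(peak, 1)
    scale <- peak / (shape - 1)  # gamma mode at (shape-1)*scale
    tt <- t_ms - tone_onsets_ms[k]
    # gamma-shaped deflection normalized to peak 1 at `peak`
    g <- ifelse(tt > 0, (tt / peak)^(shape - 1) *
                  exp(-(tt - peak) / scale), 0)
    g[!is.finite(g)] <- 0
    y <- y + template$gain * neural$kernel_amplitudes[k] * g
  }
  y
}

# raised-cosine segregation bump, peak 1, confined to the window
segregation_bump <- function(neural, fs = 1000) {
  n <- round(0.600 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  w <- neural$segregation_effect_window
  b <- numeric(n)
  inside <- t_ms >= w[1] & t_ms <= w[2]
  b[inside] <- 0.5 * (1 - cos(2 * pi * (t_ms[inside] - w[1]) / (w[2] - w[1])))
  b
}

# mixture of white and 1/f^a noise with total SD `sd`, generated in one
# pass by random-phase spectral shaping (the target amplitude spectrum is
# sqrt(white + colored) power at each frequency)
synth_noise <- function(n, neural) {
  if (neural$noise_sd == 0) return(numeric(n))
  wf <- neural$noise_white_fraction
  nfft <- stats::nextn(n, c(2, 3, 5))
  f <- pmin(seq_len(nfft) - 1, nfft - (seq_len(nfft) - 1))  # symmetric bins
  colored_pow <- ifelse(f > 0, 1 / f^neural$noise_spectrum_exponent, 0)
  # scale colored power so both components contribute unit variance
  colored_pow <- colored_pow / mean(colored_pow[f > 0])
  amp <- sqrt(wf + (1 - wf) * colored_pow)
  amp[1] <- 0
  phase <- stats::runif(nfft, 0, 2 * pi)
  x <- Re(stats::fft(amp * exp(1i * phase), inverse = TRUE))[seq_len(n)]
  x <- (x - mean(x)) / stats::sd(x)
  neural$noise_sd * x
}

#' Synthesize a continuous source-level recording for one sequence
#'
#' Places the participant's triplet-evoked kernel at every triplet onset,
#' adds the segregation positivity to triplets whose governing percept
#' phase (the phase covering the triplet onset) is segregated, and overlays
#' 1/f + white noise. Synthesis is at 1000 Hz, before preprocessing.
#'
#' @param timeline A [build_stimulus_timeline()] result.
#' @param phases A `phase_table` covering the same duration.
#' @param neural A [neural_params()].
#' @param template A [participant_template()] draw.
#' @param fs Synthesis sampling rate (Hz).
#' @return A [recording()].
#' @export
synthesize_recording <- function(timeline, phases, neural, template,
                                 fs = 1000) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  dur_ph <- attr(phases, "duration")
  if (!isTRUE(all.equal(dur_ph, timeline$duration, tolerance = 1e-6))) {
    stop("timeline and phase table cover different durations", call. = FALSE)
  }
  n <- round(timeline$duration * fs)
  kern <- triplet_kernel(neural, template, fs)
  # the percept effect has its own between-participant gain, independent of
  # the overall response gain (individuals with large evoked responses do
  # not necessarily show large percept effects)
  bump <- segregation_bump(neural, fs) *
    neural$segregation_effect_amplitude * template$effect_gain
  nk <- length(kern)
  seg_state <- percept_at(phases, timeline$triplet_onsets) == "segregated"
  # triplet blocks are contiguous and non-overlapping (period = epoch span)
  y <- rep(kern, length.out = n)
  if (any(seg_state)) {
    offsets <- round(timeline$triplet_onsets[seg_state] * fs)
    idx <- as.vector(outer(seq_len(nk), offsets, "+"))
    keep <- idx <= n
    y[idx[keep]] <- y[idx[keep]] + rep(bump, length(offsets))[keep]
  }
  y <- y + synth_noise(n, neural)
  recording(y, fs)
}

#' Percept governing each time point
#'
#' @param phases A `phase_table`.
#' @param times Times in seconds.
#' @return Character vector, `"integrated"` or `"segregated"`.
#' @export
percept_at <- function(phases, times) {
  idx <- findInterval(times, phases$onset)
  idx[idx < 1L] <- 1L
  ifelse(phases$class[idx] == "segregated", "segregated", "integrated")
}
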