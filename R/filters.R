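#' Continuous source-level recording container
#'
#' @param data Numeric vector of samples (source units).
#' @param sample_rate Sampling rate in Hz.
#' @param units Character, unit label.
#' @param channel Channel name.
#' @return An object of class `recording`.
#' @export
recording <- function(data, sample_rate, units = "source", channel = "ac_mean") {
  stopifnot(is.numeric(data), sample_rate > 0)
  structure(list(data = as.numeric(data), sample_rate = sample_rate,
                 units = units, channel = channel),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples @ %g Hz (%.3f s), channel %s\n",
              length(x$data), x$sample_rate,
              length(x$data) / x$sample_rate, x$channel))
  invisible(x)
}

#' Filter specification
#'
#' Describes a windowed-sinc FIR filter by its -6 dB cutoff and transition
#' bandwidth, the convention in which the preprocessing filters are stated
#' (low-pass 30 Hz with 6.667 Hz transition; high-pass 0.278 Hz with
#' 0.556 Hz transition).
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff_6db Cutoff frequency (Hz) at which the amplitude response
#'   is 0.5 (-6 dB).
#' @param transition_bw Transition bandwidth in Hz.
#' @param window Window function name; only `"hamming"` is implemented.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass"), cutoff_6db,
                        transition_bw, window = "hamming") {
  kind <- match.arg(kind)
  if (cutoff_6db <= 0) stop("`cutoff_6db` must be positive", call. = FALSE)
  if (transition_bw <= 0) stop("`transition_bw` must be positive", call. = FALSE)
  if (kind == "highpass" && cutoff_6db - transition_bw / 2 < 0) {
    stop("high-pass transition band extends below 0 Hz", call. = FALSE)
  }
  structure(list(kind = kind, cutoff_6db = cutoff_6db,
                 transition_bw = transition_bw, window = window),
            class = "filter_spec")
}

#' Design a linear-phase windowed-sinc FIR kernel
#'
#' An ideal sinc low-pass truncated by a Hamming window, with kernel length
#' `ceil(3.3 / (transition_bw / sample_rate))` rounded up to odd (3.3 is the
#' Hamming normalized transition width). Coefficients are normalized to unit
#' DC gain; by the symmetry of the windowed sinc the amplitude response
#' passes through 0.5 at the cutoff, matching the -6 dB convention.
#' High-pass kernels are obtained by spectral inversion of the complementary
#' low-pass, giving zero DC gain.
#'
#' @param spec A [filter_spec()].
#' @param sample_rate Sampling rate of the signal to be filtered (Hz).
#' @return Numeric vector of odd length; symmetric (linear phase).
#' @export
design_windowed_sinc <- function(spec, sample_rate) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff_6db >= sample_rate / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  if (spec$window != "hamming") {
    stop("only the Hamming window is implemented", call. = FALSE)
  }
  tb_norm <- spec$transition_bw / sample_rate
  len <- ceiling(3.3 / tb_norm)
  if (len %% 2 == 0) len <- len + 1
  m <- (len - 1) / 2
  n <- seq(-m, m)
  fc <- spec$cutoff_6db / sample_rate  # cycles per sample
  h <- 2 * fc * sinc_(2 * fc * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)   # Hamming, centered
  h <- h * w
  h <- h / sum(h)                       # exact unit DC gain
  if (spec$kind == "highpass") {
    delta <- numeric(len)
    delta[m + 1] <- 1
    h <- delta - h                      # spectral inversion
  }
  h
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR filtering
#'
#' Applies a symmetric FIR kernel with group-delay compensation so the
#' output is aligned with the input (zero phase). The signal is
#' reflect-padded by half the kernel length at each edge before convolution,
#' which avoids onset transients on signals with nonzero boundary values.
#'
#' @param rec A [recording()].
#' @param kernel Numeric FIR coefficients of odd length.
#' @return A `recording` of the same length and sampling rate.
#' @export
filter_signal <- function(rec, kernel) {
  stopifnot(inherits(rec, "recording"))
  x <- rec$data
  len <- length(kernel)
  if (len >= length(x)) stop("kernel longer than signal", call. = FALSE)
  m <- (len - 1) / 2
  xp <- c(rev(x[seq_len(m) + 1L]), x, rev(x[length(x) - seq_len(m)]))
  y <- fft_convolve(xp, kernel)
  # full convolution of length(xp) + len - 1; centre-aligned segment:
  # x[i] sits at padded position i + m, kernel centre adds another m
  y <- y[(2 * m + 1):(2 * m + length(x))]
  recording(y, rec$sample_rate, rec$units, rec$channel)
}

# linear convolution via FFT (full output)
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Re(stats::fft(X * H, inverse = TRUE) / nfft)[seq_len(n)]
}

#' Downsample a recording by integer decimation
#'
#' The pipeline applies the 30 Hz low-pass before decimation, which already
#' prevents aliasing at the 250 Hz target rate, so decimation keeps every
#' `sample_rate / target_rate`-th sample starting at the first. Sample `i`
#' (1-based) of the output corresponds to time `(i-1)/target_rate`, so event
#' times in seconds are unaffected.
#'
#' @param rec A [recording()].
#' @param target_rate Target sampling rate (Hz); must divide the source rate.
#' @return A `recording` at `target_rate` with `floor(n / factor)` samples.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "recording"))
  if (target_rate > rec$sample_rate) {
    stop("upsampling is not supported", call. = FALSE)
  }
  if (target_rate == rec$sample_rate) return(rec)
  factor <- rec$sample_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop("target rate must integer-divide the source rate", call. = FALSE)
  }
  factor <- round(factor)
  n_out <- floor(length(rec$data) / factor)
  idx <- seq(1L, by = factor, length.out = n_out)
  recording(rec$data[idx], target_rate, rec$units, rec$channel)
}

#' Standard preprocessing chain
#'
#' Low-pass filters at `lowpass` Hz, decimates to `resample` Hz, then
#' high-pass filters at `highpass` Hz (the high-pass is applied at the
#' reduced rate, where its long kernel is cheaper; linear filters commute).
#' Defaults reproduce the study chain: 30 Hz low-pass (6.667 Hz transition),
#' downsampling to 250 Hz, 0.278 Hz high-pass (0.556 Hz transition).
#'
#' @param rec A [recording()] (typically synthesized at 1000 Hz).
#' @param lowpass,lowpass_transition Low-pass -6 dB cutoff / transition (Hz).
#' @param highpass,highpass_transition High-pass cutoff / transition (Hz).
#' @param resample Target rate in Hz.
#' @return A preprocessed `recording` at `resample` Hz.
#' @export
preprocess_recording <- function(rec, lowpass = 30, lowpass_transition = 6.667,
                                 highpass = 0.278, highpass_transition = 0.556,
                                 resample = 250) {
  lp <- design_windowed_sinc(filter_spec("lowpass", lowpass, lowpass_transition),
                             rec$sample_rate)
  rec <- filter_signal(rec, lp)
  rec <- resample_recording(rec, resample)
  hp <- design_windowed_sinc(filter_spec("highpass", highpass, highpass_transition),
                             rec$sample_rate)
  filter_signal(rec, hp)
}

#' Amplitude response of an FIR kernel at given frequencies
#'
#' @param kernel FIR coefficients.
#' @param freqs Frequencies in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @return Amplitude (modulus of the frequency response) at `freqs`.
#' @export
fir_response <- function(kernel, freqs, sample_rate) {
  n <- seq_along(kernel) - 1
  vapply(freqs, function(f) {
    Mod(sum(kernel * exp(-2i * pi * f / sample_rate * n)))
  }, numeric(1))
}
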