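#' Band-pass filter specification
#'
#' Tremor analysis keeps 0.5-15 Hz: below 0.5 Hz lies postural drift, above
#' 15 Hz only noise (physiological and parkinsonian tremor sit well inside
#' the band). The filter is a Butterworth band-pass, applied forward-backward
#' (zero-phase) by default so spectral peak locations are not shifted.
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Butterworth order per band edge (default 4).
#' @param zero_phase apply forward-backward (`TRUE`, default) or single-pass.
#' @return An object of class `"bandpass_spec"`.
#' @export
bandpass_spec <- function(low_hz = 0.5, high_hz = 15, order = 4L,
                          zero_phase = TRUE) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "bandpass_spec")
}

#' Segmentation specification
#'
#' Tremor frequency drifts over a recording, so signals are analysed in short
#' windows. 2-s non-overlapping segments are the default: long enough for a
#' usable spectrum, short enough to track variation (a 30-s accelerometer
#' trace yields 15 segments, a 10-s video window 5).
#'
#' @param segment_len_s segment length in seconds (`> 0`).
#' @param overlap_s overlap between consecutive segments (`>= 0`,
#'   `< segment_len_s`).
#' @return An object of class `"segmentation_spec"`.
#' @export
segmentation_spec <- function(segment_len_s = 2, overlap_s = 0) {
  stopifnot(segment_len_s > 0, overlap_s >= 0, overlap_s < segment_len_s)
  structure(list(segment_len_s = segment_len_s, overlap_s = overlap_s),
            class = "segmentation_spec")
}

#' Band-pass filter a signal
#'
#' @param sig a [uni_signal()].
#' @param spec a [bandpass_spec()].
#' @return The filtered signal: same length, sampling rate and units.
#' @export
bandpass <- function(sig, spec = bandpass_spec()) {
  stopifnot(inherits(sig, "uni_signal"), inherits(spec, "bandpass_spec"))
  nyq <- sig$fs / 2
  if (spec$high_hz >= nyq)
    stop(sprintf(paste0("sampling rate %g Hz is too low for a %g Hz band ",
                        "edge; lower high_hz below fs/2 = %g Hz"),
                 sig$fs, spec$high_hz, nyq), call. = FALSE)
  if (length(sig$samples) <= 3 * spec$order)
    stop("signal too short for filter order ", spec$order, call. = FALSE)
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  x <- sig$samples
  if (spec$zero_phase) {
    # Odd-reflection padding suppresses start/end transients of the
    # forward-backward pass; the pad spans several periods of the low band
    # edge, where the filter's impulse response is longest.
    n <- length(x)
    pad <- min(n - 1L, ceiling(3 * sig$fs / spec$low_hz))
    left <- 2 * x[1] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    out <- y[(pad + 1L):(pad + n)]
  } else {
    out <- as.numeric(signal::filter(bf, x))
  }
  sig$samples <- out
  sig
}

#' Cut a signal into fixed-length segments
#'
#' With the default zero overlap the signal is cut into
#' `floor(duration / segment_len_s)` contiguous segments of
#' `round(segment_len_s * fs)` samples; leftover tail samples are dropped.
#'
#' @param sig a [uni_signal()].
#' @param spec a [segmentation_spec()].
#' @return A list of `uni_signal` segments, in temporal order.
#' @export
segment_signal <- function(sig, spec = segmentation_spec()) {
  stopifnot(inherits(sig, "uni_signal"), inherits(spec, "segmentation_spec"))
  n <- length(sig$samples)
  seg_n <- round(spec$segment_len_s * sig$fs)
  if (n < seg_n)
    stop(sprintf("signal (%.2f s) shorter than segment length (%g s)",
                 n / sig$fs, spec$segment_len_s), call. = FALSE)
  step <- round((spec$segment_len_s - spec$overlap_s) * sig$fs)
  starts <- seq.int(1L, n - seg_n + 1L, by = step)
  lapply(starts, function(s) {
    out <- sig
    out$samples <- sig$samples[s:(s + seg_n - 1L)]
    out
  })
}

#' One-sided amplitude/power spectrum of a segment
#'
#' The segment is mean-removed, optionally Hann-tapered, zero-padded until
#' the frequency grid spacing is at most `resolution_hz`, and transformed
#' with the FFT. The one-sided amplitude spectrum is normalized by the
#' original segment length (doubled for non-DC bins, with window-power
#' correction under the Hann taper) so that a pure in-band sinusoid of
#' amplitude A reads off as a peak of height approximately A; power is
#' amplitude squared over two, so that summed power over an unpadded spectrum
#' equals the time-domain mean square (Parseval). The peak is the grid point
#' of maximal power restricted to `band`; ties break toward the lowest
#' frequency.
#'
#' A 2-s segment has a native grid spacing of 0.5 Hz; zero-padding refines the
#' read-off grid (default 0.05 Hz) without adding information — it
#' interpolates the spectrum so sub-bin peak positions and averaged estimates
#' can be fractional.
#'
#' @param seg a [uni_signal()] segment (length >= 2).
#' @param band numeric `(low_hz, high_hz)` search band for the peak.
#' @param resolution_hz maximum frequency grid spacing after padding.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @param demean remove the segment mean before transforming (default TRUE).
#' @return An object of class `"segment_spectrum"`: fields `freqs`,
#'   `amplitude`, `power`, `peak_freq`, `peak_amplitude`, `band`,
#'   `grid_hz`, `fs`, `n`.
#' @export
segment_spectrum <- function(seg, band = c(0.5, 15), resolution_hz = 0.05,
                             window = c("rectangular", "hann"),
                             demean = TRUE) {
  window <- match.arg(window)
  stopifnot(inherits(seg, "uni_signal"))
  x <- seg$samples
  n <- length(x)
  if (n < 2L) stop("segment must contain at least 2 samples", call. = FALSE)
  if (band[1] <= 0 || band[2] >= seg$fs / 2)
    stop("band must lie inside (0, fs/2)", call. = FALSE)
  if (demean) x <- x - mean(x)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, n - 1L) / (n - 1L))
    x <- x * w
    scale <- sum(w)          # coherent gain correction
  } else {
    scale <- n
  }
  n_pad <- max(n, ceiling(seg$fs / resolution_hz))
  X <- stats::fft(c(x, numeric(n_pad - n)))
  half <- floor(n_pad / 2)
  freqs <- (0:half) * seg$fs / n_pad
  mag <- Mod(X[1:(half + 1L)])
  amp <- 2 * mag / scale
  amp[1] <- mag[1] / scale                      # DC is not doubled
  if (n_pad %% 2 == 0) amp[half + 1L] <- mag[half + 1L] / scale  # Nyquist
  power <- amp^2 / 2
  power[1] <- amp[1]^2
  if (n_pad %% 2 == 0) power[half + 1L] <- amp[half + 1L]^2
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (length(in_band) == 0L)
    stop("no spectral grid point falls inside the band", call. = FALSE)
  peak_i <- in_band[which.max(power[in_band])]  # first max = lowest frequency
  structure(list(freqs = freqs, amplitude = amp, power = power,
                 peak_freq = freqs[peak_i], peak_amplitude = amp[peak_i],
                 band = c(band[1], band[2]), grid_hz = seg$fs / n_pad,
                 fs = seg$fs, n = n),
            class = "segment_spectrum")
}

#' @export
print.segment_spectrum <- function(x, ...) {
  cat(sprintf(paste0("segment_spectrum: peak %.3f Hz (amplitude %.4g) in ",
                     "band %g-%g Hz, grid %.4g Hz\n"),
              x$peak_freq, x$peak_amplitude, x$band[1], x$band[2], x$grid_hz))
  invisible(x)
}

#' Dominant frequency of a segment spectrum
#'
#' @param spec a [segment_spectrum()].
#' @return The band-restricted peak frequency in Hz.
#' @export
dominant_frequency <- function(spec) {
  stopifnot(inherits(spec, "segment_spectrum"))
  spec$peak_freq
}

#' Second-difference acceleration estimate
#'
#' Converts a displacement trace to an acceleration-like trace by the central
#' second difference scaled by `fs^2`. Dominant-frequency estimates of a
#' narrowband signal are unchanged by this operation; amplitudes acquire a
#' `(2*pi*f)^2` factor and lose their displacement units.
#'
#' @param sig a [uni_signal()].
#' @return A `uni_signal` of the same length (endpoints replicated), units
#'   `"arbitrary"`.
#' @export
second_difference <- function(sig) {
  stopifnot(inherits(sig, "uni_signal"))
  x <- sig$samples
  n <- length(x)
  if (n < 3L) stop("signal too short to differentiate", call. = FALSE)
  d <- (x[c(2:n, n)] - 2 * x + x[c(1, 1:(n - 1))]) * sig$fs^2
  sig$samples <- d
  sig$units <- "arbitrary"
  sig
}
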