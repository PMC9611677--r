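#' Outlier rejection rule
#'
#' Values deviating from the mean by more than `k` standard deviations are
#' eliminated automatically, in a single pass. The default `k = 3` with the
#' sample (n-1) standard deviation.
#'
#' @param k standard-deviation multiplier (`> 0`).
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"`.
#' @return An object of class `"outlier_rule"`.
#' @export
outlier_rule <- function(k = 3, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(k > 0)
  structure(list(k = k, sd_mode = sd_mode), class = "outlier_rule")
}

#' Single-pass k-sigma outlier rejection
#'
#' Marks values with `|v - mean(values)| > k * SD(values)` as outliers. The
#' mean and SD are computed once from all values (no re-iteration). A zero
#' or undefined SD (constant input, single value) removes nothing.
#'
#' @param values numeric vector (length >= 1).
#' @param rule an [outlier_rule()].
#' @return A list: `kept` (the non-outlier values, order preserved) and
#'   `mask` (logical, `TRUE` where a value was rejected).
#' @export
reject_outliers <- function(values, rule = outlier_rule()) {
  stopifnot(inherits(rule, "outlier_rule"), length(values) >= 1L)
  m <- mean(values)
  s <- if (rule$sd_mode == "sample") stats::sd(values)
       else sqrt(mean((values - m)^2))
  if (is.na(s) || s == 0) {
    mask <- rep(FALSE, length(values))
  } else {
    mask <- abs(values - m) > rule$k * s
  }
  list(kept = values[!mask], mask = mask)
}

#' Per-landmark, per-segment spectral estimate matrix
#'
#' Runs the band-pass -> segment -> spectrum chain on each input signal and
#' collects dominant frequencies and peak amplitudes into matrices with one
#' row per signal (landmark, or the single accelerometer channel) and one
#' column per segment.
#'
#' @param signals a list of [uni_signal()]s sharing sampling rate and length,
#'   or a single `uni_signal`.
#' @param band a [bandpass_spec()]; also defines the peak-search band.
#' @param seg a [segmentation_spec()].
#' @param resolution_hz spectral grid spacing after zero-padding.
#' @param window FFT window, `"rectangular"` or `"hann"`.
#' @param differentiate convert each signal to a second-difference
#'   acceleration estimate before the spectrum (default `FALSE`).
#' @return An object of class `"estimate_matrix"`: `freq` and `amp` matrices,
#'   `row_labels`, `band`, `grid_hz`, `n_segments`.
#' @export
estimate_matrix <- function(signals, band = bandpass_spec(),
                            seg = segmentation_spec(), resolution_hz = 0.05,
                            window = "rectangular", differentiate = FALSE) {
  if (inherits(signals, "uni_signal")) signals <- list(signals)
  stopifnot(length(signals) >= 1L)
  fs <- signals[[1]]$fs
  len <- length(signals[[1]]$samples)
  for (s in signals) {
    stopifnot(inherits(s, "uni_signal"))
    if (s$fs != fs || length(s$samples) != len)
      stop("all signals must share sampling rate and length", call. = FALSE)
  }
  labels <- vapply(signals, function(s) {
    if (!is.null(s$landmark_id)) as.character(s$landmark_id)
    else if (s$source == "accelerometer") "accel" else s$source
  }, character(1))
  freq_m <- amp_m <- NULL
  grid_hz <- NA_real_
  for (i in seq_along(signals)) {
    filtered <- bandpass(signals[[i]], band)
    if (differentiate) filtered <- second_difference(filtered)
    pieces <- segment_signal(filtered, seg)
    specs <- lapply(pieces, segment_spectrum,
                    band = c(band$low_hz, band$high_hz),
                    resolution_hz = resolution_hz, window = window)
    if (is.null(freq_m)) {
      freq_m <- matrix(NA_real_, length(signals), length(specs))
      amp_m <- matrix(NA_real_, length(signals), length(specs))
      grid_hz <- specs[[1]]$grid_hz
    }
    freq_m[i, ] <- vapply(specs, `[[`, numeric(1), "peak_freq")
    amp_m[i, ] <- vapply(specs, `[[`, numeric(1), "peak_amplitude")
  }
  rownames(freq_m) <- rownames(amp_m) <- labels
  structure(list(freq = freq_m, amp = amp_m, row_labels = labels,
                 band = c(band$low_hz, band$high_hz), grid_hz = grid_hz,
                 n_segments = ncol(freq_m)),
            class = "estimate_matrix")
}

#' @export
print.estimate_matrix <- function(x, ...) {
  cat(sprintf("estimate_matrix: %d row(s) x %d segment(s), band %g-%g Hz\n",
              nrow(x$freq), ncol(x$freq), x$band[1], x$band[2]))
  invisible(x)
}

#' Fuse an estimate matrix into one per-recording estimate
#'
#' Pools the dominant-frequency values of all (landmark, segment) cells,
#' applies single-pass k-sigma rejection, and averages the surviving values;
#' the amplitude is averaged over the same surviving positions (one exclusion
#' process feeds both analyses). With `pooling = "per_landmark_mean"` the
#' rejection instead acts on the 21 per-landmark mean frequencies.
#'
#' @param mat an [estimate_matrix()].
#' @param rule an [outlier_rule()].
#' @param pooling `"pooled"` (elementwise over all cells, default) or
#'   `"per_landmark_mean"`.
#' @return An object of class `"tremor_estimate"`.
#' @export
fuse_estimates <- function(mat, rule = outlier_rule(),
                           pooling = c("pooled", "per_landmark_mean")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(mat, "estimate_matrix"), nrow(mat$freq) >= 1L)
  if (pooling == "pooled") {
    vals <- as.vector(mat$freq)
    rej <- reject_outliers(vals, rule)
    mask <- matrix(rej$mask, nrow(mat$freq), ncol(mat$freq))
    dominant <- mean(mat$freq[!mask])
    amplitude <- mean(mat$amp[!mask])
  } else {
    row_means <- rowMeans(mat$freq)
    rej <- reject_outliers(row_means, rule)
    mask <- matrix(rej$mask, nrow(mat$freq), ncol(mat$freq))
    dominant <- mean(mat$freq[!rej$mask, , drop = FALSE])
    amplitude <- mean(mat$amp[!rej$mask, , drop = FALSE])
  }
  stopifnot(any(!mask))  # single-pass k-sigma cannot reject everything
  per_lm <- rowMeans(ifelse(mask, NA, mat$freq), na.rm = TRUE)
  names(per_lm) <- mat$row_labels
  structure(list(dominant_freq = dominant, amplitude = amplitude,
                 n_values_used = sum(!mask), n_values_excluded = sum(mask),
                 excluded_mask = mask, per_landmark_freq = per_lm,
                 matrix = mat, band = mat$band, grid_hz = mat$grid_hz,
                 rule = rule, pooling = pooling,
                 patient_id = "unknown", session = "unspecified",
                 source = NA_character_, amplitude_units = NA_character_),
            class = "tremor_estimate")
}

#' Estimate the dominant tremor frequency and amplitude of a recording
#'
#' The package's central estimator. For a hand-landmark recording the chain
#' is: trim to the analysis window, extract the chosen axis of all 21
#' landmarks, band-pass filter (0.5-15 Hz), cut into non-overlapping 2-s
#' segments, take each segment's FFT peak, then pool the 21 x n_segments
#' (frequency, amplitude) values and fuse them with automatic 3-SD outlier
#' elimination. For a single accelerometer trace the same chain runs on a
#' 1 x n_segments matrix (no trimming).
#'
#' @param x a [landmark_recording()] or a [uni_signal()].
#' @param ... passed between methods.
#' @return An object of class `"tremor_estimate"` with fields
#'   `dominant_freq` (Hz), `amplitude` (normalized-coordinate units for
#'   video, cm/s^2 for accelerometer), the per-landmark/per-segment
#'   `matrix`, the `excluded_mask`, and exclusion counts. Supports `print`,
#'   `summary`, `coef` and `plot`.
#' @examples
#' rec <- simulate_recording(sim_config(tremor_freq_hz = 4, seed = 1))
#' est <- estimate_tremor(rec)
#' coef(est)
#' @export
estimate_tremor <- function(x, ...) UseMethod("estimate_tremor")

#' @rdname estimate_tremor
#' @param trim a [trim_policy()], or `NULL` to analyse the full recording.
#' @param band a [bandpass_spec()].
#' @param seg a [segmentation_spec()].
#' @param resolution_hz spectral grid spacing (Hz) after zero-padding.
#' @param rule an [outlier_rule()].
#' @param axis landmark coordinate to analyse (default `"y"`, the vertical).
#' @param window FFT window.
#' @param pooling outlier pooling mode, see [fuse_estimates()].
#' @param differentiate analyse the second-difference acceleration estimate
#'   instead of displacement (default `FALSE`).
#' @export
estimate_tremor.landmark_recording <- function(x, trim = trim_policy(),
                                               band = bandpass_spec(),
                                               seg = segmentation_spec(),
                                               resolution_hz = 0.05,
                                               rule = outlier_rule(),
                                               axis = "y",
                                               window = "rectangular",
                                               pooling = "pooled",
                                               differentiate = FALSE, ...) {
  if (!is.null(trim)) x <- trim_recording(x, trim)
  signals <- lapply(0:20, function(i) extract_axis(x, i, axis))
  mat <- estimate_matrix(signals, band = band, seg = seg,
                         resolution_hz = resolution_hz, window = window,
                         differentiate = differentiate)
  est <- fuse_estimates(mat, rule, pooling)
  est$patient_id <- x$patient_id
  est$session <- x$session
  est$source <- "video"
  est$amplitude_units <- if (differentiate) "a.u." else "normalized"
  est$call <- match.call()
  est
}

#' @rdname estimate_tremor
#' @export
estimate_tremor.uni_signal <- function(x, band = bandpass_spec(),
                                       seg = segmentation_spec(),
                                       resolution_hz = 0.05,
                                       rule = outlier_rule(),
                                       window = "rectangular",
                                       differentiate = FALSE, ...) {
  mat <- estimate_matrix(list(x), band = band, seg = seg,
                         resolution_hz = resolution_hz, window = window,
                         differentiate = differentiate)
  est <- fuse_estimates(mat, rule, "pooled")
  est$source <- x$source
  est$amplitude_units <- switch(x$units, cm_per_s2 = "cm/s^2",
                                normalized_coordinate = "normalized",
                                x$units)
  est$call <- match.call()
  est
}

#' @export
print.tremor_estimate <- function(x, digits = 3, ...) {
  cat("Tremor estimate (", x$source, ")\n", sep = "")
  if (x$patient_id != "unknown" || x$session != "unspecified")
    cat("  patient: ", x$patient_id, "  session: ", x$session, "\n", sep = "")
  cat(sprintf("  dominant frequency: %.*f Hz\n", digits, x$dominant_freq))
  cat(sprintf("  amplitude:          %.*g %s\n", digits + 1, x$amplitude,
              x$amplitude_units))
  cat(sprintf("  values used: %d, excluded as outliers: %d (|v - mean| > %g SD)\n",
              x$n_values_used, x$n_values_excluded, x$rule$k))
  invisible(x)
}

#' @export
coef.tremor_estimate <- function(object, ...) {
  c(dominant_freq_hz = object$dominant_freq, amplitude = object$amplitude)
}

#' @export
summary.tremor_estimate <- function(object, ...) {
  kept <- object$matrix$freq[!object$excluded_mask]
  structure(list(estimate = object,
                 freq_range = range(object$matrix$freq),
                 kept_sd = if (length(kept) > 1) stats::sd(kept) else 0,
                 per_landmark_freq = object$per_landmark_freq),
            class = "summary.tremor_estimate")
}

#' @export
print.summary.tremor_estimate <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  per-segment frequency range: %.3f - %.3f Hz (kept SD %.3f)\n",
              x$freq_range[1], x$freq_range[2], x$kept_sd))
  if (length(x$per_landmark_freq) > 1L) {
    cat("  per-landmark mean frequencies (Hz):\n")
    print(round(x$per_landmark_freq, 3))
  }
  invisible(x)
}

#' @export
plot.tremor_estimate <- function(x, ...) {
  f <- x$matrix$freq
  excl <- x$excluded_mask
  lm_idx <- rep(seq_len(nrow(f)), ncol(f))
  graphics::plot(lm_idx, as.vector(f),
                 col = ifelse(as.vector(excl), "red", "grey30"),
                 pch = ifelse(as.vector(excl), 4, 16),
                 xlab = if (nrow(f) > 1) "landmark row" else "channel",
                 ylab = "segment dominant frequency (Hz)",
                 main = sprintf("Fused dominant frequency: %.3f Hz",
                                x$dominant_freq), ...)
  graphics::abline(h = x$dominant_freq, lty = 2, col = "blue")
  invisible(x)
}
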