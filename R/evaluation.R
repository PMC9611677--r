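#' Absolute error between paired frequency estimates
#'
#' The per-patient agreement measure between the accelerometer-derived and
#' video-derived dominant frequencies, `|f_acc - f_vid|`.
#'
#' @param f_acc,f_vid dominant frequencies in Hz (vectorized).
#' @return `abs(f_acc - f_vid)` in Hz.
#' @export
absolute_error <- function(f_acc, f_vid) {
  stopifnot(is.numeric(f_acc), is.numeric(f_vid))
  abs(f_acc - f_vid)
}

#' Root mean square error between paired frequency estimates
#'
#' `sqrt(mean((f_acc - f_vid)^2))` over the n complete pairs.
#'
#' @param f_acc,f_vid paired dominant frequencies in Hz; pairs with a missing
#'   member are dropped.
#' @return RMSE in Hz.
#' @export
freq_rmse <- function(f_acc, f_vid) {
  stopifnot(length(f_acc) == length(f_vid))
  ok <- stats::complete.cases(f_acc, f_vid)
  if (!any(ok)) stop("no complete pairs", call. = FALSE)
  sqrt(mean((f_acc[ok] - f_vid[ok])^2))
}

#' Pearson correlation with a t-based p-value
#'
#' Product-moment correlation between two paired measurements, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom. Computed directly from sums; tests cross-check it
#' against [stats::cor.test()].
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return A list: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0)
    stop("zero variance in one coordinate; correlation undefined",
         call. = FALSE)
  r <- sum(xc * yc) / (sx * sy)
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Before/after medication change
#'
#' Change is `after - before`, so a negative value means the frequency (or
#' amplitude) decreased after medication.
#'
#' @param before,after paired values in the same units (vectorized).
#' @return `after - before`.
#' @export
medication_change <- function(before, after) {
  stopifnot(is.numeric(before), is.numeric(after),
            length(before) == length(after))
  after - before
}

#' Cohort mean and sample standard deviation
#'
#' @param values numeric vector (length >= 1); missing values are dropped.
#' @return A list: `mean`, `sd` (n-1 convention; 0 for a single value), `n`.
#' @export
cohort_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("no values to summarize", call. = FALSE)
  s <- if (length(values) > 1L) stats::sd(values) else 0
  list(mean = mean(values), sd = s, n = length(values))
}

#' Round half away from zero
#'
#' Report tables round at 3 decimals, half up (1.0005 -> 1.001), rather than
#' R's default round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Accelerometer-vs-video comparison table
#'
#' Joins per-patient video and accelerometer estimates on `patient_id` and
#' computes the validation statistics: per-patient absolute error, cohort
#' mean +/- SD of the absolute error, RMSE, and the Pearson correlation of
#' the paired frequencies (and of the paired amplitudes when both sides
#' provide them). Patients lacking accelerometer data remain in the table
#' with `f_acc = NA` but are excluded from `n` and all paired statistics
#' (complete-case analysis).
#'
#' @param video,accel data frames with columns `patient_id`,
#'   `dominant_freq_hz` and optionally `amplitude`.
#' @return An object of class `"cohort_comparison"`: `rows` (per-patient
#'   table), `n`, `mean_ae`, `sd_ae`, `rmse`, `pearson_r`, `pearson_p`, and
#'   `amp_pearson_r`/`amp_pearson_p` when amplitudes are available.
#' @export
build_comparison_table <- function(video, accel) {
  video <- normalize_estimate_set(video)
  accel <- normalize_estimate_set(accel)
  if (anyDuplicated(video$patient_id))
    stop("duplicate patient_id in video estimates", call. = FALSE)
  if (anyDuplicated(accel$patient_id))
    stop("duplicate patient_id in accelerometer estimates", call. = FALSE)
  ids <- sort(unique(c(video$patient_id, accel$patient_id)))
  vi <- match(ids, video$patient_id)
  ai <- match(ids, accel$patient_id)
  rows <- data.frame(
    patient_id = ids,
    f_acc = accel$dominant_freq_hz[ai],
    f_vid = video$dominant_freq_hz[vi],
    stringsAsFactors = FALSE)
  rows$ae <- absolute_error(rows$f_acc, rows$f_vid)
  have_amp <- !is.null(video$amplitude) && !is.null(accel$amplitude)
  if (have_amp) {
    rows$a_acc <- accel$amplitude[ai]
    rows$a_vid <- video$amplitude[vi]
  }
  ok <- stats::complete.cases(rows$f_acc, rows$f_vid)
  n <- sum(ok)
  out <- list(rows = rows, n = n)
  if (n >= 1L) {
    ae_sum <- cohort_summary(rows$ae[ok])
    out$mean_ae <- ae_sum$mean
    out$sd_ae <- ae_sum$sd
    out$rmse <- freq_rmse(rows$f_acc, rows$f_vid)
  } else {
    warning("no complete accelerometer/video pairs; RMSE undefined")
    out$mean_ae <- out$sd_ae <- out$rmse <- NA_real_
  }
  if (n >= 3L) {
    pr <- pearson_r(rows$f_acc, rows$f_vid)
    out$pearson_r <- pr$r; out$pearson_p <- pr$p
    if (have_amp) {
      okA <- stats::complete.cases(rows$a_acc, rows$a_vid)
      if (sum(okA) >= 3L) {
        pa <- pearson_r(rows$a_acc, rows$a_vid)
        out$amp_pearson_r <- pa$r; out$amp_pearson_p <- pa$p
      }
    }
  } else {
    out$pearson_r <- out$pearson_p <- NA_real_
  }
  structure(out, class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, digits = 3, ...) {
  cat("Accelerometer vs. video dominant-frequency comparison\n")
  rows <- x$rows
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], round_half_up, digits)
  print(rows, row.names = FALSE)
  cat(sprintf("  n complete pairs: %d\n", x$n))
  cat(sprintf("  mean AE: %.*f (+/-%.*f) Hz, RMSE: %.*f Hz\n",
              digits, round_half_up(x$mean_ae, digits),
              digits, round_half_up(x$sd_ae, digits),
              digits, round_half_up(x$rmse, digits)))
  if (!is.null(x$pearson_r) && !is.na(x$pearson_r))
    cat(sprintf("  frequency Pearson r = %.2f (p = %.3g)\n",
                x$pearson_r, x$pearson_p))
  if (!is.null(x$amp_pearson_r))
    cat(sprintf("  amplitude Pearson r = %.2f (p = %.3g)\n",
                x$amp_pearson_r, x$amp_pearson_p))
  invisible(x)
}

#' Before/after-medication change table
#'
#' Joins per-patient before- and after-medication estimates on `patient_id`
#' (complete cases only) and computes per-patient changes (`after - before`)
#' plus cohort mean +/- SD for the before column, after column, and change.
#'
#' @param before,after data frames with columns `patient_id` and `value`
#'   (any single measure: dominant frequency in Hz or amplitude), or
#'   estimate sets as accepted by [build_comparison_table()] (then
#'   `measure` selects the column).
#' @param measure which estimate column to compare when full estimate sets
#'   are given: `"dominant_freq_hz"` (default) or `"amplitude"`.
#' @return An object of class `"medication_comparison"`: `rows`
#'   (`patient_id`, `before`, `after`, `change`), `n`, and `before_mean`,
#'   `before_sd`, `after_mean`, `after_sd`, `change_mean`, `change_sd`.
#' @export
build_medication_table <- function(before, after,
                                   measure = c("dominant_freq_hz",
                                               "amplitude")) {
  measure <- match.arg(measure)
  pick <- function(df) {
    if (!is.null(df$value)) {
      data.frame(patient_id = as.character(df$patient_id), value = df$value,
                 stringsAsFactors = FALSE)
    } else {
      df <- normalize_estimate_set(df)
      if (is.null(df[[measure]]))
        stop("estimate set lacks the '", measure, "' column", call. = FALSE)
      data.frame(patient_id = df$patient_id, value = df[[measure]],
                 stringsAsFactors = FALSE)
    }
  }
  b <- pick(before); a <- pick(after)
  if (anyDuplicated(b$patient_id) || anyDuplicated(a$patient_id))
    stop("duplicate patient_id", call. = FALSE)
  ids <- sort(intersect(b$patient_id, a$patient_id))
  if (length(ids) < 1L) stop("no patients present in both sessions",
                             call. = FALSE)
  rows <- data.frame(
    patient_id = ids,
    before = b$value[match(ids, b$patient_id)],
    after = a$value[match(ids, a$patient_id)],
    stringsAsFactors = FALSE)
  rows$change <- medication_change(rows$before, rows$after)
  sb <- cohort_summary(rows$before)
  sa <- cohort_summary(rows$after)
  sc <- cohort_summary(rows$change)
  structure(list(rows = rows, n = nrow(rows),
                 before_mean = sb$mean, before_sd = sb$sd,
                 after_mean = sa$mean, after_sd = sa$sd,
                 change_mean = sc$mean, change_sd = sc$sd,
                 measure = measure),
            class = "medication_comparison")
}

#' @export
print.medication_comparison <- function(x, digits = 3, ...) {
  cat("Before/after-medication comparison (", x$measure, ")\n", sep = "")
  rows <- x$rows
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], round_half_up, digits)
  print(rows, row.names = FALSE)
  cat(sprintf("  mean before: %.*f (+/-%.*f), after: %.*f (+/-%.*f), change: %.*f (+/-%.*f)\n",
              digits, round_half_up(x$before_mean, digits),
              digits, round_half_up(x$before_sd, digits),
              digits, round_half_up(x$after_mean, digits),
              digits, round_half_up(x$after_sd, digits),
              digits, round_half_up(x$change_mean, digits),
              digits, round_half_up(x$change_sd, digits)))
  invisible(x)
}

# Accept estimate sets as data frames (patient_id + dominant_freq_hz
# [+ amplitude]) or lists of tremor_estimate objects.
normalize_estimate_set <- function(x) {
  if (is.data.frame(x)) {
    if (is.null(x$patient_id) || is.null(x$dominant_freq_hz))
      stop("estimate set needs columns patient_id and dominant_freq_hz",
           call. = FALSE)
    x$patient_id <- as.character(x$patient_id)
    return(x)
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "tremor_estimate"))) {
    return(data.frame(
      patient_id = vapply(x, `[[`, character(1), "patient_id"),
      dominant_freq_hz = vapply(x, `[[`, numeric(1), "dominant_freq"),
      amplitude = vapply(x, `[[`, numeric(1), "amplitude"),
      stringsAsFactors = FALSE))
  }
  stop("cannot interpret estimate set; give a data frame or a list of ",
       "tremor_estimate objects", call. = FALSE)
}

#' Per-patient benchmark tables from a published PD cohort
#'
#' Ships the per-patient dominant frequencies and spectral amplitudes of an
#' 11-patient Parkinson's disease cohort measured both with a wrist
#' accelerometer and with the markerless video pipeline, before and (video
#' only) after dopaminergic medication. These tables serve as fixed inputs
#' for the evaluation statistics; one patient (PAT011) has no accelerometer
#' recording and enters paired statistics as missing.
#'
#' @param name one of `"frequency_validation"` (accelerometer vs. video Hz),
#'   `"amplitude_validation"` (cm/s^2 vs. a.u.),
#'   `"medication_frequency"` (video Hz before/after),
#'   `"medication_amplitude"` (video a.u. before/after).
#' @return A data frame.
#' @export
pd_cohort_table <- function(name = c("frequency_validation",
                                     "amplitude_validation",
                                     "medication_frequency",
                                     "medication_amplitude")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("pd_cohort_", name, ".csv"),
                      package = "tremorkit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
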