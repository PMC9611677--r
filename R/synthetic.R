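#' Configuration for a synthetic hand recording
#'
#' Describes the displacement model used to generate ground-truth recordings:
#' each non-occluded landmark's vertical trace is
#' `baseline + tremor_amp * sin(2*pi*f0*t + phase)
#'  + heartbeat_amp * sin(2*pi*f_h*t) + drift + white noise`.
#' The heartbeat term models ballistocardiographic movement — subtle rhythmic
#' displacement at the resting heart rate (60-90 bpm, i.e. 1-1.5 Hz)
#' conducted into the hands, which dominates the spectrum of non-tremulous
#' hands. Drift models slow postural wander below the analysis band.
#'
#' Occluded landmarks emulate tracker pseudo-inference: a hand tracker never
#' reports a missing landmark but infers its position from the visible hand,
#' so the pseudo-trajectory keeps the hand-coherent displacement (tremor,
#' heartbeat, drift) but gains a structured low-frequency wander (a random
#' walk low-pass filtered at 2 Hz, uncorrelated with the tremor) and
#' inflated jitter. A minority of such landmarks' segments therefore peak at
#' a non-tremor frequency, which is exactly what the 3-SD fusion step is
#' there to reject.
#'
#' Defaults emulate a bedside protocol: 180 fps video, 14-s raw recording
#' (so a (2 s, 2 s, 10 s) trim applies), 4 Hz parkinsonian tremor of
#' 0.01 normalized units displacement (roughly 10 px at 1080p), a 1.2 Hz
#' heartbeat component five times smaller, sub-pixel white jitter.
#'
#' @param fps video frame rate (Hz, `> 30`).
#' @param duration_s raw recording length in seconds.
#' @param tremor_freq_hz tremor frequency f0 in Hz (0 disables the tremor
#'   via `tremor_amp = 0` as well).
#' @param tremor_amp tremor displacement amplitude, normalized units.
#' @param tremor_phase tremor phase in radians.
#' @param heartbeat_freq_hz ballistocardiographic frequency (Hz, typically
#'   1-1.5).
#' @param heartbeat_amp heartbeat displacement amplitude, normalized units.
#' @param drift_amp,drift_freq_hz slow baseline wander (drift_freq below the
#'   0.5 Hz band edge).
#' @param noise_sd white tracking-jitter SD, normalized units.
#' @param occluded_landmarks integer ids (0-20) replaced by pseudo-inferred
#'   trajectories.
#' @param pseudo_wander_sd RMS displacement of the occluded landmarks' extra
#'   low-frequency wander, normalized units.
#' @param baseline_y optional length-21 vector of rest positions in
#'   `[0.1, 0.9]`; a default spread hand layout is used when `NULL`.
#' @param accel_noise_sd accelerometer sensor noise SD in cm/s^2.
#' @param cm_per_unit physical scale: centimetres per normalized coordinate
#'   unit (field-of-view height of a hand-framing camera, default 10 cm);
#'   affects only accelerometer amplitudes, never frequencies.
#' @param seed integer seed; identical configurations generate identical
#'   recordings.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(fps = 180, duration_s = 14, tremor_freq_hz = 4,
                       tremor_amp = 0.01, tremor_phase = 0,
                       heartbeat_freq_hz = 1.2, heartbeat_amp = 0.002,
                       drift_amp = 0.005, drift_freq_hz = 0.1,
                       noise_sd = 0.001, occluded_landmarks = integer(0),
                       pseudo_wander_sd = 0.01, baseline_y = NULL,
                       accel_noise_sd = 0.5, cm_per_unit = 10, seed = 1L) {
  stopifnot(fps > 30, duration_s > 0, tremor_freq_hz >= 0, tremor_amp >= 0,
            heartbeat_freq_hz >= 0, heartbeat_amp >= 0, drift_amp >= 0,
            noise_sd >= 0, pseudo_wander_sd >= 0, cm_per_unit > 0)
  occluded_landmarks <- as.integer(occluded_landmarks)
  if (length(occluded_landmarks) &&
      (any(occluded_landmarks < 0L) || any(occluded_landmarks > 20L)))
    stop("occluded_landmarks must be ids in 0-20", call. = FALSE)
  if (is.null(baseline_y)) {
    # spread hand: wrist low in frame, fingertips higher
    baseline_y <- 0.55 - 0.25 * (0:20) / 20
  }
  stopifnot(length(baseline_y) == 21L,
            all(baseline_y >= 0.1), all(baseline_y <= 0.9))
  excursion <- tremor_amp + heartbeat_amp + drift_amp + 6 * noise_sd +
    4 * pseudo_wander_sd
  if (any(baseline_y - excursion < 0) || any(baseline_y + excursion > 1))
    stop("configured amplitudes can push y outside [0, 1]; reduce amplitudes ",
         "or move baselines toward 0.5", call. = FALSE)
  structure(list(fps = fps, duration_s = duration_s,
                 tremor_freq_hz = tremor_freq_hz, tremor_amp = tremor_amp,
                 tremor_phase = tremor_phase,
                 heartbeat_freq_hz = heartbeat_freq_hz,
                 heartbeat_amp = heartbeat_amp, drift_amp = drift_amp,
                 drift_freq_hz = drift_freq_hz, noise_sd = noise_sd,
                 occluded_landmarks = occluded_landmarks,
                 pseudo_wander_sd = pseudo_wander_sd, baseline_y = baseline_y,
                 accel_noise_sd = accel_noise_sd, cm_per_unit = cm_per_unit,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Low-pass-filtered random walk rescaled to a target RMS: the structured
# non-tremor wander of a pseudo-inferred landmark.
pseudo_wander <- function(n, fs, target_sd, cutoff_hz = 2) {
  w <- cumsum(stats::rnorm(n))
  bf <- signal::butter(2, min(cutoff_hz / (fs / 2), 0.99), type = "low")
  w <- signal::filtfilt(bf, w)
  w <- w - mean(w)
  s <- stats::sd(w)
  if (s > 0) w <- w * target_sd / s
  w
}

#' Simulate a hand-landmark recording with known ground truth
#'
#' Generates a [landmark_recording()] following the displacement model in
#' [sim_config()]. All 21 landmarks share the hand-coherent motion (tremor,
#' heartbeat, drift) around their individual baselines; occluded landmarks
#' additionally wander (see [sim_config()]) and are marked `FALSE` in the
#' recording's `visible` matrix. Identical configurations (including the
#' seed) produce bit-identical recordings.
#'
#' @param config a [sim_config()].
#' @return A `landmark_recording` at `config$fps` with
#'   `round(duration_s * fps)` frames, frame size 1920 x 1080.
#' @export
simulate_recording <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- round(config$duration_s * config$fps)
  t <- (seq_len(n) - 1L) / config$fps
  tremor <- config$tremor_amp *
    sin(2 * pi * config$tremor_freq_hz * t + config$tremor_phase)
  heart <- config$heartbeat_amp * sin(2 * pi * config$heartbeat_freq_hz * t)
  drift <- config$drift_amp * sin(2 * pi * config$drift_freq_hz * t)
  hand <- tremor + heart + drift
  x <- y <- z <- matrix(NA_real_, n, 21L)
  visible <- matrix(TRUE, n, 21L)
  occ <- config$occluded_landmarks
  for (i in 0:20) {
    j <- i + 1L
    yi <- config$baseline_y[j] + hand + stats::rnorm(n, sd = config$noise_sd)
    if (i %in% occ) {
      yi <- yi + pseudo_wander(n, config$fps, config$pseudo_wander_sd) +
        stats::rnorm(n, sd = 2 * config$noise_sd)
      visible[, j] <- FALSE
    }
    y[, j] <- pmin(pmax(yi, 0), 1)
    x[, j] <- pmin(pmax(0.35 + 0.3 * i / 20 +
                          stats::rnorm(n, sd = config$noise_sd), 0), 1)
    z[, j] <- stats::rnorm(n, sd = config$noise_sd)
  }
  landmark_recording(x = x, y = y, z = z, fps = config$fps,
                     patient_id = "synthetic", session = "unspecified",
                     frame_width = 1920, frame_height = 1080,
                     visible = visible)
}

#' Simulate an accelerometer trace consistent with a recording
#'
#' Returns the analytic second time-derivative of the hand displacement
#' model, scaled to physical units: a displacement component of amplitude
#' `a` (normalized units) at frequency `f` contributes an acceleration
#' sinusoid of amplitude `a * cm_per_unit * (2*pi*f)^2` cm/s^2, plus white
#' sensor noise.
#'
#' @param config a [sim_config()].
#' @param fs accelerometer sampling rate in Hz (`> 30`, default 100).
#' @param duration_s trace length in seconds (default 30).
#' @return A [uni_signal()] with units `cm_per_s2`, source
#'   `"accelerometer"`.
#' @export
simulate_accelerometer <- function(config = sim_config(), fs = 100,
                                   duration_s = 30) {
  stopifnot(inherits(config, "sim_config"), fs > 30)
  set.seed(config$seed + 1L)  # distinct stream from the video recording
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  d2 <- function(a, f, ph = 0) -a * (2 * pi * f)^2 * sin(2 * pi * f * t + ph)
  acc <- config$cm_per_unit *
    (d2(config$tremor_amp, config$tremor_freq_hz, config$tremor_phase) +
       d2(config$heartbeat_amp, config$heartbeat_freq_hz) +
       d2(config$drift_amp, config$drift_freq_hz)) +
    stats::rnorm(n, sd = config$accel_noise_sd)
  uni_signal(acc, fs = fs, units = "cm_per_s2", source = "accelerometer")
}

#' Simulate a before/after-medication cohort with ground truth
#'
#' Builds paired recordings for `n_patients` subjects. A fraction
#' `tremor_fraction` of patients carry classical parkinsonian tremor
#' (f0 drawn in 4-5 Hz); the remainder show only the low-frequency rhythmic
#' movement of a resting non-tremulous hand (f0 drawn in 1-1.5 Hz, the
#' ballistocardiographic range). Medication reduces frequency by
#' `effect_freq_delta` Hz (floored at 0.9 Hz so the signal stays in band)
#' and multiplies displacement amplitude by `effect_amp_factor`.
#'
#' @param n_patients cohort size (default 11).
#' @param tremor_fraction fraction with parkinsonian tremor (default 2/11).
#' @param effect_freq_delta additive frequency change after medication in Hz
#'   (negative = decrease; default -0.5).
#' @param effect_amp_factor multiplicative amplitude change after medication
#'   (default 0.5).
#' @param seed integer seed.
#' @param accelerometer also simulate a before-medication accelerometer
#'   trace per patient (default TRUE).
#' @return A list with `patients` (per patient: `before`, `after`
#'   [landmark_recording()]s and optionally `accel` [uni_signal()]) and
#'   `truth`, a data frame of
#'   (`patient_id`, `f0_before_hz`, `f0_after_hz`, `amp_before`,
#'   `amp_after`, `tremor`).
#' @export
make_cohort <- function(n_patients = 11, tremor_fraction = 2 / 11,
                        effect_freq_delta = -0.5, effect_amp_factor = 0.5,
                        seed = 1L, accelerometer = TRUE) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  n_tremor <- round(n_patients * tremor_fraction)
  is_tremor <- seq_len(n_patients) <= n_tremor
  f0 <- ifelse(is_tremor, stats::runif(n_patients, 4, 5),
               stats::runif(n_patients, 1, 1.5))
  amp <- ifelse(is_tremor, stats::runif(n_patients, 0.008, 0.015),
                stats::runif(n_patients, 0.002, 0.004))
  f0_after <- pmax(f0 + effect_freq_delta, 0.9)
  amp_after <- amp * effect_amp_factor
  ids <- sprintf("SIM%03d", seq_len(n_patients))
  patient_seeds <- sample.int(2^20, n_patients)
  patients <- vector("list", n_patients)
  names(patients) <- ids
  for (i in seq_len(n_patients)) {
    # Non-tremor patients: the f0 sinusoid IS their heartbeat-conducted
    # movement, so no second cardiac tone is added on top of it.
    hb_amp <- if (is_tremor[i]) 0.002 else 0
    cfg_b <- sim_config(tremor_freq_hz = f0[i], tremor_amp = amp[i],
                        heartbeat_amp = hb_amp, seed = patient_seeds[i])
    cfg_a <- sim_config(tremor_freq_hz = f0_after[i], tremor_amp = amp_after[i],
                        heartbeat_amp = hb_amp,
                        seed = patient_seeds[i] + 500000L)
    before <- simulate_recording(cfg_b)
    before$patient_id <- ids[i]; before$session <- "before_medication"
    after <- simulate_recording(cfg_a)
    after$patient_id <- ids[i]; after$session <- "after_medication"
    patients[[i]] <- list(before = before, after = after)
    if (accelerometer)
      patients[[i]]$accel <- simulate_accelerometer(cfg_b)
  }
  truth <- data.frame(patient_id = ids, f0_before_hz = f0,
                      f0_after_hz = f0_after, amp_before = amp,
                      amp_after = amp_after, tremor = is_tremor,
                      stringsAsFactors = FALSE)
  list(patients = patients, truth = truth)
}
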