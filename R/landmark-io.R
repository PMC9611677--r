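#' Hand-landmark recording
#'
#' Container for a markerless hand-tracking recording: per-frame positions of
#' the 21 canonical hand landmarks (wrist, finger joints, fingertips), with
#' `x` and `y` normalized to `[0, 1]` by the frame width and height and `z` a
#' dimensionless relative depth. Landmark ids follow the usual hand-tracker
#' convention: 0 = wrist, 4 = thumb tip, 8 = index fingertip, 12 = middle
#' fingertip, 16 = ring fingertip, 20 = little fingertip.
#'
#' @param x,y,z numeric matrices of dimension `n_frames x 21`; column `j`
#'   holds landmark id `j - 1`. `x` and `y` must lie in `[0, 1]`.
#' @param fps frames per second (Hz, `>= 1`).
#' @param patient_id character label for the subject.
#' @param session one of `"before_medication"`, `"after_medication"`,
#'   `"unspecified"`.
#' @param frame_width,frame_height optional frame dimensions in pixels.
#' @param visible optional logical matrix (`n_frames x 21`): `TRUE` where the
#'   tracker actually saw the landmark, `FALSE` where it inferred it.
#'
#' @return An object of class `"landmark_recording"`.
#' @seealso [read_landmarks()], [trim_recording()], [extract_axis()]
#' @export
landmark_recording <- function(x, y, z, fps,
                               patient_id = "unknown",
                               session = c("unspecified", "before_medication",
                                           "after_medication"),
                               frame_width = NULL, frame_height = NULL,
                               visible = NULL) {
  session <- match.arg(session)
  x <- as.matrix(x); y <- as.matrix(y); z <- as.matrix(z)
  rec <- structure(
    list(patient_id = as.character(patient_id), session = session,
         fps = as.numeric(fps),
         frame_width = if (is.null(frame_width)) NULL else as.numeric(frame_width),
         frame_height = if (is.null(frame_height)) NULL else as.numeric(frame_height),
         x = x, y = y, z = z, visible = visible),
    class = "landmark_recording")
  validate_recording(rec)
  rec
}

#' Validate a landmark recording
#'
#' Checks the structural invariants: 21 landmarks per frame, normalized
#' coordinates in range, a positive frame rate.
#'
#' @param rec a [landmark_recording()].
#' @return `rec`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "landmark_recording"))
  for (f in c("x", "y", "z")) {
    m <- rec[[f]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("field '", f, "' must be a numeric matrix", call. = FALSE)
    if (ncol(m) != 21L)
      stop("each frame must contain exactly 21 landmarks; field '", f,
           "' has ", ncol(m), " columns", call. = FALSE)
    if (anyNA(m))
      stop("field '", f, "' contains missing values", call. = FALSE)
  }
  if (nrow(rec$x) != nrow(rec$y) || nrow(rec$x) != nrow(rec$z))
    stop("x, y, z must have the same number of frames", call. = FALSE)
  if (nrow(rec$x) < 1L) stop("recording has no frames", call. = FALSE)
  bad <- which(rec$x < 0 | rec$x > 1 | rec$y < 0 | rec$y > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("normalized coordinates outside [0, 1] at frame ", bad[1, 1] - 1L,
         ", landmark ", bad[1, 2] - 1L, call. = FALSE)
  if (!is.numeric(rec$fps) || length(rec$fps) != 1L || !is.finite(rec$fps) ||
      rec$fps < 1)
    stop("fps must be a single finite number >= 1", call. = FALSE)
  if (!is.null(rec$visible) &&
      (!is.logical(rec$visible) || !identical(dim(rec$visible), dim(rec$x))))
    stop("visible must be a logical matrix congruent with the coordinates",
         call. = FALSE)
  invisible(rec)
}

#' @rdname landmark_recording
#' @param rec a `landmark_recording`.
#' @export
n_frames <- function(rec) nrow(rec$y)

#' @rdname landmark_recording
#' @export
recording_duration <- function(rec) nrow(rec$y) / rec$fps

#' @export
print.landmark_recording <- function(x, ...) {
  cat("Hand-landmark recording\n")
  cat("  patient: ", x$patient_id, "  session: ", x$session, "\n", sep = "")
  cat(sprintf("  %d frames at %g fps (%.2f s), 21 landmarks\n",
              n_frames(x), x$fps, recording_duration(x)))
  if (!is.null(x$frame_width))
    cat(sprintf("  frame: %g x %g px\n", x$frame_width, x$frame_height))
  invisible(x)
}

#' Uniformly sampled one-dimensional signal
#'
#' The common carrier for both video-derived landmark trajectories and
#' accelerometer traces.
#'
#' @param samples numeric vector of sample values.
#' @param fs sampling rate in Hz (`> 0`).
#' @param units one of `"normalized_coordinate"`, `"pixel"`, `"cm_per_s2"`,
#'   `"arbitrary"`.
#' @param source one of `"video_landmark"`, `"accelerometer"`, `"synthetic"`.
#' @param landmark_id optional integer 0-20 identifying the landmark the
#'   signal was extracted from.
#' @return An object of class `"uni_signal"`.
#' @export
uni_signal <- function(samples, fs,
                       units = c("normalized_coordinate", "pixel",
                                 "cm_per_s2", "arbitrary"),
                       source = c("video_landmark", "accelerometer",
                                  "synthetic"),
                       landmark_id = NULL) {
  units <- match.arg(units)
  source <- match.arg(source)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample",
                                 call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (!is.null(landmark_id)) {
    landmark_id <- as.integer(landmark_id)
    if (landmark_id < 0L || landmark_id > 20L)
      stop("landmark_id must be in 0-20", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.numeric(fs), units = units,
                 source = source, landmark_id = landmark_id),
            class = "uni_signal")
}

#' @export
print.uni_signal <- function(x, ...) {
  cat(sprintf("uni_signal: %d samples at %g Hz (%.2f s), units %s, source %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$units, x$source))
  invisible(x)
}

#' @export
length.uni_signal <- function(x) length(x$samples)

# ---- interchange formats ----------------------------------------------------

#' Read a hand-landmark trajectory file
#'
#' Two equivalent dialects are supported. The CSV dialect is long-format, one
#' row per (frame, landmark), with header
#' `frame,time_s,landmark_id,x,y,z[,visible]`; recording metadata
#' (`patient_id`, `session`, `fps`, `frame_width`, `frame_height`) travels in
#' `# key: value` comment lines before the header. The JSON dialect is the
#' nested object written by [write_landmarks()]. Files are validated on read:
#' every frame must list each landmark id 0-20 exactly once, frame indices
#' must be strictly increasing, and x/y must lie in `[0, 1]`.
#'
#' @param path file to read.
#' @param dialect `"auto"` (by file extension), `"csv"` or `"json"`.
#' @return A validated [landmark_recording()].
#' @export
read_landmarks <- function(path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (dialect == "json") read_landmarks_json(path) else read_landmarks_csv(path)
}

read_landmarks_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0)
      meta[[trimws(substr(kv, 1, pos - 1))]] <- trimws(substr(kv, pos + 1, nchar(kv)))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "landmark_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  for (cn in need)
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in column '", cn, "'", call. = FALSE)
  frames <- unique(df$frame)
  if (is.unsorted(frames, strictly = TRUE))
    stop("frame indices are not strictly increasing", call. = FALSE)
  n <- length(frames)
  # id completeness per frame
  split_ids <- split(df$landmark_id, df$frame)
  for (k in seq_along(frames)) {
    ids <- sort(split_ids[[k]])
    if (length(ids) != 21L || !identical(as.integer(ids), 0:20)) {
      dup <- unique(split_ids[[k]][duplicated(split_ids[[k]])])
      if (length(dup))
        stop("frame ", frames[k], ": landmark id ", dup[1],
             " listed more than once", call. = FALSE)
      stop("frame ", frames[k], ": expected landmark ids 0-20 exactly once",
           call. = FALSE)
    }
  }
  ord <- order(df$frame, df$landmark_id)
  df <- df[ord, ]
  shape <- function(v) matrix(v, nrow = n, ncol = 21L, byrow = TRUE)
  fps <- if (!is.null(meta$fps)) as.numeric(meta$fps) else {
    if (n < 2L) stop("cannot infer fps from a single frame; ",
                     "add a '# fps: <Hz>' metadata line", call. = FALSE)
    tt <- df$time_s[!duplicated(df$frame)]
    (n - 1) / (tt[n] - tt[1])
  }
  vis <- if ("visible" %in% names(df)) shape(as.logical(df$visible)) else NULL
  landmark_recording(
    x = shape(df$x), y = shape(df$y), z = shape(df$z), fps = fps,
    patient_id = if (is.null(meta$patient_id)) "unknown" else meta$patient_id,
    session = if (is.null(meta$session)) "unspecified" else meta$session,
    frame_width = if (is.null(meta$frame_width)) NULL else as.numeric(meta$frame_width),
    frame_height = if (is.null(meta$frame_height)) NULL else as.numeric(meta$frame_height),
    visible = vis)
}

read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fr <- obj$frames
  if (is.null(fr)) stop("JSON recording lacks a 'frames' field", call. = FALSE)
  n <- length(fr)
  x <- y <- z <- matrix(NA_real_, n, 21L)
  vis <- NULL
  for (k in seq_len(n)) {
    f <- lapply(fr[[k]], unlist)
    ids <- as.integer(f$id)
    if (length(ids) != 21L || anyDuplicated(ids) || !setequal(ids, 0:20)) {
      dup <- unique(ids[duplicated(ids)])
      if (length(dup))
        stop("frame ", k - 1L, ": landmark id ", dup[1],
             " listed more than once", call. = FALSE)
      stop("frame ", k - 1L, ": expected landmark ids 0-20 exactly once",
           call. = FALSE)
    }
    ord <- order(ids)
    x[k, ] <- f$x[ord]; y[k, ] <- f$y[ord]; z[k, ] <- f$z[ord]
    if (!is.null(f$visible)) {
      if (is.null(vis)) vis <- matrix(TRUE, n, 21L)
      vis[k, ] <- as.logical(f$visible)[ord]
    }
  }
  scalar <- function(v, default = NULL) if (is.null(v)) default else unlist(v)
  landmark_recording(
    x = x, y = y, z = z, fps = as.numeric(scalar(obj$fps)),
    patient_id = scalar(obj$patient_id, "unknown"),
    session = as.character(scalar(obj$session, "unspecified")),
    frame_width = scalar(obj$frame_width),
    frame_height = scalar(obj$frame_height),
    visible = vis)
}

#' Write a hand-landmark trajectory file
#'
#' Inverse of [read_landmarks()]; the written file round-trips losslessly
#' (within double-precision formatting) in either dialect.
#'
#' @param rec a valid [landmark_recording()].
#' @param path output file.
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(rec, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  validate_recording(rec)
  n <- n_frames(rec)
  if (dialect == "json") {
    frames <- lapply(seq_len(n), function(k) {
      f <- list(id = 0:20, x = rec$x[k, ], y = rec$y[k, ], z = rec$z[k, ])
      if (!is.null(rec$visible)) f$visible <- rec$visible[k, ]
      f
    })
    obj <- list(patient_id = rec$patient_id, session = rec$session,
                fps = rec$fps, frame_width = rec$frame_width,
                frame_height = rec$frame_height, frames = frames)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    meta <- c(paste0("# patient_id: ", rec$patient_id),
              paste0("# session: ", rec$session),
              paste0("# fps: ", format(rec$fps, digits = 17)))
    if (!is.null(rec$frame_width))
      meta <- c(meta, paste0("# frame_width: ", rec$frame_width),
                paste0("# frame_height: ", rec$frame_height))
    df <- data.frame(
      frame = rep(seq_len(n) - 1L, each = 21L),
      time_s = rep((seq_len(n) - 1L) / rec$fps, each = 21L),
      landmark_id = rep(0:20, n),
      x = as.vector(t(rec$x)), y = as.vector(t(rec$y)), z = as.vector(t(rec$z)))
    if (!is.null(rec$visible)) df$visible <- as.vector(t(rec$visible))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(meta, con)
    utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a single-channel accelerometer trace
#'
#' Accepts either a two-column CSV with header `time_s,accel_cm_s2` (the
#' sampling rate is then inferred from the time stamps) or a one-column CSV of
#' acceleration values, in which case `fs` must be supplied.
#'
#' @param path CSV file.
#' @param fs sampling rate in Hz; required for one-column files, overrides
#'   the inferred rate otherwise.
#' @return A [uni_signal()] with units `cm_per_s2` and source
#'   `"accelerometer"`.
#' @export
read_accelerometer <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("accelerometer file is empty: ", path, call. = FALSE)
  if (all(c("time_s", "accel_cm_s2") %in% names(df))) {
    v <- df$accel_cm_s2
    if (is.null(fs)) {
      if (nrow(df) < 2L)
        stop("cannot infer fs from a single sample; supply fs", call. = FALSE)
      fs <- (nrow(df) - 1) / (df$time_s[nrow(df)] - df$time_s[1])
    }
  } else {
    if (ncol(df) != 1L)
      stop("expected columns time_s,accel_cm_s2 or a single value column",
           call. = FALSE)
    v <- df[[1]]
    if (is.null(fs))
      stop("fs must be supplied for a one-column accelerometer file",
           call. = FALSE)
  }
  if (!is.numeric(v) || anyNA(v))
    stop("non-numeric rows in accelerometer file", call. = FALSE)
  uni_signal(v, fs = fs, units = "cm_per_s2", source = "accelerometer")
}

#' Write an accelerometer trace as CSV
#'
#' @param sig a [uni_signal()].
#' @param path output CSV (`time_s,accel_cm_s2`).
#' @return `path`, invisibly.
#' @export
write_accelerometer <- function(sig, path) {
  stopifnot(inherits(sig, "uni_signal"))
  df <- data.frame(time_s = (seq_along(sig$samples) - 1) / sig$fs,
                   accel_cm_s2 = sig$samples)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- geometry / windowing ---------------------------------------------------

#' Trim policy for the analysis window
#'
#' Recordings often start and end with the hand outside its test posture
#' (lifting from / returning to the lap), so a few seconds are cut from both
#' ends and a fixed-length analysis window is taken from what remains. The
#' defaults (cut 2 s either side, analyse 10 s) match a 30-s bedside video
#' protocol.
#'
#' @param cut_start_s,cut_end_s seconds removed from the start / end (`>= 0`).
#' @param analysis_window_s length of the retained window in seconds (`> 0`).
#' @return An object of class `"trim_policy"`.
#' @export
trim_policy <- function(cut_start_s = 2, cut_end_s = 2, analysis_window_s = 10) {
  stopifnot(cut_start_s >= 0, cut_end_s >= 0, analysis_window_s > 0)
  structure(list(cut_start_s = cut_start_s, cut_end_s = cut_end_s,
                 analysis_window_s = analysis_window_s),
            class = "trim_policy")
}

#' Trim a recording to its analysis window
#'
#' Removes `cut_start_s` seconds from the start and `cut_end_s` from the end,
#' then keeps the first `analysis_window_s` seconds of the remainder. Refuses
#' (rather than silently truncating) when the recording is too short.
#'
#' @param rec a [landmark_recording()].
#' @param policy a [trim_policy()].
#' @return The trimmed `landmark_recording`
#'   (`round(analysis_window_s * fps)` frames).
#' @export
trim_recording <- function(rec, policy = trim_policy()) {
  validate_recording(rec)
  stopifnot(inherits(policy, "trim_policy"))
  n <- n_frames(rec)
  drop_start <- round(policy$cut_start_s * rec$fps)
  drop_end <- round(policy$cut_end_s * rec$fps)
  keep <- round(policy$analysis_window_s * rec$fps)
  avail <- n - drop_start - drop_end
  if (avail < keep)
    stop(sprintf(paste0("recording too short for trim policy: %.2f s remain ",
                        "after cutting, %.2f s required"),
                 avail / rec$fps, policy$analysis_window_s), call. = FALSE)
  idx <- seq.int(drop_start + 1L, drop_start + keep)
  rec$x <- rec$x[idx, , drop = FALSE]
  rec$y <- rec$y[idx, , drop = FALSE]
  rec$z <- rec$z[idx, , drop = FALSE]
  if (!is.null(rec$visible)) rec$visible <- rec$visible[idx, , drop = FALSE]
  rec
}

#' Extract one landmark's coordinate trace as a signal
#'
#' Videos of a resting or postural hand are usually framed so that tremor
#' shows as vertical motion, so the default axis is `y`.
#'
#' @param rec a [landmark_recording()].
#' @param landmark_id integer 0-20.
#' @param axis `"x"`, `"y"` (default) or `"z"`.
#' @return A [uni_signal()] sampled at the recording's frame rate.
#' @export
extract_axis <- function(rec, landmark_id, axis = c("y", "x", "z")) {
  axis <- match.arg(axis)
  landmark_id <- as.integer(landmark_id)
  if (is.na(landmark_id) || landmark_id < 0L || landmark_id > 20L)
    stop("landmark_id must be in 0-20", call. = FALSE)
  uni_signal(rec[[axis]][, landmark_id + 1L], fs = rec$fps,
             units = "normalized_coordinate", source = "video_landmark",
             landmark_id = landmark_id)
}

#' Convert a normalized coordinate to pixels
#'
#' @param value normalized coordinate(s) in `[0, 1]`.
#' @param frame_dim frame width (for x) or height (for y) in pixels.
#' @return `value * frame_dim`.
#' @export
to_pixels <- function(value, frame_dim) {
  if (any(frame_dim <= 0)) stop("frame_dim must be > 0", call. = FALSE)
  value * frame_dim
}
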