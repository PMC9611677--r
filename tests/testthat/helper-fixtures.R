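# Small in-code fixtures shared across test files.

# A compact valid recording with reproducible pseudo-random coordinates.
make_small_recording <- function(n = 40, fps = 20, seed = 42,
                                 with_visible = FALSE) {
  set.seed(seed)
  rec <- landmark_recording(
    x = matrix(runif(n * 21, 0.2, 0.8), n, 21),
    y = matrix(runif(n * 21, 0.2, 0.8), n, 21),
    z = matrix(rnorm(n * 21, 0, 0.05), n, 21),
    fps = fps, patient_id = "TST001", session = "before_medication",
    frame_width = 1920, frame_height = 1080,
    visible = if (with_visible) matrix(sample(c(TRUE, FALSE), n * 21,
                                              replace = TRUE, prob = c(.9, .1)),
                                       n, 21) else NULL)
  rec
}

# A recording whose landmark-0 y channel encodes the original frame index,
# so trimming can be checked by index arithmetic.
make_indexed_recording <- function(n, fps) {
  y <- matrix(0.5, n, 21)
  y[, 1] <- 0.1 + 0.8 * (seq_len(n) - 1) / n
  landmark_recording(x = matrix(0.5, n, 21), y = y,
                     z = matrix(0, n, 21), fps = fps)
}

# Pure-tone uni_signal helper.
tone_signal <- function(freq, amp = 1, fs = 180, dur = 10, phase = 0,
                        units = "arbitrary", source = "synthetic") {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  uni_signal(amp * sin(2 * pi * freq * t + phase), fs, units, source)
}

# Long-format landmark CSV text for schema-error tests.
landmark_csv_text <- function(frames_ids, fps = 30) {
  # frames_ids: list of integer vectors, the landmark ids listed per frame
  rows <- c(paste0("# fps: ", fps), "frame,time_s,landmark_id,x,y,z")
  for (k in seq_along(frames_ids)) {
    for (id in frames_ids[[k]]) {
      rows <- c(rows, sprintf("%d,%.6f,%d,0.5,0.5,0.0",
                              k - 1L, (k - 1L) / fps, id))
    }
  }
  rows
}
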