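# In-code fixtures shared across test files.

# Minimal frame table: all 17 AU channels present, zeros unless overridden
# via `...` (e.g. AU12_r = c(...), AU12_c = c(...)).
make_ft <- function(timestamps, confidence = NULL, success = NULL,
                    gaze_x = NULL, gaze_y = NULL, person_id = "test", ...) {
  n <- length(timestamps)
  df <- data.frame(
    frame_index = seq_len(n),
    timestamp = timestamps,
    confidence = confidence %||% rep(0.99, n),
    success = success %||% rep(TRUE, n)
  )
  for (au in sit_aus()) {
    df[[paste0(au, "_r")]] <- rep(0, n)
    df[[paste0(au, "_c")]] <- rep(0L, n)
  }
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df$gaze_x <- gaze_x %||% rep(0, n)
  df$gaze_y <- gaze_y %||% rep(0, n)
  frame_table(df, person_id = person_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-segment toy schedule used by slicing/summary tests.
toy_schedule <- function() {
  segment_schedule(data.frame(
    name = c("a", "b"),
    start = c(0, 10),
    end = c(10, 20),
    valence = c("neutral", "positive"),
    speaker = c("actress", "participant"),
    analyzed = TRUE
  ))
}

# Small labeled feature matrix with pure-noise features plus an optional
# perfectly separating column.
make_fm <- function(n_per_class = 6, p = 10, separator = FALSE, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  labels <- rep(c("ASD", "NT"), each = n_per_class)
  if (separator) X[, 1] <- ifelse(labels == "ASD", 1, 0) + rnorm(n, 0, 0.01)
  ids <- sprintf("s%02d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) X[i, ])
  names(rows) <- ids
  meta <- data.frame(subject_id = ids, label = labels,
                     gender = rep_len(c(0, 1), n), age = 30)
  feature_matrix(rows, meta, modality = "face")
}

# Scaled-down cohort settings used by end-to-end tests: short audio, low
# sampling rates, keeping runtimes inside the suite budget (sizes documented
# in the methods vignette).
fast_cohort_spec <- function(n_per_group, seed, preset = "paper",
                             fps = 15, ...) {
  cohort_spec(n_per_group = n_per_group, seed = seed, preset = preset,
              fps = fps, voice_duration = 2, audio_rate = 8000, ...)
}

fast_config <- function(seed) {
  run_config(seed = seed, mimicry_lags = c(0, 0.5, 1),
             grid = default_grid(c(4, 32), 8), n_trees = 150)
}

# all permutations of 1..n as rows (n small)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# public wrapper over the package's deterministic seed splitter
child_seed_pub <- function(seed, grp, i) {
  sitpipe:::child_seed(seed, paste0(grp, i))
}
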