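# Frame-table I/O and quality control for OpenFace 2.x per-frame output.

#' The 17 OpenFace intensity action units
#'
#' Names of the action units (AUs) for which OpenFace emits both an intensity
#' channel (`AU##_r`, 0-5) and a presence channel (`AU##_c`, 0/1).
#'
#' @return Character vector of 17 AU names (`"AU01"` ... `"AU45"`).
#' @export
sit_aus <- function() {
  c("AU01", "AU02", "AU04", "AU05", "AU06", "AU07", "AU09", "AU10",
    "AU12", "AU14", "AU15", "AU17", "AU20", "AU23", "AU25", "AU26", "AU45")
}

#' Construct a frame table
#'
#' A frame table is the per-person stream of tracking records: one row per
#' video frame with a timestamp, tracking confidence and success flag, the 17
#' AU intensity and presence channels, and the two gaze angles (radians,
#' averaged over both eyes, camera as reference).
#'
#' @param df Data frame with columns `frame_index`, `timestamp`, `confidence`,
#'   `success`, `<AU>_r` and `<AU>_c` for each AU in [sit_aus()], `gaze_x`,
#'   `gaze_y`.
#' @param person_id Identifier attached to the table.
#' @return An object of class `frame_table` (a data frame).
#' @export
frame_table <- function(df, person_id = "unknown") {
  req <- c("frame_index", "timestamp", "confidence", "success",
           paste0(sit_aus(), "_r"), paste0(sit_aus(), "_c"),
           "gaze_x", "gaze_y")
  missing_cols <- setdiff(req, names(df))
  assert_that(length(missing_cols) == 0,
              paste0("frame table missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df)[, req]
  validate_frame_table(df)
  structure(df, person_id = person_id,
            class = c("frame_table", "data.frame"))
}

validate_frame_table <- function(df) {
  if (nrow(df) > 1) {
    assert_that(all(diff(df$timestamp) > 0),
                "timestamps must be strictly increasing")
  }
  assert_that(all(df$confidence >= 0 & df$confidence <= 1),
              "confidence must lie in [0, 1]")
  pres <- unlist(df[paste0(sit_aus(), "_c")], use.names = FALSE)
  assert_that(all(pres %in% c(0, 1)), "AU presence channels must be 0/1")
  ints <- unlist(df[paste0(sit_aus(), "_r")], use.names = FALSE)
  assert_that(all(ints >= 0), "AU intensity channels must be non-negative")
  invisible(df)
}

#' @export
print.frame_table <- function(x, ...) {
  cat(sprintf("<frame_table> person %s: %d frames, %.1f-%.1f s\n",
              attr(x, "person_id"), nrow(x),
              if (nrow(x)) min(x$timestamp) else NA_real_,
              if (nrow(x)) max(x$timestamp) else NA_real_))
  invisible(x)
}

person_id <- function(ft) attr(ft, "person_id") %||% "unknown"

# Map this package's canonical column names to the OpenFace CSV dialect.
openface_name <- function(cols) {
  out <- cols
  out[out == "frame_index"] <- "frame"
  out[out == "gaze_x"] <- "gaze_angle_x"
  out[out == "gaze_y"] <- "gaze_angle_y"
  out
}

#' Read a per-frame tracking table in the OpenFace CSV dialect
#'
#' Parses an OpenFace 2.x per-frame output CSV. Header matching is
#' whitespace-tolerant (OpenFace pads column names with a space) and
#' order-independent; extra columns (landmarks, pose, ...) are ignored.
#'
#' @param path CSV file path.
#' @param person_id Identifier for the person; defaults to the file stem.
#' @return A [frame_table()].
#' @examples
#' ft <- actress_reference(default_schedule(), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_frame_table(ft, f)
#' ft2 <- read_frame_table(f, person_id = "actress")
#' @export
read_frame_table <- function(path, person_id = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  person_id <- person_id %||% tools::file_path_sans_ext(basename(path))
  raw <- utils::read.csv(path, check.names = FALSE)
  names(raw) <- trimws(names(raw))
  req <- c("timestamp", "confidence", "success",
           paste0(sit_aus(), "_r"), paste0(sit_aus(), "_c"),
           "gaze_angle_x", "gaze_angle_y")
  missing_cols <- setdiff(req, names(raw))
  assert_that(length(missing_cols) == 0,
              paste0("OpenFace table ", basename(path),
                     " missing required column(s): ",
                     paste(missing_cols, collapse = ", ")))
  df <- data.frame(
    frame_index = if ("frame" %in% names(raw)) raw$frame else seq_len(nrow(raw)),
    timestamp = raw$timestamp,
    confidence = raw$confidence,
    success = as.logical(raw$success > 0),
    check.names = FALSE
  )
  for (au in sit_aus()) {
    df[[paste0(au, "_r")]] <- raw[[paste0(au, "_r")]]
    df[[paste0(au, "_c")]] <- raw[[paste0(au, "_c")]]
  }
  df$gaze_x <- raw$gaze_angle_x
  df$gaze_y <- raw$gaze_angle_y
  frame_table(df, person_id = person_id)
}

#' Write a frame table as an OpenFace-dialect CSV
#'
#' @param ft A [frame_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(ft, path) {
  out <- as.data.frame(ft)
  out$success <- as.integer(out$success)
  names(out) <- openface_name(names(out))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop unreliably tracked frames
#'
#' Retains exactly the frames tracked successfully with confidence at or
#' above the threshold; order is preserved and the input is unmodified.
#'
#' @param ft A [frame_table()].
#' @param conf_threshold Confidence threshold in [0, 1]; default 0.75.
#' @return A filtered [frame_table()] (possibly empty).
#' @export
filter_frames <- function(ft, conf_threshold = 0.75) {
  assert_that(conf_threshold >= 0 && conf_threshold <= 1,
              "conf_threshold must lie in [0, 1]")
  keep <- ft$success & ft$confidence >= conf_threshold
  out <- ft[keep, , drop = FALSE]
  structure(as.data.frame(out), person_id = person_id(ft),
            class = c("frame_table", "data.frame"))
}

#' Participant-level tracking quality control
#'
#' A participant is included when more than the required fraction of frames
#' is retained by [filter_frames()] (default 0.90) and the mean tracking
#' confidence is at least `conf_min` (default 0.75).
#'
#' @param ft A [frame_table()] (unfiltered).
#' @param conf_threshold Per-frame confidence threshold passed to
#'   [filter_frames()].
#' @param tracked_min Minimum fraction of retained frames (default 0.90).
#' @param conf_min Minimum mean confidence (default 0.75).
#' @param confidence_scope Whether mean confidence is computed over `"all"`
#'   frames (default) or only `"retained"` frames.
#' @return One-row data frame: `person_id`, `fraction_tracked`,
#'   `mean_confidence`, `n_frames_total`, `n_frames_retained`, `included`.
#' @export
participant_qc <- function(ft, conf_threshold = 0.75, tracked_min = 0.90,
                           conf_min = 0.75,
                           confidence_scope = c("all", "retained")) {
  assert_that(nrow(ft) > 0, "participant_qc requires a non-empty frame table")
  confidence_scope <- match.arg(confidence_scope)
  kept <- filter_frames(ft, conf_threshold)
  mean_conf <- if (confidence_scope == "all") {
    mean(ft$confidence)
  } else if (nrow(kept)) mean(kept$confidence) else 0
  frac <- nrow(kept) / nrow(ft)
  data.frame(
    person_id = person_id(ft),
    fraction_tracked = frac,
    mean_confidence = mean_conf,
    n_frames_total = nrow(ft),
    n_frames_retained = nrow(kept),
    included = frac >= tracked_min && mean_conf >= conf_min,
    stringsAsFactors = FALSE
  )
}
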