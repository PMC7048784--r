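# Conversation structure of the simulated interaction and stream slicing.

VALENCES <- c("neutral", "positive", "negative", "none")
SPEAKERS <- c("actress", "participant", "both")

#' Construct a segment schedule
#'
#' A segment schedule is the timed structure of the simulated conversation:
#' named, pairwise-disjoint, half-open intervals `[start, end)` on the
#' post-warm-up clock, each tagged with a valence and the active speaker.
#'
#' @param segments Data frame with columns `name`, `start`, `end` (seconds),
#'   `valence` (one of neutral/positive/negative/none), `speaker` (one of
#'   actress/participant/both) and optionally `analyzed` (default `TRUE`).
#' @return An object of class `segment_schedule`.
#' @export
segment_schedule <- function(segments) {
  segments <- as.data.frame(segments)
  req <- c("name", "start", "end", "valence", "speaker")
  missing_cols <- setdiff(req, names(segments))
  assert_that(length(missing_cols) == 0,
              paste0("schedule missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  if (is.null(segments$analyzed)) segments$analyzed <- TRUE
  assert_that(all(segments$valence %in% VALENCES),
              paste0("unknown valence tag(s): ",
                     paste(setdiff(segments$valence, VALENCES), collapse = ", ")))
  assert_that(all(segments$speaker %in% SPEAKERS),
              paste0("unknown speaker tag(s): ",
                     paste(setdiff(segments$speaker, SPEAKERS), collapse = ", ")))
  assert_that(all(segments$end > segments$start),
              "each segment must have end > start")
  assert_that(!anyDuplicated(segments$name), "segment names must be unique")
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) > 1) {
    ok <- segments$start[-1] >= segments$end[-nrow(segments)]
    assert_that(all(ok),
                paste0("overlapping segments: ",
                       paste(segments$name[c(which(!ok), which(!ok) + 1)],
                             collapse = ", ")))
  }
  structure(segments, class = c("segment_schedule", "data.frame"))
}

#' Default conversation schedule
#'
#' Six analyzed segments on the post-warm-up clock: the actress talking about
#' table setting (neutral, 26 s), liked food (positive, 24 s) and disliked
#' food (negative, 26 s), each followed by about half a minute of participant
#' answer with the same valence. The warm-up precedes this clock and is not
#' analyzed, so it does not appear in the schedule.
#'
#' @return A [segment_schedule()] with segments `neutral_listen`,
#'   `neutral_answer`, `positive_listen`, `positive_answer`,
#'   `negative_listen`, `negative_answer`.
#' @export
default_schedule <- function() {
  segment_schedule(data.frame(
    name = c("neutral_listen", "neutral_answer", "positive_listen",
             "positive_answer", "negative_listen", "negative_answer"),
    start = c(0, 26, 56, 80, 110, 136),
    end = c(26, 56, 80, 110, 136, 166),
    valence = c("neutral", "neutral", "positive", "positive",
                "negative", "negative"),
    speaker = c("actress", "participant", "actress", "participant",
                "actress", "participant"),
    analyzed = TRUE,
    stringsAsFactors = FALSE
  ))
}

#' Load a segment schedule from a YAML config
#'
#' The config holds a `segments:` list of maps with keys `name`, `start`,
#' `end`, `valence`, `speaker` and optional `analyzed`. A `NULL` path or a
#' config without a `segments` entry yields [default_schedule()].
#'
#' @param path YAML file path, or `NULL` for the default schedule.
#' @return A [segment_schedule()].
#' @export
load_schedule <- function(path = NULL) {
  if (is.null(path)) return(default_schedule())
  assert_that(file.exists(path), paste0("schedule config not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$segments)) return(default_schedule())
  rows <- lapply(cfg$segments, function(s) {
    data.frame(name = s$name, start = s$start, end = s$end,
               valence = s$valence, speaker = s$speaker,
               analyzed = s$analyzed %||% TRUE, stringsAsFactors = FALSE)
  })
  segment_schedule(do.call(rbind, rows))
}

#' Write a segment schedule to a YAML config
#'
#' @param sched A [segment_schedule()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(sched, path) {
  segs <- lapply(seq_len(nrow(sched)), function(i) {
    list(name = sched$name[i], start = sched$start[i], end = sched$end[i],
         valence = sched$valence[i], speaker = sched$speaker[i],
         analyzed = sched$analyzed[i])
  })
  yaml::write_yaml(list(segments = segs), path)
  invisible(path)
}

#' Names of the analyzed conversation parts
#'
#' The analyzed segments of a schedule plus the `"whole"` aggregate
#' (the union of all analyzed segments); with the default schedule these are
#' the seven parts over which secondary features are computed.
#'
#' @param sched A [segment_schedule()].
#' @return Character vector of part names, ending with `"whole"`.
#' @export
schedule_parts <- function(sched) {
  c(sched$name[sched$analyzed], "whole")
}

#' Slice a frame table to one conversation part
#'
#' Returns the frames with `start <= timestamp < end` for the named segment.
#' The name `"whole"` returns the union of all analyzed segments.
#'
#' @param ft A [frame_table()].
#' @param sched A [segment_schedule()].
#' @param name Segment name or `"whole"`.
#' @return A [frame_table()] restricted to the part.
#' @export
slice_segment <- function(ft, sched, name) {
  if (identical(name, "whole")) {
    keep <- rep(FALSE, nrow(ft))
    for (i in which(sched$analyzed)) {
      keep <- keep | (ft$timestamp >= sched$start[i] & ft$timestamp < sched$end[i])
    }
  } else {
    i <- match(name, sched$name)
    assert_that(!is.na(i), paste0("unknown segment: ", name))
    keep <- ft$timestamp >= sched$start[i] & ft$timestamp < sched$end[i]
  }
  out <- ft[keep, , drop = FALSE]
  structure(as.data.frame(out), person_id = person_id(ft),
            class = c("frame_table", "data.frame"))
}
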