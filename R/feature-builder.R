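# Secondary feature matrices: per-subject face (715), gaze (85), voice (58)
# blocks and their combination.

CHANNEL_STAT_NAMES <- c("mean", "sd", "min", "max", "skew", "kurt")

#' Six summary statistics of a channel
#'
#' Order-invariant summary of one time series: mean, standard deviation
#' (n-1 denominator), minimum, maximum, skewness (biased moment ratio g1)
#' and excess kurtosis (g2 = m4/m2^2 - 3). For a constant series skewness
#' and kurtosis are undefined and returned as `NA`.
#'
#' @param series Numeric vector.
#' @return Named numeric vector `mean`, `sd`, `min`, `max`, `skew`, `kurt`.
#' @export
channel_stats <- function(series) {
  x <- series[!is.na(series)]
  out <- stats::setNames(rep(NA_real_, 6), CHANNEL_STAT_NAMES)
  if (!length(x)) return(out)
  out["mean"] <- mean(x)
  out["min"] <- min(x)
  out["max"] <- max(x)
  if (length(x) < 2) return(out)
  out["sd"] <- stats::sd(x)
  if (out["sd"] > 0) {
    out["skew"] <- e1071::skewness(x, type = 1)
    out["kurt"] <- e1071::kurtosis(x, type = 1)
  }
  out
}

part_channel_stats <- function(ft, sched, channels, prefix, short_names) {
  parts <- schedule_parts(sched)
  out <- numeric(0)
  for (part in parts) {
    sub <- slice_segment(ft, sched, part)
    for (k in seq_along(channels)) {
      s <- if (nrow(sub)) channel_stats(sub[[channels[k]]]) else
        stats::setNames(rep(NA_real_, 6), CHANNEL_STAT_NAMES)
      names(s) <- paste(prefix, part, short_names[k], CHANNEL_STAT_NAMES,
                        sep = ".")
      out <- c(out, s)
    }
  }
  out
}

#' Face feature vector (715 features)
#'
#' The six [channel_stats()] of each of the 17 AU intensity channels within
#' each of the seven conversation parts (six segments plus the whole
#' conversation): 17 x 6 x 7 = 714 values, plus gender. Column names are
#' deterministic (`face.<part>.<AU>.<stat>`), identical across subjects.
#'
#' @param ft A QC-passed, frame-filtered [frame_table()].
#' @param sched A [segment_schedule()].
#' @param gender 0/1 metadata value.
#' @return Named numeric vector of length 715; empty parts contribute `NA`s.
#' @export
build_face_features <- function(ft, sched, gender) {
  c(part_channel_stats(ft, sched, paste0(sit_aus(), "_r"), "face", sit_aus()),
    gender = as.numeric(gender))
}

#' Gaze feature vector (85 features)
#'
#' As [build_face_features()] on the two gaze-angle channels:
#' 2 x 6 x 7 = 84 values plus gender.
#'
#' @inheritParams build_face_features
#' @return Named numeric vector of length 85.
#' @export
build_gaze_features <- function(ft, sched, gender) {
  c(part_channel_stats(ft, sched, c("gaze_x", "gaze_y"), "gaze",
                       c("x", "y")),
    gender = as.numeric(gender))
}

#' Voice feature vector (58 features)
#'
#' The 57 fields of [voice_summary()] prefixed `voice.`, plus gender.
#'
#' @param vf Named vector from [voice_summary()].
#' @param gender 0/1 metadata value.
#' @return Named numeric vector of length 58.
#' @export
build_voice_features <- function(vf, gender) {
  stats::setNames(
    c(as.numeric(vf), as.numeric(gender)),
    c(paste0("voice.", names(vf)), "gender")
  )
}

#' Assemble a per-subject feature matrix
#'
#' Stacks per-subject feature vectors (rows) into a labeled feature matrix
#' carrying subject metadata and a per-column modality tag.
#'
#' @param rows Named list (subject_id -> named numeric vector); all vectors
#'   must share names.
#' @param metadata Data frame with columns `subject_id`, `label`
#'   (`"ASD"`/`"NT"`), `gender`, `age` (and optionally `severity`), one row
#'   per subject in `rows`.
#' @param modality Single modality tag for all columns, or `NULL` to derive
#'   per-column tags from the name prefix (`face.`/`gaze.`/`voice.`; the
#'   shared `gender` column is tagged `meta`).
#' @return Object of class `feature_matrix`: list with `X` (numeric matrix),
#'   `meta` (data frame) and `modality` (character per column).
#' @export
feature_matrix <- function(rows, metadata, modality = NULL) {
  assert_that(length(rows) > 0, "no feature rows")
  nm <- names(rows[[1]])
  ok <- vapply(rows, function(r) identical(names(r), nm), logical(1))
  assert_that(all(ok), "feature rows have inconsistent column names")
  assert_that(!anyDuplicated(nm), "feature column names must be unique")
  X <- do.call(rbind, lapply(rows, as.numeric))
  colnames(X) <- nm
  rownames(X) <- names(rows)
  metadata <- as.data.frame(metadata)
  assert_that(all(names(rows) %in% metadata$subject_id),
              "metadata missing some subjects")
  meta <- metadata[match(names(rows), metadata$subject_id), , drop = FALSE]
  assert_that(!any(is.na(meta$label)), "missing labels are not allowed")
  rownames(meta) <- NULL
  tags <- if (!is.null(modality)) {
    rep(modality, length(nm))
  } else {
    ifelse(startsWith(nm, "face."), "face",
           ifelse(startsWith(nm, "gaze."), "gaze",
                  ifelse(startsWith(nm, "voice."), "voice", "meta")))
  }
  structure(list(X = X, meta = meta, modality = tags),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(names(table(x$modality)), table(x$modality),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Combine modality feature blocks
#'
#' Column-wise concatenation of face, gaze and voice blocks for the same
#' subjects, keeping a single shared `gender` column. Any block may be
#' `NULL`. Missing values are left in place; imputation happens inside the
#' classifier's training folds, never here.
#'
#' @param face,gaze,voice `feature_matrix` objects (or `NULL`).
#' @return A combined `feature_matrix`.
#' @export
combine_features <- function(face = NULL, gaze = NULL, voice = NULL) {
  blocks <- Filter(Negate(is.null), list(face = face, gaze = gaze,
                                         voice = voice))
  assert_that(length(blocks) > 0, "no feature blocks given")
  ids <- lapply(blocks, function(b) b$meta$subject_id)
  assert_that(all(vapply(ids, identical, logical(1), ids[[1]])),
              "feature blocks cover different subjects")
  Xs <- list()
  tags <- character(0)
  gender_col <- NULL
  for (b in blocks) {
    keep <- colnames(b$X) != "gender"
    if (is.null(gender_col) && "gender" %in% colnames(b$X)) {
      gender_col <- b$X[, "gender", drop = FALSE]
    }
    Xs[[length(Xs) + 1]] <- b$X[, keep, drop = FALSE]
    tags <- c(tags, b$modality[keep])
  }
  X <- do.call(cbind, Xs)
  if (!is.null(gender_col)) {
    X <- cbind(X, gender_col)
    tags <- c(tags, "meta")
  }
  structure(list(X = X, meta = blocks[[1]]$meta, modality = tags),
            class = "feature_matrix")
}

#' Write a feature matrix to CSV
#'
#' Metadata columns first (`subject_id`, `label`, `gender`, `age`), then the
#' named feature columns.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  meta_cols <- intersect(c("subject_id", "label", "gender", "age", "severity"),
                         names(fm$meta))
  out <- cbind(fm$meta[meta_cols], as.data.frame(fm$X))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV written by [write_feature_matrix()].
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- intersect(c("subject_id", "label", "gender", "age", "severity"),
                         names(df))
  X <- as.matrix(df[setdiff(names(df), meta_cols)])
  rownames(X) <- df$subject_id
  rows <- lapply(seq_len(nrow(X)), function(i) X[i, ])
  names(rows) <- df$subject_id
  feature_matrix(rows, df[meta_cols])
}

#' Subset a feature matrix by modality
#'
#' @param fm A `feature_matrix`.
#' @param modality One of `"face"`, `"gaze"`, `"voice"`, `"all"`. The shared
#'   `gender` column (`meta` tag) is always retained.
#' @return A `feature_matrix` restricted to the modality.
#' @export
select_modality <- function(fm, modality = c("all", "face", "gaze", "voice")) {
  modality <- match.arg(modality)
  if (modality == "all") return(fm)
  keep <- fm$modality == modality | fm$modality == "meta"
  structure(list(X = fm$X[, keep, drop = FALSE], meta = fm$meta,
                 modality = fm$modality[keep]),
            class = "feature_matrix")
}
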