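# Part-wise action-unit biomarkers, social smiling, and facial mimicry.

# AUs tied to the elicited emotions: joy = AU6 (orbicularis oculi) + AU12
# (zygomaticus major); disgust = AU4 (corrugator supercilii) + AU9
# (levator labii).
MIMICRY_AUS <- c("AU06", "AU12", "AU04", "AU09")

#' Per-part AU occurrence and intensity
#'
#' For every analyzed conversation part (plus the `"whole"` aggregate) and
#' every requested AU, computes occurrence (mean of the binary presence
#' channel) and intensity (mean of the intensity channel) over the frames of
#' that part. Parts without frames yield `NA`, never zero.
#'
#' @param ft A QC-filtered [frame_table()].
#' @param sched A [segment_schedule()].
#' @param aus AU names (subset of [sit_aus()]); default all 17.
#' @return Long data frame: `person_id`, `segment`, `au`, `occurrence`,
#'   `intensity`.
#' @export
au_segment_summary <- function(ft, sched, aus = sit_aus()) {
  unknown <- setdiff(aus, sit_aus())
  assert_that(length(unknown) == 0,
              paste0("unknown AU(s): ", paste(unknown, collapse = ", ")))
  parts <- schedule_parts(sched)
  rows <- lapply(parts, function(part) {
    sub <- slice_segment(ft, sched, part)
    occ <- if (nrow(sub)) vapply(aus, function(a) mean(sub[[paste0(a, "_c")]]),
                                 numeric(1)) else rep(NA_real_, length(aus))
    int <- if (nrow(sub)) vapply(aus, function(a) mean(sub[[paste0(a, "_r")]]),
                                 numeric(1)) else rep(NA_real_, length(aus))
    data.frame(person_id = person_id(ft), segment = part, au = aus,
               occurrence = unname(occ), intensity = unname(int),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Social smiling over the whole conversation
#'
#' Occurrence and intensity of the two smile AUs (AU12 lip-corner puller,
#' AU6 cheek raiser) over the union of all analyzed segments.
#'
#' @param ft A QC-filtered [frame_table()].
#' @param sched A [segment_schedule()].
#' @return Named list: `AU12_occ`, `AU12_int`, `AU6_occ`, `AU6_int` (all `NA`
#'   when no frames fall in the analyzed parts).
#' @export
social_smiling <- function(ft, sched) {
  s <- au_segment_summary(ft, sched, aus = c("AU12", "AU06"))
  w <- s[s$segment == "whole", ]
  list(
    AU12_occ = w$occurrence[w$au == "AU12"],
    AU12_int = w$intensity[w$au == "AU12"],
    AU6_occ = w$occurrence[w$au == "AU06"],
    AU6_int = w$intensity[w$au == "AU06"]
  )
}

# Nearest-timestamp alignment of two series; tolerance in seconds.
# Returns index pairs (i into ta, j into tb).
align_nearest <- function(ta, tb, tol) {
  if (!length(ta) || !length(tb)) {
    return(list(i = integer(0), j = integer(0)))
  }
  j <- findInterval(ta, tb)
  j_lo <- pmax(j, 1L)
  j_hi <- pmin(j + 1L, length(tb))
  d_lo <- abs(ta - tb[j_lo])
  d_hi <- abs(ta - tb[j_hi])
  jj <- ifelse(d_lo <= d_hi, j_lo, j_hi)
  dd <- pmin(d_lo, d_hi)
  keep <- dd <= tol & j >= 0
  list(i = which(keep), j = jj[keep])
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' Time-shifted windowed mimicry correlation
#'
#' Quantifies how strongly a participant mirrors the actress's facial
#' activity in one AU. For each candidate lag, the participant's intensity
#' series is shifted back by the lag (mimicry is reactive: the participant
#' follows the actress), aligned to the actress's series by nearest timestamp
#' (tolerance half a frame period), and the overlap is split into
#' non-overlapping windows (default 10 s). Pearson correlations are computed
#' per window — windows with fewer than `min_samples` aligned samples or zero
#' variance on either side are skipped — and aggregated by the Fisher-z mean.
#' The score is the aggregate at the lag that maximizes it.
#'
#' @param participant,actress [frame_table()]s on a shared clock.
#' @param au AU name present in both tables.
#' @param window Window length in seconds (default 10).
#' @param lag_grid Candidate lags in seconds (default 0 to 3 s, step 0.25).
#' @param min_samples Minimum aligned samples per usable window (default 10).
#' @param channel `"intensity"` (default) or `"presence"`.
#' @return One-row data frame: `person_id`, `au`, `score`, `lag_selected`,
#'   `n_windows_used`. `score` is `NA` with `n_windows_used = 0` when no
#'   window is usable at any lag.
#' @export
mimicry_correlation <- function(participant, actress, au, window = 10,
                                lag_grid = seq(0, 3, by = 0.25),
                                min_samples = 10,
                                channel = c("intensity", "presence")) {
  channel <- match.arg(channel)
  suffix <- if (channel == "intensity") "_r" else "_c"
  col <- paste0(au, suffix)
  assert_that(col %in% names(participant) && col %in% names(actress),
              paste0("AU channel not present: ", au))
  ta <- actress$timestamp
  xa <- actress[[col]]
  tp <- participant$timestamp
  xp <- participant[[col]]
  period <- if (length(ta) > 1) stats::median(diff(ta)) else 1 / 30
  tol <- period / 2

  best <- list(score = NA_real_, lag = NA_real_, n = 0L)
  for (lag in lag_grid) {
    al <- align_nearest(ta, tp - lag, tol)
    if (length(al$i) < min_samples) next
    t0 <- ta[al$i[1]]
    win_id <- floor((ta[al$i] - t0) / window)
    zs <- c()
    for (w in unique(win_id)) {
      sel <- win_id == w
      if (sum(sel) < min_samples) next
      a <- xa[al$i[sel]]
      p <- xp[al$j[sel]]
      if (stats::sd(a) == 0 || stats::sd(p) == 0) next
      zs <- c(zs, fisher_z(stats::cor(a, p)))
    }
    if (!length(zs)) next
    score <- tanh(mean(zs))
    if (is.na(best$score) || score > best$score) {
      best <- list(score = score, lag = lag, n = length(zs))
    }
  }
  data.frame(person_id = person_id(participant), au = au,
             score = best$score, lag_selected = best$lag,
             n_windows_used = best$n, stringsAsFactors = FALSE)
}

#' Mimicry scores for the emotion-relevant AUs
#'
#' Convenience wrapper running [mimicry_correlation()] for the joy AUs
#' (AU6, AU12) and disgust AUs (AU4, AU9).
#'
#' @inheritParams mimicry_correlation
#' @param aus AU names (default the four emotion-relevant AUs).
#' @return Data frame with one row per AU.
#' @export
mimicry_scores <- function(participant, actress, aus = MIMICRY_AUS,
                           window = 10, lag_grid = seq(0, 3, by = 0.25)) {
  out <- do.call(rbind, lapply(aus, function(a) {
    mimicry_correlation(participant, actress, a, window = window,
                        lag_grid = lag_grid)
  }))
  rownames(out) <- NULL
  out
}
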