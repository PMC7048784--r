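# Gaze kinematics: angle statistics and finite-difference speed/acceleration.

#' Gaze kinematics features
#'
#' Computes, per axis (horizontal = `gaze_x`, vertical = `gaze_y`):
#' the mean raw angle; the mean absolute deviation from the participant's
#' median angle (median-centering absorbs differences in height and seating
#' position); the mean speed (first derivative); and the mean acceleration
#' (second derivative). Derivatives are absolute finite differences scaled by
#' the actual timestamp deltas, computed only across consecutive retained
#' frames whose gap does not exceed `max_gap_periods` nominal frame periods —
#' larger gaps (typically frames removed by quality control) break the
#' differencing chain rather than producing spurious velocities.
#'
#' @param ft A QC-filtered [frame_table()] with at least 3 frames.
#' @param max_gap_periods Maximum gap, in nominal frame periods (median
#'   timestamp delta), across which finite differences are taken. Default 2.
#' @return Data frame with rows `horizontal` and `vertical` and columns
#'   `person_id`, `axis`, `mean_angle`, `abs_dev_median`, `mean_speed`,
#'   `mean_accel` (radians, radians, rad/s, rad/s^2). All-`NA` rows when
#'   fewer than 3 usable frames.
#' @export
gaze_kinematics <- function(ft, max_gap_periods = 2) {
  axes <- c(horizontal = "gaze_x", vertical = "gaze_y")
  empty <- data.frame(
    person_id = person_id(ft), axis = names(axes),
    mean_angle = NA_real_, abs_dev_median = NA_real_,
    mean_speed = NA_real_, mean_accel = NA_real_,
    stringsAsFactors = FALSE
  )
  if (nrow(ft) < 3) return(empty)
  t <- ft$timestamp
  period <- stats::median(diff(t))
  out <- empty
  for (k in seq_along(axes)) {
    theta <- ft[[axes[k]]]
    out$mean_angle[k] <- mean(theta)
    out$abs_dev_median[k] <- mean(abs(theta - stats::median(theta)))
    dt <- diff(t)
    ok <- dt <= max_gap_periods * period
    v <- abs(diff(theta)) / dt           # speed on interval i -> i+1
    tv <- (t[-length(t)] + t[-1]) / 2    # speed located at interval midpoint
    v <- v[ok]
    tv <- tv[ok]
    chain <- ok                          # intervals usable for speed
    out$mean_speed[k] <- if (length(v)) mean(v) else NA_real_
    # acceleration from consecutive speed samples belonging to adjacent
    # intervals (no broken chain between them)
    if (length(v) >= 2) {
      adj <- which(diff(which(chain)) == 1)  # consecutive usable intervals
      if (length(adj)) {
        dv <- abs(v[adj + 1] - v[adj])
        dtv <- tv[adj + 1] - tv[adj]
        out$mean_accel[k] <- mean(dv / dtv)
      }
    }
  }
  out
}
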