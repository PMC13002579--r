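# linear-interpolated threshold crossing time between samples i and i+1
interp_cross <- function(t, x, i, thr) {
  if (i < 1) return(t[1])
  t[i] + (thr - x[i]) / (x[i + 1] - x[i]) * (t[i + 1] - t[i])
}

#' Detect the STS interval from trunk tilt
#'
#' The STS interval is the period during which the torso is tilted forward
#' by more than `threshold_deg` (default 10 deg) relative to the initial
#' seated posture, taken as the mean tilt over the first
#' `baseline_window_s` seconds. Crossing times are linearly interpolated
#' between samples. If the tilt exceeds the threshold in several disjoint
#' episodes (e.g. pre-motion fidgeting), the longest episode is used.
#'
#' @param tilt Trunk tilt series in degrees.
#' @param rate Sampling rate in Hz.
#' @param threshold_deg Onset threshold relative to seated baseline.
#' @param baseline_window_s Length of the initial window defining the
#'   seated posture.
#' @return Named numeric `c(onset, completion)` in seconds from series
#'   start.
#' @export
detect_sts_interval <- function(tilt, rate, threshold_deg = 10,
                                baseline_window_s = 0.5) {
  t <- (seq_along(tilt) - 1) / rate
  nb <- max(1, min(length(tilt), round(baseline_window_s * rate)))
  rel <- tilt - mean(tilt[seq_len(nb)])
  above <- rel > threshold_deg
  if (!any(above)) {
    sts_error("sts_no_motion_error",
              sprintf("tilt never exceeds %g deg above seated baseline",
                      threshold_deg))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ai <- which(runs$values)
  pick <- ai[which.max(runs$lengths[ai])]
  i0 <- starts[pick]
  i1 <- ends[pick]
  onset <- if (i0 == 1) t[1] else interp_cross(t, rel, i0 - 1, threshold_deg)
  completion <- if (i1 == length(rel)) t[length(rel)] else
    interp_cross(t, rel, i1, threshold_deg)
  c(onset = onset, completion = completion)
}

#' Detect seat-off from the seat reaction force
#'
#' Seat-off is the first time within the STS interval at which the seat
#' reaction force drops below `frac` (default 5%) of the seated baseline,
#' where the baseline is the mean force over the pre-onset window.
#'
#' @param force Seat reaction force series in newtons.
#' @param rate Sampling rate in Hz.
#' @param interval `c(onset, completion)` from [detect_sts_interval()].
#' @param frac Threshold as a fraction of baseline.
#' @return Seat-off time in seconds.
#' @export
detect_seat_off <- function(force, rate, interval, frac = 0.05) {
  t <- (seq_along(force) - 1) / rate
  pre <- force[t < interval[1]]
  if (length(pre) == 0) {
    sts_error("sts_segmentation_error", "no pre-onset force baseline window")
  }
  baseline <- mean(pre)
  inside <- t >= interval[1] & t <= interval[2]
  idx <- which(inside & force < frac * baseline)
  if (length(idx) == 0) {
    sts_error("sts_seatoff_error",
              sprintf("force never drops below %g%% of baseline within the STS interval",
                      100 * frac))
  }
  unname(t[idx[1]])
}

#' Segment an STS trial into four phases
#'
#' Five ordered boundaries are derived from kinematics alone:
#' \describe{
#'   \item{t0}{STS onset: first upward 10 deg tilt crossing.}
#'   \item{t1}{time of peak forward tilt (clamped to the midpoint of
#'     `(t0, t2)` if the peak falls at or after seat-off).}
#'   \item{t2}{seat-off: force below 5% of the seated baseline.}
#'   \item{t3}{tilt half-decay: first time after seat-off at which tilt
#'     falls below threshold + 0.5 x (peak - threshold); clamped to the
#'     midpoint of `(t2, t4)` if undefined.}
#'   \item{t4}{STS completion: last downward 10 deg crossing.}
#' }
#' The four phases are the half-open intervals `[t_k, t_{k+1})`.
#'
#' @param tilt,force Kinematic series (deg, N) at a common rate.
#' @param rate Sampling rate in Hz.
#' @param threshold_deg,baseline_window_s Passed to
#'   [detect_sts_interval()].
#' @param force_frac Passed to [detect_seat_off()].
#' @return Object of class `sts_segments` with `boundaries` (named t0..t4)
#'   and `durations` (4 phase lengths, s).
#' @export
segment_phases <- function(tilt, force, rate, threshold_deg = 10,
                           force_frac = 0.05, baseline_window_s = 0.5) {
  interval <- detect_sts_interval(tilt, rate, threshold_deg, baseline_window_s)
  t2 <- detect_seat_off(force, rate, interval, force_frac)
  t <- (seq_along(tilt) - 1) / rate
  nb <- max(1, min(length(tilt), round(baseline_window_s * rate)))
  rel <- tilt - mean(tilt[seq_len(nb)])

  inside <- t >= interval[1] & t <= interval[2]
  peak_i <- which(inside)[which.max(rel[inside])]
  t1 <- t[peak_i]
  peak <- rel[peak_i]
  if (t1 >= t2) t1 <- (interval[1] + t2) / 2

  thr3 <- threshold_deg + 0.5 * (peak - threshold_deg)
  t3 <- NA_real_
  cand <- which(t > t2 & t <= interval[2])
  for (i in cand) {
    if (i > 1 && rel[i - 1] >= thr3 && rel[i] < thr3) {
      t3 <- interp_cross(t, rel, i - 1, thr3)
      break
    }
  }
  if (is.na(t3) || t3 <= t2 || t3 >= interval[2]) {
    t3 <- (t2 + interval[2]) / 2
  }

  b <- c(t0 = unname(interval[1]), t1 = unname(t1), t2 = t2, t3 = t3,
         t4 = unname(interval[2]))
  if (any(diff(b) <= 0)) {
    sts_error("sts_segmentation_error",
              paste("phase boundaries not strictly increasing:",
                    paste(sprintf("%.3f", b), collapse = " ")))
  }
  structure(list(boundaries = b, durations = unname(diff(b))),
            class = "sts_segments")
}

#' @export
print.sts_segments <- function(x, ...) {
  cat("<sts_segments> boundaries (s):",
      paste(sprintf("%s=%.3f", names(x$boundaries), x$boundaries),
            collapse = " "), "\n")
  invisible(x)
}

#' Segment a trial object
#'
#' Convenience wrapper applying [segment_phases()] to a trial's tilt and
#' force channels.
#'
#' @param trial An `sts_trial`.
#' @param ... Passed to [segment_phases()].
#' @return An `sts_segments` object.
#' @export
segment_trial <- function(trial, ...) {
  segment_phases(trial$tilt, trial$force, trial$kin_rate, ...)
}
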