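# Fourth-order Butterworth designs for the activation chain.
butter_filters <- function(rate, band = c(40, 400), lowpass = 4, order = 4) {
  nyq <- rate / 2
  list(bandpass = signal::butter(order, band / nyq, type = "pass"),
       lowpass = signal::butter(order, lowpass / nyq, type = "low"),
       order = order)
}

#' Zero-phase (forward-backward) IIR filtering with reflection padding
#'
#' Applies the filter forwards then backwards, which squares the magnitude
#' response and cancels the phase response, so envelope peaks are not
#' delayed. Edges are extended by odd reflection before filtering to
#' suppress startup transients on short trials.
#'
#' @param flt A filter object with `b`/`a` coefficients (e.g. from
#'   [signal::butter()]).
#' @param x Numeric vector.
#' @return Filtered vector, same length as `x`.
#' @export
zero_phase_filter <- function(flt, x) {
  n <- length(x)
  np <- min(n - 1, 3 * (max(length(flt$b), length(flt$a)) - 1) * 3)
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filter(flt$b, flt$a, xp))
  y <- rev(as.numeric(signal::filter(flt$b, flt$a, rev(y))))
  y[(np + 1):(np + n)]
}

#' Convert raw EMG to muscle-activation envelopes
#'
#' The standard surface-EMG activation chain: zero-phase fourth-order
#' Butterworth band-pass (40-400 Hz), full-wave rectification, zero-phase
#' fourth-order Butterworth low-pass (4 Hz), then clipping of residual
#' negative low-pass ripple to zero.
#'
#' @param emg Numeric matrix (samples x channels) or vector, in mV.
#' @param rate Sampling rate in Hz; must exceed 800 Hz so the 400 Hz band
#'   edge is below Nyquist.
#' @param band,lowpass,order Filter parameters; defaults are the analysis
#'   protocol.
#' @return Nonnegative envelope, same shape as `emg`.
#' @export
emg_to_activation <- function(emg, rate, band = c(40, 400), lowpass = 4,
                              order = 4) {
  if (rate <= 2 * max(band)) {
    sts_error("sts_rate_error",
              sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                      rate, max(band)))
  }
  vec <- is.null(dim(emg))
  x <- as.matrix(emg)
  if (anyNA(x) || any(!is.finite(x))) {
    sts_error("sts_data_error", "EMG contains missing or non-finite samples")
  }
  flt <- butter_filters(rate, band, lowpass, order)
  out <- apply(x, 2, function(ch) {
    pmax(zero_phase_filter(flt$lowpass,
                           abs(zero_phase_filter(flt$bandpass, ch))), 0)
  })
  out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  if (vec) out[, 1] else out
}

#' Attach activation envelopes to a trial
#'
#' @param trial An `sts_trial` with raw EMG.
#' @param ... Passed to [emg_to_activation()].
#' @return The trial with an `activation` matrix (samples x 8, mV) added.
#' @export
process_trial <- function(trial, ...) {
  if (is.null(trial$emg)) {
    sts_error("sts_data_error", "trial has no raw EMG to process")
  }
  trial$activation <- emg_to_activation(trial$emg, trial$emg_rate, ...)
  trial
}

#' Pooled RMS muscle activation over an interval
#'
#' Root-mean-square of the activation envelope pooled over all channels
#' within the given time interval (typically STS onset to completion).
#'
#' @param activation Samples x channels envelope matrix (mV).
#' @param rate Sampling rate of `activation` in Hz.
#' @param interval Length-2 numeric `c(start, end)` in seconds, or `NULL`
#'   for the whole series.
#' @return Scalar RMS in mV.
#' @export
trial_rms <- function(activation, rate, interval = NULL) {
  a <- as.matrix(activation)
  if (!is.null(interval)) {
    t <- (seq_len(nrow(a)) - 1) / rate
    keep <- t >= interval[1] & t < interval[2]
    if (!any(keep)) {
      sts_error("sts_segment_error", "RMS interval contains no samples")
    }
    a <- a[keep, , drop = FALSE]
  }
  if (nrow(a) == 0) {
    sts_error("sts_segment_error", "RMS interval contains no samples")
  }
  sqrt(mean(a^2))
}
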