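#' Canonical ordering of the 100 trial features
#'
#' Four segment durations first, then EMG features in muscle-major,
#' segment-minor order with (mean, sd, peak-to-peak) innermost:
#' `dur_seg1..dur_seg4, TA_seg1_mean, TA_seg1_sd, TA_seg1_ptp, TA_seg2_mean,
#' ..., ES_seg4_ptp`. Total 4 + 3 x 8 x 4 = 100.
#'
#' @return Character vector of 100 feature names.
#' @export
feature_names <- function() {
  emg <- as.vector(vapply(sts_muscles(), function(m) {
    as.vector(vapply(1:4, function(s) {
      paste0(m, "_seg", s, "_", c("mean", "sd", "ptp"))
    }, character(3)))
  }, character(12)))
  c(paste0("dur_seg", 1:4), emg)
}

#' Extract the 100-dimensional feature vector of one trial
#'
#' Per STS segment: one temporal feature (segment duration, s) and, per
#' muscle, the mean, sample standard deviation and peak-to-peak amplitude
#' (mV) of the activation envelope -- 25 features per segment, 100 per
#' trial.
#'
#' @param activation Samples x 8 activation envelope matrix (mV).
#' @param segments An `sts_segments` object or numeric vector of five
#'   boundary times (s). Segments are half-open `[t_k, t_{k+1})`.
#' @param rate Sampling rate of `activation` in Hz.
#' @return Named numeric vector of length 100 in [feature_names()] order.
#' @export
extract_features <- function(activation, segments, rate) {
  b <- if (inherits(segments, "sts_segments")) segments$boundaries
       else as.numeric(segments)
  if (length(b) != 5 || any(diff(b) <= 0)) {
    sts_error("sts_feature_error", "need five strictly increasing boundaries")
  }
  a <- as.matrix(activation)
  if (ncol(a) != 8) {
    sts_error("sts_feature_error", "activation must have 8 channels")
  }
  t <- (seq_len(nrow(a)) - 1) / rate
  out <- numeric(100)
  names(out) <- feature_names()
  out[1:4] <- diff(b)
  for (s in 1:4) {
    idx <- which(t >= b[s] & t < b[s + 1])
    if (length(idx) < 2) {
      sts_error("sts_feature_error",
                sprintf("segment %d has %d envelope samples (need >= 2)",
                        s, length(idx)))
    }
    seg <- a[idx, , drop = FALSE]
    for (m in 1:8) {
      base <- 4 + (m - 1) * 12 + (s - 1) * 3
      v <- seg[, m]
      out[base + 1] <- mean(v)
      out[base + 2] <- stats::sd(v)
      out[base + 3] <- max(v) - min(v)
    }
  }
  out
}

#' Fit per-feature standardization statistics
#'
#' Means and sample standard deviations are estimated on the training
#' trials only and later applied unchanged to test trials, so no test
#' information leaks into the scaling. Zero-variance features get sd 1
#' (with a warning), which maps them to constant 0.
#'
#' @param x Numeric matrix or data frame of training feature vectors (rows
#'   = trials).
#' @return Object of class `sts_standardizer` with `mean` and `sd`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    sts_error("sts_feature_error", "need at least 2 training vectors")
  }
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  zero <- sd == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s); sd set to 1", sum(zero)))
    sd[zero] <- 1
  }
  structure(list(mean = mu, sd = sd), class = "sts_standardizer")
}

#' Apply (or invert) fitted standardization
#'
#' @param x Feature matrix or single named vector.
#' @param stats An `sts_standardizer` from [fit_standardizer()].
#' @return Standardized values, same shape as `x`.
#' @export
apply_standardizer <- function(x, stats) {
  if (is.null(dim(x))) {
    (x - stats$mean) / stats$sd
  } else {
    sweep(sweep(as.matrix(x), 2, stats$mean), 2, stats$sd, "/")
  }
}

#' @rdname apply_standardizer
#' @export
invert_standardizer <- function(x, stats) {
  if (is.null(dim(x))) {
    x * stats$sd + stats$mean
  } else {
    sweep(sweep(as.matrix(x), 2, stats$sd, "*"), 2, stats$mean, "+")
  }
}

#' Generate, preprocess, segment and featurize a dataset in one stream
#'
#' Runs the full per-trial chain (raw-EMG synthesis, activation-envelope
#' extraction, phase segmentation, feature extraction) one trial at a time,
#' so full-scale datasets never need to be held in memory. Also records
#' per-trial QC: the worst phase-boundary recovery error against the
#' generator's ground truth (in kinematic samples) and the pooled
#' activation RMS over the STS interval.
#'
#' @param config A [generator_config()].
#' @param manifest Optional manifest subset (default
#'   `simulate_manifest(config)`).
#' @param verbose Print progress every 100 trials.
#' @return List of class `sts_feature_set`: `features` (data frame:
#'   trial_id, participant, the four control bits, cond_id, 100 feature
#'   columns), `qc` (trial_id, boundary_err_samples, rms_mv), and `config`.
#' @export
extract_dataset_features <- function(config = generator_config(),
                                     manifest = NULL, verbose = FALSE) {
  if (is.null(manifest)) manifest <- simulate_manifest(config)
  n <- nrow(manifest)
  feat <- matrix(NA_real_, n, 100, dimnames = list(NULL, feature_names()))
  qc_err <- numeric(n)
  qc_rms <- numeric(n)
  for (i in seq_len(n)) {
    tr <- generate_trial(unlist(manifest[i, control_variables()]),
                         manifest$participant[i], config,
                         seed = manifest$seed[i])
    tr <- process_trial(tr)
    seg <- segment_trial(tr)
    feat[i, ] <- extract_features(tr$activation, seg, tr$emg_rate)
    gt <- tr$ground_truth$boundaries
    qc_err[i] <- max(abs(seg$boundaries - gt)) * config$kin_rate
    qc_rms[i] <- trial_rms(tr$activation, tr$emg_rate,
                           seg$boundaries[c(1, 5)])
    if (verbose && i %% 100 == 0) {
      message(sprintf("featurized %d/%d trials", i, n))
    }
  }
  features <- cbind(
    manifest[, c("trial_id", "participant", control_variables(), "cond_id")],
    as.data.frame(feat))
  rownames(features) <- NULL
  structure(list(
    features = features,
    qc = data.frame(trial_id = manifest$trial_id,
                    boundary_err_samples = qc_err, rms_mv = qc_rms),
    config = config
  ), class = "sts_feature_set")
}

#' @export
print.sts_feature_set <- function(x, ...) {
  cat("<sts_feature_set>", nrow(x$features), "trials x 100 features;",
      length(unique(x$features$participant)), "participant(s)\n")
  cat(sprintf("  boundary recovery: %.1f%% of trials within 2 kinematic samples\n",
              100 * mean(x$qc$boundary_err_samples <= 2)))
  cat(sprintf("  pooled STS activation RMS: %.3f mV (mean)\n",
              mean(x$qc$rms_mv)))
  invisible(x)
}

#' Feature-matrix columns holding the 100 features
#'
#' @param features A feature data frame from [extract_dataset_features()].
#' @return Numeric matrix (trials x 100) with trial ids as rownames.
#' @export
feature_matrix <- function(features) {
  m <- as.matrix(features[, feature_names()])
  rownames(m) <- features$trial_id
  m
}
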