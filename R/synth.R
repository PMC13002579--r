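#' Configuration for the synthetic sit-to-stand trial generator
#'
#' The generator emulates the statistical structure of the chair-assisted STS
#' recordings the downstream analysis assumes: per-participant sets of trials
#' under all 16 control conditions, with condition-dependent modulation of
#' muscle-activation amplitude (speed variables, concentrated on TA/SO/VM/RF)
#' and of phase durations (timing variables), plus trial-to-trial noise.
#'
#' Each trial contains a trunk-tilt trace that rises through the 10 deg
#' onset threshold once, peaks, and falls back; a seat reaction force that
#' decays sigmoidally through 5% of its seated baseline at seat-off; and
#' eight EMG channels built as a band-limited (40-400 Hz) zero-mean carrier
#' amplitude-modulated by a nonnegative envelope of per-phase Gaussian
#' bursts.
#'
#' @param n_participants Number of virtual participants (default 6).
#' @param trials_per_condition Trials recorded per condition (default 10).
#' @param emg_rate,kin_rate Sampling rates in Hz for EMG and for the
#'   tilt/force kinematic channels.
#' @param rise_s,fall_s Mean tilt rise (onset-to-peak) and fall
#'   (peak-to-completion) durations in seconds, before condition shifts.
#' @param rise_sd,fall_sd Trial-to-trial SD (s) of the rise/fall durations.
#' @param pre_s,post_s Quiet sitting before tilt onset begins and standing
#'   after completion (s).
#' @param peak_tilt_deg Population mean peak trunk tilt (deg);
#'   `peak_tilt_participant_sd` and `peak_tilt_trial_sd` give between- and
#'   within-participant SDs.
#' @param seatoff_frac Position of seat-off between peak tilt and the tilt
#'   half-decay landmark (0-1).
#' @param burst_amp 8 x 4 matrix of baseline burst amplitudes (mV), rows in
#'   [sts_muscles()] order, columns = STS phases 1-4.
#' @param effect_amp Named list (one element per control variable) of
#'   8-vectors: multiplicative envelope-amplitude factors applied when that
#'   variable is in the fast state.
#' @param effect_dur Named list of length-2 vectors `c(rise, fall)`: additive
#'   duration shifts in seconds applied when the variable is fast.
#' @param amp_cv Lognormal CV of each burst amplitude (independent per
#'   muscle and phase); `trial_cv` an additional whole-trial amplitude CV;
#'   `participant_cv` the CV of per-participant, per-muscle gain factors.
#' @param weight_kg_mean,weight_kg_sd Participant body-mass distribution;
#'   the seated force baseline is body weight in newtons.
#' @param force_width_s Time constant (s) of the sigmoidal force decay at
#'   seat-off; `force_noise_frac` white-noise SD as a fraction of baseline.
#' @param tilt_noise_deg White sensor-noise SD (deg) applied to tilt before
#'   a 0.25 s moving-average smoothing.
#' @param seed Base seed; all per-participant and per-trial seeds are
#'   derived from it deterministically.
#' @return A list of class `sts_generator_config`.
#' @export
generator_config <- function(n_participants = 6,
                             trials_per_condition = 10,
                             emg_rate = 2000,
                             kin_rate = 100,
                             rise_s = 1.05,
                             fall_s = 1.55,
                             rise_sd = 0.10,
                             fall_sd = 0.12,
                             pre_s = 1.2,
                             post_s = 0.6,
                             peak_tilt_deg = 38,
                             peak_tilt_participant_sd = 2.5,
                             peak_tilt_trial_sd = 1.5,
                             seatoff_frac = 0.4,
                             burst_amp = default_burst_amplitudes(),
                             effect_amp = default_amplitude_effects(),
                             effect_dur = default_duration_effects(),
                             amp_cv = 0.15,
                             trial_cv = 0.08,
                             participant_cv = 0.15,
                             weight_kg_mean = 75.0,
                             weight_kg_sd = 12.2,
                             force_width_s = 0.03,
                             force_noise_frac = 0.003,
                             tilt_noise_deg = 0.05,
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    trials_per_condition = as.integer(trials_per_condition),
    emg_rate = emg_rate, kin_rate = kin_rate,
    rise_s = rise_s, fall_s = fall_s, rise_sd = rise_sd, fall_sd = fall_sd,
    pre_s = pre_s, post_s = post_s,
    peak_tilt_deg = peak_tilt_deg,
    peak_tilt_participant_sd = peak_tilt_participant_sd,
    peak_tilt_trial_sd = peak_tilt_trial_sd,
    seatoff_frac = seatoff_frac,
    burst_amp = burst_amp, effect_amp = effect_amp, effect_dur = effect_dur,
    amp_cv = amp_cv, trial_cv = trial_cv, participant_cv = participant_cv,
    weight_kg_mean = weight_kg_mean, weight_kg_sd = weight_kg_sd,
    force_width_s = force_width_s, force_noise_frac = force_noise_frac,
    tilt_noise_deg = tilt_noise_deg,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "sts_generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$emg_rate <= 0 || cfg$kin_rate <= 0) {
    sts_error("sts_config_error", "sampling rates must be positive")
  }
  if (cfg$trials_per_condition < 1 || cfg$n_participants < 1) {
    sts_error("sts_config_error",
              "need at least one participant and one trial per condition")
  }
  if (cfg$rise_s <= 0 || cfg$fall_s <= 0 || cfg$pre_s <= 0 || cfg$post_s < 0) {
    sts_error("sts_config_error", "trial durations must be positive")
  }
  for (v in control_variables()) {
    fac <- cfg$effect_amp[[v]]
    if (length(fac) != 8 || any(fac <= 0)) {
      sts_error("sts_config_error",
                "amplitude effect factors must be 8 positive values per variable")
    }
  }
  if (!is.matrix(cfg$burst_amp) || !all(dim(cfg$burst_amp) == c(8, 4)) ||
      any(cfg$burst_amp < 0)) {
    sts_error("sts_config_error", "burst_amp must be a nonnegative 8 x 4 matrix")
  }
  invisible(cfg)
}

#' Baseline burst amplitudes per muscle and STS phase
#'
#' Amplitudes (mV) follow the usual STS recruitment sequence: TA and ES lead
#' during forward lean, the knee extensors (VM/RF/VL) dominate around
#' seat-off and the rising phase, SO ramps up late for push-off and
#' stabilization.
#'
#' @return 8 x 4 numeric matrix (muscles x phases), dimnames set.
#' @export
default_burst_amplitudes <- function() {
  m <- rbind(
    TA = c(0.25, 0.30, 0.10, 0.05),
    SO = c(0.05, 0.10, 0.25, 0.30),
    VM = c(0.10, 0.35, 0.40, 0.15),
    RF = c(0.10, 0.30, 0.35, 0.12),
    VL = c(0.08, 0.30, 0.38, 0.14),
    ST = c(0.15, 0.10, 0.20, 0.10),
    GM = c(0.08, 0.20, 0.28, 0.12),
    ES = c(0.30, 0.25, 0.15, 0.10)
  )
  colnames(m) <- paste0("seg", 1:4)
  m
}

#' Default amplitude effects of the fast control levels
#'
#' Fast seat speeds provide inertial assistance: the knee/ankle agonists
#' (TA, VM, RF) drop while SO rises for postural stabilization. Timing
#' variables carry only weak amplitude effects; their signature is mainly in
#' the phase durations.
#'
#' @return Named list of four 8-vectors of multiplicative factors.
#' @export
default_amplitude_effects <- function() {
  base <- stats::setNames(rep(1, 8), sts_muscles())
  fwd_speed <- base; fwd_speed[c("TA", "SO", "VM", "RF")] <- c(0.78, 1.25, 0.85, 0.95)
  up_speed <- base; up_speed[c("TA", "SO", "VM", "RF", "VL")] <- c(0.85, 1.22, 0.72, 0.78, 0.95)
  fwd_timing <- base; fwd_timing[c("TA", "VM")] <- c(0.95, 0.97)
  up_timing <- base; up_timing[c("SO", "RF")] <- c(0.96, 0.97)
  list(fwd_speed = fwd_speed, up_speed = up_speed,
       fwd_timing = fwd_timing, up_timing = up_timing)
}

#' Default phase-duration effects of the fast control levels
#'
#' Immediate (0 s wait) seat motion shortens the movement phase it assists;
#' fast speeds shorten it slightly further.
#'
#' @return Named list of `c(rise, fall)` shifts in seconds.
#' @export
default_duration_effects <- function() {
  list(fwd_speed = c(rise = -0.05, fall = 0),
       up_speed = c(rise = 0, fall = -0.08),
       fwd_timing = c(rise = -0.12, fall = 0),
       up_timing = c(rise = 0, fall = -0.15))
}

as_condition <- function(condition) {
  if (inherits(condition, "sts_condition")) return(condition)
  if (is.data.frame(condition)) condition <- unlist(condition[1, control_variables()])
  if (!is.null(names(condition))) condition <- condition[control_variables()]
  if (length(condition) != 4 || anyNA(condition)) {
    sts_error("sts_config_error", "condition must supply the four control bits")
  }
  control_condition(condition[[1]], condition[[2]], condition[[3]], condition[[4]])
}

# per-participant latent parameters, reproducible from (config$seed, id)
participant_params <- function(participant_id, config) {
  with_seed(mix_seed(config$seed, 104729, participant_id), {
    list(
      muscle_gain = exp(stats::rnorm(8, 0, config$participant_cv) -
                          config$participant_cv^2 / 2),
      weight_kg = max(45, stats::rnorm(1, config$weight_kg_mean,
                                       config$weight_kg_sd)),
      peak_tilt = stats::rnorm(1, config$peak_tilt_deg,
                               config$peak_tilt_participant_sd)
    )
  })
}

#' Generate one synthetic STS trial
#'
#' @param condition A condition from [control_condition()], a named 0/1
#'   vector, or one row of [control_conditions()].
#' @param participant_id Integer participant index.
#' @param config A [generator_config()].
#' @param seed Integer seed for this trial's randomness.
#' @param include_emg If `FALSE`, skip raw-EMG carrier synthesis (tilt,
#'   force and the ground-truth envelope are still produced); useful when
#'   only kinematics or envelopes are needed.
#' @return An `sts_trial`: list with `emg` (n x 8 matrix, mV; `NULL` when
#'   `include_emg = FALSE`), `tilt` (deg), `force` (N), sampling rates,
#'   `condition`, and `ground_truth` (phase boundaries in seconds, the
#'   noise-free envelope at EMG rate, realized burst amplitudes, and the
#'   trial's latent geometry).
#' @export
generate_trial <- function(condition, participant_id, config = generator_config(),
                           seed = config$seed, include_emg = TRUE) {
  validate_generator_config(config)
  condition <- as_condition(condition)
  pp <- participant_params(participant_id, config)
  bits <- as.numeric(condition)
  names(bits) <- control_variables()

  with_seed(seed, {
    # latent geometry ------------------------------------------------------
    rise <- config$rise_s + sum(vapply(control_variables(), function(v)
      bits[[v]] * config$effect_dur[[v]][["rise"]], numeric(1))) +
      stats::rnorm(1, 0, config$rise_sd)
    fall <- config$fall_s + sum(vapply(control_variables(), function(v)
      bits[[v]] * config$effect_dur[[v]][["fall"]], numeric(1))) +
      stats::rnorm(1, 0, config$fall_sd)
    rise <- max(rise, 0.5)
    fall <- max(fall, 0.6)
    peak_tilt <- min(max(pp$peak_tilt +
                           stats::rnorm(1, 0, config$peak_tilt_trial_sd), 25), 55)
    lean_start <- config$pre_s + stats::runif(1, -0.1, 0.1)

    t_peak <- lean_start + rise
    onset <- lean_start + rise * acos(1 - 20 / peak_tilt) / pi
    half_thr <- 10 + 0.5 * (peak_tilt - 10)
    u3 <- fall * acos(10 / peak_tilt) / pi        # peak -> half-decay
    t3 <- t_peak + u3
    completion <- t_peak + fall * acos(20 / peak_tilt - 1) / pi
    seat_off <- t_peak + config$seatoff_frac * u3
    boundaries <- c(t0 = onset, t1 = t_peak, t2 = seat_off,
                    t3 = t3, t4 = completion)
    duration <- lean_start + rise + fall + config$post_s

    # kinematics -----------------------------------------------------------
    tk <- seq(0, duration, by = 1 / config$kin_rate)
    tilt <- numeric(length(tk))
    up <- tk >= lean_start & tk <= t_peak
    dn <- tk > t_peak & tk <= t_peak + fall
    tilt[up] <- peak_tilt * 0.5 * (1 - cos(pi * (tk[up] - lean_start) / rise))
    tilt[dn] <- peak_tilt * 0.5 * (1 + cos(pi * (tk[dn] - t_peak) / fall))
    noise <- stats::rnorm(length(tk), 0, config$tilt_noise_deg)
    k <- min(25, length(tk))
    tilt <- tilt + as.numeric(stats::filter(noise, rep(1 / k, k), sides = 2,
                                            circular = TRUE))

    baseline_n <- pp$weight_kg * 9.81
    tc <- seat_off - config$force_width_s * log(19)
    force <- baseline_n * stats::plogis(-(tk - tc) / config$force_width_s)
    force <- pmax(force + stats::rnorm(length(tk), 0,
                                       config$force_noise_frac * baseline_n), 0)

    # activation envelope --------------------------------------------------
    te <- seq(0, duration, by = 1 / config$emg_rate)
    amp_factor <- rep(1, 8)
    for (v in control_variables()) {
      if (bits[[v]] == 1) amp_factor <- amp_factor * config$effect_amp[[v]]
    }
    trial_gain <- exp(stats::rnorm(1, 0, config$trial_cv) - config$trial_cv^2 / 2)
    burst_noise <- matrix(exp(stats::rnorm(32, 0, config$amp_cv) -
                                config$amp_cv^2 / 2), 8, 4)
    burst_amps <- config$burst_amp * amp_factor * pp$muscle_gain *
      trial_gain * burst_noise
    dimnames(burst_amps) <- dimnames(config$burst_amp)

    centers <- (boundaries[-5] + boundaries[-1]) / 2
    widths <- 0.22 * diff(boundaries)
    envelope <- matrix(0, length(te), 8, dimnames = list(NULL, sts_muscles()))
    for (k in 1:4) {
      bump <- exp(-(te - centers[k])^2 / (2 * widths[k]^2))
      envelope <- envelope + outer(bump, burst_amps[, k])
    }

    # raw EMG: band-limited carrier, unit mean rectified amplitude ---------
    emg <- NULL
    if (include_emg) {
      flt <- butter_filters(config$emg_rate)
      emg <- matrix(0, length(te), 8, dimnames = list(NULL, sts_muscles()))
      for (m in 1:8) {
        carrier <- zero_phase_filter(flt$bandpass, stats::rnorm(length(te)))
        carrier <- carrier / mean(abs(carrier))
        emg[, m] <- carrier * envelope[, m]
      }
    }

    structure(list(
      trial_id = sprintf("P%02d_C%02d_S%d", participant_id,
                         condition_id(bits[1], bits[2], bits[3], bits[4]), seed),
      participant_id = as.integer(participant_id),
      condition = condition,
      emg = emg, emg_rate = config$emg_rate,
      tilt = tilt, force = force, kin_rate = config$kin_rate,
      duration = duration,
      ground_truth = list(boundaries = boundaries, envelope = envelope,
                          burst_amps = burst_amps, rise = rise, fall = fall,
                          peak_tilt = peak_tilt, force_baseline = baseline_n)
    ), class = "sts_trial")
  })
}

#' @export
print.sts_trial <- function(x, ...) {
  cat("<sts_trial>", x$trial_id, "\n")
  cat("  participant:", x$participant_id,
      " condition:", paste(as.integer(x$condition), collapse = ""), "\n")
  cat(sprintf("  duration %.2f s; EMG %s at %g Hz; kinematics at %g Hz\n",
              x$duration, if (is.null(x$emg)) "absent" else "8 ch", x$emg_rate,
              x$kin_rate))
  cat("  boundaries:",
      paste(sprintf("%.2f", x$ground_truth$boundaries), collapse = " "), "s\n")
  invisible(x)
}

#' Plan a full synthetic dataset
#'
#' Builds the trial manifest for `n_participants x 16 conditions x
#' trials_per_condition` trials. Condition block order is randomized per
#' participant under the config seed; each row carries the derived seed that
#' [generate_trial()] uses, so any single trial can be regenerated without
#' materializing the rest.
#'
#' @param config A [generator_config()].
#' @return Data frame with columns `trial_id`, `participant`, the four
#'   control bits, `cond_id`, `trial`, `seed`.
#' @export
simulate_manifest <- function(config = generator_config()) {
  conds <- control_conditions()
  rows <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    order_p <- with_seed(mix_seed(config$seed, 555, p), sample.int(16))
    blocks <- lapply(order_p, function(ci) {
      cbind(conds[rep(ci, config$trials_per_condition), ],
            trial = seq_len(config$trials_per_condition))
    })
    block <- do.call(rbind, blocks)
    block$participant <- p
    rows[[p]] <- block
  }
  man <- do.call(rbind, rows)
  man$seed <- mapply(function(p, ci, tr) mix_seed(config$seed, p, ci, tr),
                     man$participant, man$cond_id, man$trial)
  man$trial_id <- sprintf("P%02d_C%02d_T%02d", man$participant, man$cond_id,
                          man$trial)
  rownames(man) <- NULL
  man[, c("trial_id", "participant", control_variables(), "cond_id",
          "trial", "seed")]
}

#' Generate a complete synthetic dataset in memory
#'
#' Materializes every trial of the manifest. At the default scale (960
#' trials with raw EMG) this needs several hundred MB; for full-scale
#' analyses prefer the streaming [extract_dataset_features()], which
#' processes one trial at a time.
#'
#' @param config A [generator_config()].
#' @param include_emg Passed to [generate_trial()].
#' @return List of class `sts_dataset` with elements `trials` (list of
#'   `sts_trial`) and `manifest`.
#' @export
generate_dataset <- function(config = generator_config(), include_emg = TRUE) {
  man <- simulate_manifest(config)
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    trials[[i]] <- generate_trial(
      unlist(man[i, control_variables()]), man$participant[i], config,
      seed = man$seed[i], include_emg = include_emg)
    trials[[i]]$trial_id <- man$trial_id[i]
  }
  names(trials) <- man$trial_id
  structure(list(trials = trials, manifest = man), class = "sts_dataset")
}

#' Write a dataset to per-trial CSV files
#'
#' One `<trial_id>_emg.csv` (time_s + eight emg_* columns, mV) and one
#' `<trial_id>_kin.csv` (time_s, tilt_deg, force_N) per trial, plus
#' `manifest.csv` and `ground_truth.csv` (true phase-boundary times).
#'
#' @param dataset An `sts_dataset` from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- dataset$manifest
  man$path <- file.path(dir, paste0(man$trial_id, "_emg.csv"))
  gt <- NULL
  for (tr in dataset$trials) {
    if (!is.null(tr$emg)) {
      emg <- data.frame(time_s = seq(0, tr$duration, by = 1 / tr$emg_rate),
                        tr$emg, check.names = FALSE)
      names(emg)[-1] <- paste0("emg_", sts_muscles())
      utils::write.csv(emg, file.path(dir, paste0(tr$trial_id, "_emg.csv")),
                       row.names = FALSE)
    }
    kin <- data.frame(time_s = seq(0, tr$duration, by = 1 / tr$kin_rate),
                      tilt_deg = tr$tilt, force_N = tr$force)
    utils::write.csv(kin, file.path(dir, paste0(tr$trial_id, "_kin.csv")),
                     row.names = FALSE)
    gt <- rbind(gt, data.frame(trial_id = tr$trial_id,
                               t(tr$ground_truth$boundaries)))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read one trial back from CSV files
#'
#' @param trial_id Trial identifier used by [write_dataset()].
#' @param dir Directory holding the CSV files.
#' @param condition Optional condition bits to attach.
#' @return An `sts_trial` (without generator ground truth).
#' @export
read_trial_csv <- function(trial_id, dir, condition = NULL) {
  emg <- utils::read.csv(file.path(dir, paste0(trial_id, "_emg.csv")))
  kin <- utils::read.csv(file.path(dir, paste0(trial_id, "_kin.csv")))
  emg_rate <- round(1 / stats::median(diff(emg$time_s)))
  kin_rate <- round(1 / stats::median(diff(kin$time_s)))
  structure(list(
    trial_id = trial_id, participant_id = NA_integer_,
    condition = if (is.null(condition)) NULL else as_condition(condition),
    emg = as.matrix(emg[, -1]), emg_rate = emg_rate,
    tilt = kin$tilt_deg, force = kin$force_N, kin_rate = kin_rate,
    duration = max(kin$time_s), ground_truth = NULL
  ), class = "sts_trial")
}
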