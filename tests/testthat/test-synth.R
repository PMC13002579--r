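test_that("control space enumerates 16 distinct 4-bit conditions", {
  cc <- control_conditions()
  expect_equal(nrow(cc), 16)
  expect_equal(nrow(unique(cc[, control_variables()])), 16)
  expect_true(all(unlist(cc[, control_variables()]) %in% 0:1))
  expect_equal(condition_id(cc$fwd_speed, cc$up_speed, cc$fwd_timing,
                            cc$up_timing), cc$cond_id)
  expect_error(control_condition(2, 0, 0, 0), class = "sts_config_error")
})

test_that("trial generation is seed-deterministic", {
  cfg <- generator_config(seed = 3L)
  a <- generate_trial(control_condition(1, 1, 0, 0), 2, cfg, seed = 99)
  b <- generate_trial(control_condition(1, 1, 0, 0), 2, cfg, seed = 99)
  expect_identical(a$emg, b$emg)
  expect_identical(a$tilt, b$tilt)
  expect_identical(a$ground_truth$boundaries, b$ground_truth$boundaries)
  d <- generate_trial(control_condition(1, 1, 0, 0), 2, cfg, seed = 100)
  expect_false(identical(a$emg, d$emg))
})

test_that("generated trials honor the measurement structure", {
  tr <- demo_trial()
  gt <- tr$ground_truth
  expect_true(all(diff(gt$boundaries) > 0))
  expect_true(all(tr$force >= 0))
  expect_true(all(gt$envelope >= 0))
  expect_identical(colnames(gt$envelope), sts_muscles())
  # tilt crosses the 10 deg threshold exactly once up and once down
  rel <- tr$tilt - mean(tr$tilt[1:round(0.5 * tr$kin_rate)])
  crossings <- diff(rel > 10)
  expect_equal(sum(crossings == 1), 1)
  expect_equal(sum(crossings == -1), 1)
  # force decays below 5% of its seated baseline between onset and completion
  t <- (seq_along(tr$force) - 1) / tr$kin_rate
  baseline <- mean(tr$force[t < gt$boundaries[1]])
  inside <- t >= gt$boundaries[1] & t <= gt$boundaries[5]
  expect_true(any(tr$force[inside] < 0.05 * baseline))
})

test_that("dataset counts follow participants x 16 conditions x trials", {
  man <- simulate_manifest(generator_config(n_participants = 6,
                                            trials_per_condition = 10))
  expect_equal(nrow(man), 960)
  expect_equal(as.vector(table(man$participant)), rep(160, 6))
  expect_equal(as.vector(table(man$participant, man$cond_id)),
               rep(10, 96))
  expect_true(all(man$seed >= 0 & man$seed < 2^31))

  ds <- generate_dataset(generator_config(n_participants = 1,
                                          trials_per_condition = 1,
                                          seed = 2L), include_emg = FALSE)
  expect_length(ds$trials, 16)

  m1 <- simulate_manifest(generator_config(seed = 1L))
  m2 <- simulate_manifest(generator_config(seed = 2L))
  expect_identical(dim(m1), dim(m2))
  expect_false(identical(m1$trial_id, m2$trial_id))
  expect_identical(m1, simulate_manifest(generator_config(seed = 1L)))
})

test_that("null effect configuration leaves burst amplitudes condition-free", {
  ones <- lapply(default_amplitude_effects(), function(v) { v[] <- 1; v })
  zero <- lapply(default_duration_effects(), function(v) { v[] <- 0; v })
  cfg <- generator_config(effect_amp = ones, effect_dur = zero, seed = 9L)
  peak <- function(cond, s) {
    max(generate_trial(cond, 1, cfg, seed = s,
                       include_emg = FALSE)$ground_truth$burst_amps)
  }
  a <- vapply(1:100, function(i) peak(control_condition(1, 1, 1, 1), 100 + i),
              numeric(1))
  b <- vapply(1:100, function(i) peak(control_condition(0, 0, 0, 0), 900 + i),
              numeric(1))
  expect_gt(stats::ks.test(a, b)$p.value, 0.01)
})

test_that("a configured VM amplitude factor is recovered from envelopes", {
  ea <- default_amplitude_effects()
  ea$up_speed[] <- 1
  ea$up_speed["VM"] <- 0.7
  zero <- lapply(default_duration_effects(), function(v) { v[] <- 0; v })
  cfg <- generator_config(effect_amp = ea, effect_dur = zero, seed = 4L)
  seg_mean <- function(cond, s) {
    tr <- generate_trial(cond, 1, cfg, seed = s, include_emg = FALSE)
    b <- tr$ground_truth$boundaries
    te <- seq(0, tr$duration, by = 1 / cfg$emg_rate)
    mean(tr$ground_truth$envelope[te >= b[3] & te < b[4], "VM"])
  }
  fast <- vapply(1:100, function(i) seg_mean(control_condition(0, 1, 0, 0),
                                             1000 + i), numeric(1))
  slow <- vapply(1:100, function(i) seg_mean(control_condition(0, 0, 0, 0),
                                             5000 + i), numeric(1))
  expect_equal(mean(fast) / mean(slow), 0.7, tolerance = 0.08)
  # log-scale regression recovers the configured log-factor within 2 SE
  fit <- stats::lm(log(c(fast, slow)) ~ rep(1:0, each = 100))
  est <- stats::coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - log(0.7)), 2 * est["Std. Error"])
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(emg_rate = 0), class = "sts_config_error")
  expect_error(generator_config(trials_per_condition = 0),
               class = "sts_config_error")
  bad <- default_amplitude_effects()
  bad$fwd_speed[1] <- -1
  expect_error(generator_config(effect_amp = bad), class = "sts_config_error")
})

test_that("trials round-trip through the CSV interface", {
  dir <- tempfile("sts_ds_")
  on.exit(unlink(dir, recursive = TRUE))
  ds <- generate_dataset(generator_config(n_participants = 1,
                                          trials_per_condition = 1,
                                          seed = 6L))
  ds$trials <- ds$trials[1:2]
  ds$manifest <- ds$manifest[1:2, ]
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  tr0 <- ds$trials[[1]]
  tr1 <- read_trial_csv(tr0$trial_id, dir)
  expect_equal(unname(tr1$emg), unname(tr0$emg), tolerance = 1e-6)
  expect_equal(tr1$tilt, tr0$tilt, tolerance = 1e-6)
  expect_equal(tr1$kin_rate, tr0$kin_rate)
})
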