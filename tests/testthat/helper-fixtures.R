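# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# one default-scale trial with activation + segmentation attached
demo_trial <- function() {
  if (is.null(.fixtures$trial)) {
    cfg <- generator_config(seed = 11L)
    tr <- generate_trial(control_condition(1, 0, 1, 0), 1, cfg, seed = 42)
    tr <- process_trial(tr)
    tr$segments <- segment_trial(tr)
    .fixtures$trial <- tr
  }
  .fixtures$trial
}

# small end-to-end dataset: 1 participant, 4 trials per condition
demo_pipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    .fixtures$pipeline <- run_sts_pipeline(
      generator_config(n_participants = 1, trials_per_condition = 4,
                       seed = 7L))
  }
  .fixtures$pipeline
}

# well-separated two-class toy problem for classifier tests
toy_classes <- function(n = 30, p = 5, delta = 3, seed = 5) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[, 1] <- x[, 1] + delta * y
  x <- scale(x)
  list(x = x, y = y)
}
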