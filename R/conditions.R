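#' Muscle channel order
#'
#' Fixed recording order of the eight surface-EMG channels: tibialis anterior
#' (TA), soleus (SO), vastus medialis (VM), rectus femoris (RF), vastus
#' lateralis (VL), semitendinosus (ST), gluteus medius (GM), erector spinae
#' (ES). All multichannel containers in the package use this order.
#'
#' @return Character vector of the eight muscle abbreviations.
#' @export
sts_muscles <- function() {
  c("TA", "SO", "VM", "RF", "VL", "ST", "GM", "ES")
}

#' Names of the four chair control variables
#'
#' The assistive chair is commanded by four binary variables: forward and
#' upward seat speed (1 = fast, 0.22 m/s; 0 = slow, 0.08 m/s) and forward and
#' upward motion onset timing (1 = immediate, 0 s wait; 0 = delayed, 0.3 s
#' wait after torso-tilt onset).
#'
#' @return Character vector of length four.
#' @export
control_variables <- function() {
  c("fwd_speed", "up_speed", "fwd_timing", "up_timing")
}

#' Construct a single control condition
#'
#' @param fwd_speed,up_speed,fwd_timing,up_timing Binary (0/1) states; 1 is
#'   the "fast" level of each variable.
#' @return Named integer vector of length 4 with class `sts_condition`.
#' @export
control_condition <- function(fwd_speed, up_speed, fwd_timing, up_timing) {
  bits <- c(fwd_speed = fwd_speed, up_speed = up_speed,
            fwd_timing = fwd_timing, up_timing = up_timing)
  if (!all(bits %in% c(0, 1))) {
    sts_error("sts_config_error", "control condition bits must be 0 or 1")
  }
  structure(as.integer(bits), names = names(bits), class = "sts_condition")
}

#' Enumerate the full control space
#'
#' All 2^4 = 16 combinations of the four binary chair control variables, in a
#' fixed canonical order (`fwd_speed` varying slowest).
#'
#' @return Data frame with columns `cond_id` (1..16) and the four control
#'   bits.
#' @export
control_conditions <- function() {
  grid <- expand.grid(up_timing = 0:1, fwd_timing = 0:1,
                      up_speed = 0:1, fwd_speed = 0:1)
  grid <- grid[, rev(seq_along(grid))]
  data.frame(cond_id = seq_len(nrow(grid)), grid)
}

#' Map condition bits to the canonical condition id
#'
#' @param fwd_speed,up_speed,fwd_timing,up_timing Binary states, vectorized.
#' @return Integer id(s) in 1..16 matching [control_conditions()].
#' @export
condition_id <- function(fwd_speed, up_speed, fwd_timing, up_timing) {
  as.integer(8 * fwd_speed + 4 * up_speed + 2 * fwd_timing + up_timing + 1)
}

#' Physical levels of the control variables
#'
#' @return Data frame listing, for each control variable, the physical value
#'   of its slow (0) and fast (1) level.
#' @export
condition_levels <- function() {
  data.frame(
    variable = control_variables(),
    unit = c("m/s", "m/s", "s wait", "s wait"),
    slow = c(0.08, 0.08, 0.3, 0.3),
    fast = c(0.22, 0.22, 0.0, 0.0)
  )
}

# classed error helper shared by all modules
sts_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "sts_error")))
}

# deterministic seed mixing; keeps every derived seed in [0, 2^31 - 2]
mix_seed <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 7919 + as.numeric(x) + 1) %% 2147483563
  as.integer(s)
}

# run code under a local RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
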