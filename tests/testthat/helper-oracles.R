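# Independent oracles used across the suite.

# polar form of the vector from -> to via complex arithmetic
oracle_polar <- function(from, to) {
  z <- complex(real = to[1] - from[1], imaginary = to[2] - from[2])
  list(amp = Mod(z), angle = Arg(z) * 180 / pi)
}

# Mann-Whitney U by direct pair counting
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided p for U by exhaustive enumeration of group assignments
oracle_u_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) oracle_u(pooled[ix], pooled[-ix]))
  mu <- n1 * length(y) / 2
  obs <- oracle_u(x, y)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# generator configurations for the canonical noise-free regimes
zero_noise_gen <- function(lambda, gain_1 = 0.85, gain_2 = 1) {
  gen_params(
    cd_gain = lambda, motor_gain_1 = gain_1, motor_gain_2 = gain_2,
    motor_noise_cv = 0, memory_noise_deg = 0, invalid_rate = 0,
    subject_sd = 0, dat_coupling = c(lambda = 0, gain = 0),
    laterality_delta = c(lambda = 0, gain = 0)
  )
}

# minimal single-trial fixation table in the package's column layout
fixation_table <- function(points, quadrant = "UR", t2_index = 2,
                           condition = "Baseline", trial_id = 1L,
                           subject_id = "S01") {
  n <- nrow(points)
  tibble::tibble(
    trial_id = trial_id, subject_id = subject_id, condition = condition,
    quadrant = quadrant, t2_index = as.integer(t2_index),
    fixation = seq_len(n), x = points[, 1], y = points[, 2],
    onset_ms = seq_len(n) * 300, offset_ms = seq_len(n) * 300 + 250
  )
}
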