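#' Generative-model parameters for synthetic double-saccade cohorts
#'
#' The generator implements the corollary-discharge (CD) gain model: the
#' oculomotor system executes a first saccade with endpoint `E1`, internally
#' registers a displacement `lambda * E1`, and aims the second saccade at the
#' remembered second target minus that registered displacement. `lambda = 1`
#' is veridical CD; `lambda > 1` ("amplified" CD, the regime inferred for
#' Parkinson patients) biases second saccades inward, toward the initial
#' fixation; `lambda < 1` ("diminished" CD) biases them outward.
#'
#' @param cd_gain CD gain per group; a named vector `c(control = , pd = )` or
#'   a single value used for both groups.
#' @param motor_gain_1,motor_gain_2 Multiplicative motor gains of the first
#'   and second saccade (< 1 produces hypometria).
#' @param motor_noise_cv Coefficient of variation of isotropic Gaussian
#'   endpoint noise relative to the intended saccade amplitude
#'   (signal-dependent motor noise).
#' @param memory_noise_deg SD (degrees) of additive Gaussian noise on the
#'   remembered second-target position; applied in the Memory condition only.
#' @param invalid_rate Probability that a trial's first saccade is misdirected
#'   into a random other quadrant (feeds the preprocessing exclusion rule).
#' @param subject_sd Between-subject SD of the CD gain and the motor gains.
#' @param dat_coupling Named vector `c(lambda = , gain = )`: slopes linking a
#'   patient's (cohort-centred) lower-hemisphere mean striatal binding ratio
#'   to the CD gain and the motor gains. The default negative `lambda` slope
#'   means lower dopamine-transporter binding gives a more amplified CD.
#' @param laterality_delta Named vector `c(lambda = , gain = )`: additive
#'   change applied on trials whose targets lie on the side of the patient's
#'   predominant motor symptoms.
#' @param dat_mean_pd,dat_mean_control,dat_sd Mean striatal specific binding
#'   ratio distribution per group (controls carry no scan by default and get
#'   `NA` unless `simulate_control_dat = TRUE`).
#' @param dat_asymmetry Binding deficit of the hemisphere contralateral to
#'   the symptomatic body side (SBR units).
#' @param updrs_mean,updrs_sd Motor MDS-UPDRS distribution for patients.
#' @param symptom_side_prob Probabilities of left / right / symmetric
#'   predominant motor symptoms among patients.
#' @param polar_angle,eccentricity_deg,t2_spacing_deg Task geometry passed to
#'   [make_layout()].
#' @param simulate_control_dat Give control subjects synthetic scans too.
#'
#' @return A list of class `gen_params`.
#' @export
gen_params <- function(cd_gain = c(control = 1.0, pd = 1.1),
                       motor_gain_1 = 0.9, motor_gain_2 = 1.0,
                       motor_noise_cv = 0.05, memory_noise_deg = 1.0,
                       invalid_rate = 0.06, subject_sd = 0.05,
                       dat_coupling = c(lambda = -0.2, gain = 0.1),
                       laterality_delta = c(lambda = 0.05, gain = -0.03),
                       dat_mean_pd = 1.5, dat_mean_control = 2.5, dat_sd = 0.3,
                       dat_asymmetry = 0.3,
                       updrs_mean = 37, updrs_sd = 20,
                       symptom_side_prob = c(left = 8, right = 4, symmetric = 2) / 14,
                       polar_angle = 45, eccentricity_deg = 16,
                       t2_spacing_deg = 2.4,
                       simulate_control_dat = FALSE) {
  if (length(cd_gain) == 1) cd_gain <- c(control = unname(cd_gain), pd = unname(cd_gain))
  stopifnot(
    all(cd_gain > 0), motor_gain_1 > 0, motor_gain_2 > 0,
    motor_noise_cv >= 0, memory_noise_deg >= 0,
    invalid_rate >= 0, invalid_rate < 1, subject_sd >= 0,
    all(c("lambda", "gain") %in% names(dat_coupling)),
    all(c("lambda", "gain") %in% names(laterality_delta)),
    abs(sum(symptom_side_prob) - 1) < 1e-8
  )
  structure(as.list(environment()), class = "gen_params")
}

other_quadrants <- function(q) setdiff(c("UR", "UL", "LR", "LL"), q)

#' Simulate one double-saccade trial under the CD-gain model
#'
#' Mechanics: the first-saccade endpoint is
#' `E1 = gain_1 * T1 + noise`; the internally registered displacement is
#' `lambda * E1`; the second-saccade goal (retinocentric) is
#' `G = T2* - lambda * E1`, where `T2*` is the remembered second-target
#' position (with memory noise in the Memory condition); the second endpoint
#' is `E2 = E1 + gain_2 * G + noise`. Motor noise is isotropic Gaussian with
#' SD `motor_noise_cv` times the intended amplitude. An invalid trial sends
#' the first saccade into a random other quadrant. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param layout A [make_layout()] row.
#' @param condition `"Baseline"` or `"Memory"`.
#' @param lambda CD gain for this trial.
#' @param gain_1,gain_2 Motor gains.
#' @param motor_noise_cv Endpoint noise CV.
#' @param memory_noise_px SD (px) of memory noise on the stored T2 (Memory
#'   condition only).
#' @param invalid Misdirect the first saccade?
#'
#' @return A list with `fixations` (ordinal, x, y, onset_ms, offset_ms: start
#'   fixation, the two saccade endpoints, and a return-to-centre fixation)
#'   and `truth` (latent endpoints and parameters).
#' @export
#' @examples
#' lay <- make_layout(screen_config(), "UR", 2)
#' simulate_trial(lay, "Baseline", lambda = 1.2, gain_1 = 0.85)$truth
simulate_trial <- function(layout, condition = c("Baseline", "Memory"),
                           lambda = 1, gain_1 = 1, gain_2 = 1,
                           motor_noise_cv = 0, memory_noise_px = 0,
                           invalid = FALSE) {
  condition <- match.arg(condition)
  t1 <- c(layout$t1_x, layout$t1_y)
  t2 <- c(layout$t2_x, layout$t2_y)

  aim1 <- gain_1 * t1
  if (invalid) {
    s <- quadrant_signs(sample(other_quadrants(layout$quadrant), 1))
    aim1 <- abs(aim1) * s
  }
  e1 <- aim1 + rnorm(2, 0, motor_noise_cv * sqrt(sum(aim1^2)))

  t2_store <- t2
  if (condition == "Memory" && memory_noise_px > 0) {
    t2_store <- t2 + rnorm(2, 0, memory_noise_px)
  }
  goal <- t2_store - lambda * e1           # retinocentric second-saccade goal
  move2 <- gain_2 * goal
  e2 <- e1 + move2 + rnorm(2, 0, motor_noise_cv * sqrt(sum(move2^2)))

  fix_dur <- runif(1, 1200, 1500)
  # go-signal: targets offset in Memory, free initiation in Baseline
  go <- fix_dur + 500 + 130 + if (condition == "Memory") 180 else -150
  onsets <- c(0, go, go + 290, go + 580)
  fixations <- tibble::tibble(
    fixation = 1:4,
    x = c(0, e1[1], e2[1], 0),
    y = c(0, e1[2], e2[2], 0),
    onset_ms = onsets,
    offset_ms = onsets + c(fix_dur, 250, 250, 400)
  )
  truth <- tibble::tibble(
    e1_x = e1[1], e1_y = e1[2], e2_x = e2[1], e2_y = e2[2],
    lambda = lambda, gain_1 = gain_1, gain_2 = gain_2,
    invalid = invalid, condition = condition
  )
  list(fixations = fixations, truth = truth)
}

draw_subjects <- function(gen, n_pd, n_control) {
  n <- n_pd + n_control
  group <- rep(c("pd", "control"), c(n_pd, n_control))
  subject_id <- sprintf("S%02d", seq_len(n))
  symptom_side <- ifelse(
    group == "pd",
    sample(names(gen$symptom_side_prob), n, replace = TRUE,
           prob = gen$symptom_side_prob),
    NA_character_
  )
  dat_mean <- rnorm(n, ifelse(group == "pd", gen$dat_mean_pd, gen$dat_mean_control),
                    gen$dat_sd)
  dat_mean <- pmax(dat_mean, 0.1)
  # lower binding in the hemisphere contralateral to the symptomatic side
  asym <- dplyr::case_when(
    group == "pd" & symptom_side == "left" ~ gen$dat_asymmetry,   # right hemi low
    group == "pd" & symptom_side == "right" ~ -gen$dat_asymmetry, # left hemi low
    TRUE ~ 0
  )
  dat_left <- pmax(dat_mean + asym / 2, 0.05)
  dat_right <- pmax(dat_mean - asym / 2, 0.05)
  if (!gen$simulate_control_dat) {
    dat_left[group == "control"] <- NA_real_
    dat_right[group == "control"] <- NA_real_
  }
  motor_updrs <- ifelse(group == "pd",
                        pmax(round(rnorm(n, gen$updrs_mean, gen$updrs_sd)), 5), 0)

  lambda <- unname(gen$cd_gain[group]) + rnorm(n, 0, gen$subject_sd)
  gain_1 <- gen$motor_gain_1 + rnorm(n, 0, gen$subject_sd)
  gain_2 <- gen$motor_gain_2 + rnorm(n, 0, gen$subject_sd)

  # DAT coupling, applied to subjects that carry a scan, centred within group
  dat_low <- pmin(dat_left, dat_right)
  has_dat <- !is.na(dat_low)
  if (any(has_dat)) {
    centred <- dat_low[has_dat] - mean(dat_low[has_dat])
    lambda[has_dat] <- lambda[has_dat] + gen$dat_coupling[["lambda"]] * centred
    gain_1[has_dat] <- gain_1[has_dat] + gen$dat_coupling[["gain"]] * centred
    gain_2[has_dat] <- gain_2[has_dat] + gen$dat_coupling[["gain"]] * centred
  }
  tibble::tibble(
    subject_id, group, symptom_side, motor_updrs,
    dat_left, dat_right,
    lambda, gain_1 = pmax(gain_1, 0.1), gain_2 = pmax(gain_2, 0.1)
  )
}

#' Simulate a full double-saccade cohort
#'
#' Draws subjects (group, symptom laterality, motor MDS-UPDRS, striatal
#' binding, latent CD/motor gains with DAT coupling) and simulates
#' `trials_per_condition` trials per condition per subject, with condition
#' order counterbalanced across subjects and target quadrants balanced within
#' condition. Latent per-trial parameters and endpoints are kept in `trials`
#' for parameter-recovery studies.
#'
#' @param gen A [gen_params()] object.
#' @param n_pd,n_control Group sizes.
#' @param trials_per_condition Trials per condition per subject.
#' @param config A [screen_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return A list of class `saccade_cohort` with tibbles `subjects`, `trials`
#'   (latent truth incl. target positions and validity labels) and
#'   `fixations` (the observable fixation table).
#' @export
#' @examples
#' coh <- simulate_cohort(gen_params(), n_pd = 2, n_control = 2,
#'                        trials_per_condition = 5, seed = 1)
#' dplyr::count(coh$fixations, subject_id, condition)
simulate_cohort <- function(gen = gen_params(), n_pd = 14, n_control = 14,
                            trials_per_condition = 30,
                            config = screen_config(), seed = NULL) {
  stopifnot(n_pd >= 1, n_control >= 1, trials_per_condition >= 1)
  if (!is.null(seed)) set.seed(seed)
  subjects <- draw_subjects(gen, n_pd, n_control)

  quadrants <- c("UR", "UL", "LR", "LL")
  n_sub <- nrow(subjects)
  tpc <- trials_per_condition

  # trial skeleton: condition order counterbalanced, quadrants balanced
  skel <- purrr::map_dfr(seq_len(n_sub), function(i) {
    conds <- if (i %% 2 == 1) c("Baseline", "Memory") else c("Memory", "Baseline")
    tibble::tibble(
      subject_id = subjects$subject_id[i],
      condition = rep(conds, each = tpc),
      quadrant = c(sample(rep(quadrants, length.out = tpc)),
                   sample(rep(quadrants, length.out = tpc))),
      t2_index = sample(4, 2 * tpc, replace = TRUE)
    )
  })
  n <- nrow(skel)

  # vectorised layout (same arithmetic as make_layout)
  sx <- ifelse(skel$quadrant %in% c("UL", "LL"), -1, 1)
  sy <- ifelse(skel$quadrant %in% c("LR", "LL"), -1, 1)
  ecc_px <- deg_to_px(gen$eccentricity_deg, config)
  theta <- gen$polar_angle * pi / 180
  t1_x <- sx * ecc_px * cos(theta)
  t1_y <- sy * ecc_px * sin(theta)
  offsets <- (seq_len(4) - 2.5) * deg_to_px(gen$t2_spacing_deg, config)
  t2_x <- t1_x + offsets[skel$t2_index]
  t2_y <- rep(0, n)

  # per-trial parameters with the laterality adjustment
  sidx <- match(skel$subject_id, subjects$subject_id)
  target_side <- ifelse(t1_x < 0, "left", "right")
  ipsi <- !is.na(subjects$symptom_side[sidx]) &
    subjects$symptom_side[sidx] == target_side
  lambda <- subjects$lambda[sidx] + ipsi * gen$laterality_delta[["lambda"]]
  gain_1 <- subjects$gain_1[sidx] + ipsi * gen$laterality_delta[["gain"]]
  gain_2 <- subjects$gain_2[sidx] + ipsi * gen$laterality_delta[["gain"]]

  # first saccade (misdirected into a random other quadrant when invalid)
  invalid <- runif(n) < gen$invalid_rate
  aim1_x <- gain_1 * t1_x
  aim1_y <- gain_1 * t1_y
  if (any(invalid)) {
    k <- which(invalid)
    new_q <- vapply(skel$quadrant[k],
                    function(q) sample(other_quadrants(q), 1), character(1))
    aim1_x[k] <- abs(aim1_x[k]) * ifelse(new_q %in% c("UL", "LL"), -1, 1)
    aim1_y[k] <- abs(aim1_y[k]) * ifelse(new_q %in% c("LR", "LL"), -1, 1)
  }
  amp1 <- sqrt(aim1_x^2 + aim1_y^2)
  e1_x <- aim1_x + rnorm(n, 0, gen$motor_noise_cv * amp1)
  e1_y <- aim1_y + rnorm(n, 0, gen$motor_noise_cv * amp1)

  # second saccade toward the (remembered) target minus the registered
  # displacement lambda * E1
  mem_px <- deg_to_px(gen$memory_noise_deg, config)
  is_mem <- skel$condition == "Memory"
  t2s_x <- t2_x + is_mem * rnorm(n, 0, mem_px)
  t2s_y <- t2_y + is_mem * rnorm(n, 0, mem_px)
  move2_x <- gain_2 * (t2s_x - lambda * e1_x)
  move2_y <- gain_2 * (t2s_y - lambda * e1_y)
  amp2 <- sqrt(move2_x^2 + move2_y^2)
  e2_x <- e1_x + move2_x + rnorm(n, 0, gen$motor_noise_cv * amp2)
  e2_y <- e1_y + move2_y + rnorm(n, 0, gen$motor_noise_cv * amp2)

  trials <- dplyr::bind_cols(
    tibble::tibble(trial_id = seq_len(n)),
    skel,
    tibble::tibble(
      t1_x = t1_x, t1_y = t1_y, t2_x = t2_x, t2_y = t2_y,
      e1_x = e1_x, e1_y = e1_y, e2_x = e2_x, e2_y = e2_y,
      lambda = lambda, gain_1 = gain_1, gain_2 = gain_2, invalid = invalid
    )
  )

  fix_dur <- runif(n, 1200, 1500)
  go <- fix_dur + 500 + 130 + ifelse(is_mem, 180, -150)
  idx4 <- rep(seq_len(n), each = 4)
  ordinal <- rep(1:4, n)
  onset <- go[idx4] + c(0, 0, 290, 580)[ordinal]
  onset[ordinal == 1] <- 0
  fixations <- tibble::tibble(
    trial_id = trials$trial_id[idx4],
    subject_id = trials$subject_id[idx4],
    condition = trials$condition[idx4],
    quadrant = trials$quadrant[idx4],
    t2_index = trials$t2_index[idx4],
    fixation = ordinal,
    x = as.numeric(rbind(0, e1_x, e2_x, 0)),
    y = as.numeric(rbind(0, e1_y, e2_y, 0)),
    onset_ms = onset,
    offset_ms = onset + ifelse(ordinal == 1, fix_dur[idx4],
                               c(0, 250, 250, 400)[ordinal])
  )

  structure(
    list(subjects = subjects, trials = trials, fixations = fixations,
         gen = gen, config = config),
    class = "saccade_cohort"
  )
}

#' @export
print.saccade_cohort <- function(x, ...) {
  cat("<saccade_cohort>\n")
  cat(" ", nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "pd"), "PD /",
      sum(x$subjects$group == "control"), "control ),",
      nrow(x$trials), "trials,", nrow(x$fixations), "fixations\n")
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    trials = file.path(dir, "trials.csv"),
    fixations = file.path(dir, "fixations.csv")
  )
  write.csv(cohort$subjects, paths["subjects"], row.names = FALSE)
  write.csv(cohort$trials, paths["trials"], row.names = FALSE)
  write.csv(cohort$fixations, paths["fixations"], row.names = FALSE)
  invisible(paths)
}
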