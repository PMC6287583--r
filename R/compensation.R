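wrap_angle <- function(deg) {
  # wrap to (-180, 180]
  out <- (deg + 180) %% 360 - 180
  ifelse(out == -180, 180, out)
}

#' Ideal and actual second-saccade vectors
#'
#' `ideal_second_saccade()` returns the amplitude and direction of the
#' second saccade that would land exactly on the second target given the
#' first saccade's actual endpoint: the vector `t2 - f1`.
#' `actual_second_saccade()` applies the same formula to the executed vector
#' `f2 - f1`. Angles are degrees counterclockwise from the +x axis
#' (`atan2`), in (-180, 180]; amplitudes in px. A zero-length vector yields
#' amplitude 0 and angle `NA`.
#'
#' @param f1_x,f1_y First-saccade endpoint (canonical frame, px).
#' @param t2_x,t2_y Second-target position.
#' @param f2_x,f2_y Second-saccade endpoint.
#' @return A tibble with columns `amp` and `angle`.
#' @export
#' @examples
#' ideal_second_saccade(248.9, 248.9, 248.9, 0)  # straight down: -90 deg
ideal_second_saccade <- function(f1_x, f1_y, t2_x, t2_y) {
  vx <- t2_x - f1_x
  vy <- t2_y - f1_y
  amp <- sqrt(vx^2 + vy^2)
  tibble::tibble(amp = amp,
                 angle = ifelse(amp == 0, NA_real_, atan2(vy, vx) * 180 / pi))
}

#' @rdname ideal_second_saccade
#' @export
actual_second_saccade <- function(f1_x, f1_y, f2_x, f2_y) {
  ideal_second_saccade(f1_x, f1_y, f2_x, f2_y)
}

#' Code target laterality for a trial
#'
#' Against the `symptom_side` reference, targets on the same screen side as
#' the predominant motor symptoms are `ipsi`. Against the
#' `low_dat_hemisphere` reference, targets in the visual hemifield on the
#' same side as the lower-binding hemisphere are `ipsi` — equivalently,
#' targets in the hemifield *contralateral* to the lower-binding hemisphere
#' are `contra` (the hemifield-to-hemisphere crossing is applied once, here).
#' Subjects without an asymmetry under the chosen reference get `none`.
#'
#' @param target_side `"left"`/`"right"` screen side of the trial's targets.
#' @param symptom_side `"left"`, `"right"`, `"symmetric"` or `NA`.
#' @param dat_left,dat_right Mean striatal binding per hemisphere.
#' @param reference `"symptom_side"` or `"low_dat_hemisphere"`.
#' @return Character vector in `{"ipsi", "contra", "none"}`.
#' @export
#' @examples
#' laterality_code("left", symptom_side = "left")          # "ipsi"
#' laterality_code("right", dat_left = 1.2, dat_right = 1.8,
#'                 reference = "low_dat_hemisphere")        # "contra"
laterality_code <- function(target_side, symptom_side = NA,
                            dat_left = NA, dat_right = NA,
                            reference = c("symptom_side", "low_dat_hemisphere")) {
  reference <- match.arg(reference)
  ref_side <- if (reference == "symptom_side") {
    ifelse(is.na(symptom_side) | symptom_side == "symmetric",
           NA_character_, symptom_side)
  } else {
    dplyr::case_when(
      is.na(dat_left) | is.na(dat_right) | dat_left == dat_right ~ NA_character_,
      dat_left < dat_right ~ "left",
      TRUE ~ "right"
    )
  }
  dplyr::case_when(
    is.na(ref_side) ~ "none",
    target_side == ref_side ~ "ipsi",
    TRUE ~ "contra"
  )
}

#' Build compensation records from trial observations
#'
#' For every valid trial, computes the ideal second saccade (from the actual
#' first-saccade endpoint to the second target) and the executed second
#' saccade, their amplitudes and absolute directions in the canonical frame,
#' and the signed angle error `actual_angle - ideal_angle` (wrapped to
#' (-180, 180]). In the canonical upper-right arrangement a negative angle
#' error means the second saccade was rotated toward the initial fixation
#' point — inward, the amplified-CD signature; positive means outward.
#' Laterality is coded per trial when a subject table is supplied.
#'
#' @param observations Output of [preprocess_trials()].
#' @param subjects Optional subject table (`subject_id`, `group`,
#'   `symptom_side`, `dat_left`, `dat_right`, ...).
#' @param reference Laterality reference passed to [laterality_code()].
#' @return A tibble with one row per valid trial: `ideal_amp`, `ideal_angle`,
#'   `actual_amp`, `actual_angle`, `angle_error`, `amp_error`
#'   (actual - ideal), `laterality`, plus ids, condition, and any subject
#'   covariates. Trials with `f1` on the second target are flagged
#'   `degenerate` and carry `NA` angles.
#' @export
#' @examples
#' coh <- simulate_cohort(gen_params(), 2, 2, 5, seed = 1)
#' rec <- compensation_records(preprocess_trials(coh$fixations), coh$subjects)
#' head(rec)
compensation_records <- function(observations, subjects = NULL,
                                 reference = "symptom_side") {
  rec <- observations |>
    dplyr::filter(.data$valid) |>
    dplyr::mutate(
      target_side = ifelse(.data$quadrant %in% c("UL", "LL"), "left", "right")
    )
  ideal <- ideal_second_saccade(rec$f1_x, rec$f1_y, rec$t2_x, rec$t2_y)
  actual <- actual_second_saccade(rec$f1_x, rec$f1_y, rec$f2_x, rec$f2_y)
  rec <- rec |>
    dplyr::mutate(
      ideal_amp = ideal$amp, ideal_angle = ideal$angle,
      actual_amp = actual$amp, actual_angle = actual$angle,
      degenerate = .data$ideal_amp == 0 | .data$actual_amp == 0,
      angle_error = wrap_angle(.data$actual_angle - .data$ideal_angle),
      amp_error = .data$actual_amp - .data$ideal_amp
    ) |>
    dplyr::select("subject_id", "trial_id", "condition", "quadrant",
                  "target_side", "ideal_amp", "ideal_angle", "actual_amp",
                  "actual_angle", "angle_error", "amp_error", "degenerate")
  if (!is.null(subjects)) {
    rec <- dplyr::left_join(rec, subjects, by = "subject_id")
    rec$laterality <- laterality_code(
      rec$target_side,
      symptom_side = if ("symptom_side" %in% names(rec)) rec$symptom_side else NA,
      dat_left = if ("dat_left" %in% names(rec)) rec$dat_left else NA,
      dat_right = if ("dat_right" %in% names(rec)) rec$dat_right else NA,
      reference = reference
    )
  } else {
    rec$laterality <- "none"
  }
  rec
}

#' Estimate the CD gain per subject from trial observations
#'
#' Under the CD-gain model with unit second-saccade motor gain, the
#' second-saccade endpoint satisfies `f2 - t2 = (1 - lambda) * f1` (canonical
#' frame, fixation at the origin), so each valid trial yields the moment
#' estimate `lambda_hat = 1 - ((f2 - t2) . f1) / |f1|^2`. Endpoint and memory
#' noise enter with zero mean, so the per-subject average is a consistent
#' estimator when the second-saccade gain is near 1; a gain below 1 inflates
#' the apparent lambda.
#'
#' @param observations Output of [preprocess_trials()] (invalid trials are
#'   ignored).
#' @return A tibble with `subject_id`, `lambda_hat`, `n_trials`.
#' @export
#' @examples
#' coh <- simulate_cohort(gen_params(motor_noise_cv = 0.02), 3, 3, 20, seed = 1)
#' estimate_cd_gain(preprocess_trials(coh$fixations))
estimate_cd_gain <- function(observations) {
  observations |>
    dplyr::filter(.data$valid) |>
    dplyr::mutate(
      lambda_trial = 1 -
        ((.data$f2_x - .data$t2_x) * .data$f1_x +
           (.data$f2_y - .data$t2_y) * .data$f1_y) /
        (.data$f1_x^2 + .data$f1_y^2)
    ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(lambda_hat = mean(.data$lambda_trial),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Centre the ideal-saccade predictors
#'
#' Subtracts the mean ideal angle and amplitude, either over the whole
#' analysis set (grand mean, the default) or within subject, storing the
#' centred values alongside the raw ones as `centered_ideal_angle` and
#' `centered_ideal_amp`.
#'
#' @param records Output of [compensation_records()].
#' @param grouping `"grand"` or `"subject"`.
#' @return `records` with the two centred columns added.
#' @export
center_predictors <- function(records, grouping = c("grand", "subject")) {
  grouping <- match.arg(grouping)
  if (nrow(records) == 0) stop("no records to centre")
  if (grouping == "grand") {
    dplyr::mutate(
      records,
      centered_ideal_angle = .data$ideal_angle - mean(.data$ideal_angle, na.rm = TRUE),
      centered_ideal_amp = .data$ideal_amp - mean(.data$ideal_amp, na.rm = TRUE)
    )
  } else {
    records |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::mutate(
        centered_ideal_angle = .data$ideal_angle - mean(.data$ideal_angle, na.rm = TRUE),
        centered_ideal_amp = .data$ideal_amp - mean(.data$ideal_amp, na.rm = TRUE)
      ) |>
      dplyr::ungroup()
  }
}
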