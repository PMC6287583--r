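angle_between <- function(v1, v2) {
  # unsigned angle between two 2-vectors, degrees
  d <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
  if (d == 0) return(NA_real_)
  acos(pmin(pmax(sum(v1 * v2) / d, -1), 1)) * 180 / pi
}

#' Screen one trial for validity
#'
#' A trial is valid when (a) its first saccade (first inter-fixation
#' displacement of at least `min_amp_deg`) is directed toward the first
#' target within `angle_tol` degrees of the fixation-to-target direction, and
#' (b) some subsequent displacement is directed toward the second target
#' under the same tolerance. Mirrors the inclusion rule "first saccade
#' directed toward T1, followed by a saccade toward T2".
#'
#' @param fixations Tibble of one trial's fixations, ordered, with columns
#'   `x`, `y` (px, screen-centred).
#' @param layout The trial's [make_layout()] row.
#' @param config A [screen_config()].
#' @param angle_tol Half-angle tolerance (degrees) around the target
#'   direction.
#' @param min_amp_deg Minimum saccade amplitude (degrees).
#' @return A list: `valid` flag, `reason` (`"ok"`, `"no_saccade"`,
#'   `"t1_misdirected"`, `"no_t2_saccade"`), and `first_idx`, the fixation
#'   index the first saccade lands on.
#' @export
screen_trial <- function(fixations, layout, config = screen_config(),
                         angle_tol = 45, min_amp_deg = 2) {
  min_amp <- deg_to_px(min_amp_deg, config)
  n <- nrow(fixations)
  if (n < 2) return(list(valid = FALSE, reason = "no_saccade", first_idx = NA))
  xy <- cbind(fixations$x, fixations$y)
  steps <- diff(xy)
  amps <- sqrt(rowSums(steps^2))
  first <- which(amps >= min_amp)[1]
  if (is.na(first)) {
    return(list(valid = FALSE, reason = "no_saccade", first_idx = NA))
  }
  t1 <- c(layout$t1_x, layout$t1_y)
  t2 <- c(layout$t2_x, layout$t2_y)
  dev1 <- angle_between(steps[first, ], t1 - xy[first, ])
  if (is.na(dev1) || dev1 > angle_tol) {
    return(list(valid = FALSE, reason = "t1_misdirected", first_idx = first + 1L))
  }
  later <- seq_len(nrow(steps)) > first
  toward_t2 <- vapply(which(later), function(i) {
    if (amps[i] < min_amp) return(FALSE)
    dev <- angle_between(steps[i, ], t2 - xy[i, ])
    !is.na(dev) && dev <= angle_tol
  }, logical(1))
  if (!any(toward_t2)) {
    return(list(valid = FALSE, reason = "no_t2_saccade", first_idx = first + 1L))
  }
  list(valid = TRUE, reason = "ok", first_idx = first + 1L)
}

#' Match fixations to the two targets
#'
#' Implements the closest-fixation rule: `f1` is the fixation nearest the
#' first target; `f2` is the fixation nearest the second target among
#' fixations that occur after `f1` (so a return-to-centre fixation is only
#' picked if nothing closer to T2 follows the first-target fixation).
#'
#' @inheritParams screen_trial
#' @return A list with `f1`, `f2` (length-2 xy vectors in screen
#'   coordinates) and their row indices, or `NULL` f2 when no fixation
#'   follows `f1`.
#' @export
match_fixations <- function(fixations, layout) {
  xy <- cbind(fixations$x, fixations$y)
  d1 <- sqrt((xy[, 1] - layout$t1_x)^2 + (xy[, 2] - layout$t1_y)^2)
  i1 <- which.min(d1)
  after <- seq_len(nrow(xy)) > i1
  if (!any(after)) {
    return(list(f1 = xy[i1, ], i1 = i1, f2 = NULL, i2 = NA_integer_))
  }
  d2 <- sqrt((xy[, 1] - layout$t2_x)^2 + (xy[, 2] - layout$t2_y)^2)
  d2[!after] <- Inf
  i2 <- which.min(d2)
  list(f1 = xy[i1, ], i1 = i1, f2 = xy[i2, ], i2 = i2)
}

#' Preprocess a fixation table into trial observations
#'
#' For every trial: screens validity ([screen_trial()]), matches fixations to
#' the targets ([match_fixations()]), transposes coordinates to the canonical
#' upper-right arrangement ([to_canonical()]) and computes signed endpoint
#' errors (fixation minus target, componentwise, canonical frame). Under this
#' convention a hypometric first saccade has negative errors, while a
#' hypometric second saccade (stopping above the horizontal meridian) has a
#' positive vertical error.
#'
#' @param fixations Fixation table: columns `trial_id`, `subject_id`,
#'   `condition`, `quadrant`, `t2_index`, `fixation`, `x`, `y` (a
#'   [simulate_cohort()] `$fixations` tibble, or the same read from CSV).
#' @param config A [screen_config()].
#' @param angle_tol,min_amp_deg Screening tolerances (see [screen_trial()]).
#' @param polar_angle,eccentricity_deg,t2_spacing_deg Task geometry used to
#'   reconstruct each trial's layout (must match the acquisition settings).
#' @return A tibble with one row per trial: validity flag and reason,
#'   matched fixations `f1_x ... f2_y` and targets (canonical frame), and the
#'   signed errors `t1_dx`, `t1_dy`, `t2_dx`, `t2_dy` (px; `NA` for invalid
#'   trials). Deterministic: rerunning on the same input reproduces the same
#'   output.
#' @export
#' @examples
#' coh <- simulate_cohort(gen_params(), 2, 2, 5, seed = 1)
#' obs <- preprocess_trials(coh$fixations)
#' table(obs$valid)
preprocess_trials <- function(fixations, config = screen_config(),
                              angle_tol = 45, min_amp_deg = 2,
                              polar_angle = 45, eccentricity_deg = 16,
                              t2_spacing_deg = 2.4) {
  needed <- c("trial_id", "subject_id", "condition", "quadrant", "t2_index",
              "fixation", "x", "y")
  stopifnot(all(needed %in% names(fixations)))
  fixations <- dplyr::arrange(fixations, .data$trial_id, .data$fixation)

  # 4 quadrants x 4 T2 candidates: cache the 16 possible layouts
  cache_key <- function(q, i) paste(q, i)
  layouts <- list()
  for (q in c("UR", "UL", "LR", "LL")) {
    for (i in 1:4) {
      layouts[[cache_key(q, i)]] <- make_layout(
        config, q, i, polar_angle = polar_angle,
        eccentricity_deg = eccentricity_deg, t2_spacing_deg = t2_spacing_deg
      )
    }
  }

  meta <- dplyr::distinct(fixations, .data$trial_id, .data$subject_id,
                          .data$condition, .data$quadrant, .data$t2_index)
  idx <- split(seq_len(nrow(fixations)), fixations$trial_id)
  idx <- idx[match(as.character(meta$trial_id), names(idx))]

  n <- nrow(meta)
  valid <- logical(n)
  reason <- character(n)
  num <- matrix(NA_real_, n, 12,
                dimnames = list(NULL, c("f1_x", "f1_y", "f2_x", "f2_y",
                                        "t1_x", "t1_y", "t2_x", "t2_y",
                                        "t1_dx", "t1_dy", "t2_dx", "t2_dy")))
  for (k in seq_len(n)) {
    rows <- fixations[idx[[k]], c("x", "y")]
    lay <- layouts[[cache_key(meta$quadrant[k], meta$t2_index[k])]]
    scr <- screen_trial(rows, lay, config, angle_tol, min_amp_deg)
    valid[k] <- scr$valid
    reason[k] <- scr$reason
    if (!scr$valid) next
    m <- match_fixations(rows, lay)
    if (is.null(m$f2)) {
      valid[k] <- FALSE
      reason[k] <- "no_t2_saccade"
      next
    }
    q <- meta$quadrant[k]
    sx <- if (q %in% c("UL", "LL")) -1 else 1
    sy <- if (q %in% c("LR", "LL")) -1 else 1
    can <- c(m$f1[1] * sx, m$f1[2] * sy, m$f2[1] * sx, m$f2[2] * sy,
             lay$t1_x * sx, lay$t1_y * sy, lay$t2_x * sx, lay$t2_y * sy)
    num[k, 1:8] <- can
    num[k, 9:12] <- c(can[1] - can[5], can[2] - can[6],
                      can[3] - can[7], can[4] - can[8])
  }
  dplyr::bind_cols(
    meta,
    tibble::tibble(valid = valid, reason = reason),
    tibble::as_tibble(num)
  )
}

#' Pivot trial observations to the long error format used by the models
#'
#' One row per trial x target, with the error components and a `target`
#' factor (`T1` reference), ready for [fit_error_model()].
#'
#' @param observations Output of [preprocess_trials()] (invalid trials are
#'   dropped).
#' @param subjects Optional subject table joined in by `subject_id` (adds
#'   `group` etc.).
#' @return A tibble with columns `subject_id`, `trial_id`, `condition`,
#'   `target`, `dx`, `dy` plus any subject covariates.
#' @export
errors_long <- function(observations, subjects = NULL) {
  out <- observations |>
    dplyr::filter(.data$valid) |>
    dplyr::select("subject_id", "trial_id", "condition",
                  "t1_dx", "t1_dy", "t2_dx", "t2_dy") |>
    tidyr::pivot_longer(
      cols = c("t1_dx", "t1_dy", "t2_dx", "t2_dy"),
      names_to = c("target", ".value"),
      names_pattern = "(t[12])_(d[xy])"
    ) |>
    dplyr::mutate(target = factor(toupper(.data$target), levels = c("T1", "T2")))
  if (!is.null(subjects)) {
    out <- dplyr::left_join(out, subjects, by = "subject_id")
  }
  out
}
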