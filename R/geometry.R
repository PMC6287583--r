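#' Screen and task configuration
#'
#' Display geometry for the double-saccade task. Coordinates used throughout
#' the package are in pixels with the origin at screen centre, +x rightward
#' and +y upward. The pixel-per-degree constant is taken as authoritative
#' rather than derived from monitor size and viewing distance.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param px_per_deg Pixels per degree of visual angle.
#' @param refresh_hz Display refresh rate (Hz).
#' @param viewing_distance_cm Viewing distance (cm); carried as metadata.
#'
#' @return A list of class `screen_config`.
#' @export
#' @examples
#' cfg <- screen_config()
#' deg_to_px(16, cfg)
screen_config <- function(width_px = 1024, height_px = 768, px_per_deg = 22,
                          refresh_hz = 85, viewing_distance_cm = 70) {
  stopifnot(
    width_px > 0, height_px > 0, refresh_hz > 0, viewing_distance_cm > 0,
    is.finite(px_per_deg), px_per_deg > 0
  )
  structure(
    list(
      width_px = width_px, height_px = height_px, px_per_deg = px_per_deg,
      refresh_hz = refresh_hz, viewing_distance_cm = viewing_distance_cm
    ),
    class = "screen_config"
  )
}

#' Convert between degrees of visual angle and pixels
#'
#' @param deg,px Value(s) to convert.
#' @param config A [screen_config()].
#' @return Numeric vector.
#' @export
deg_to_px <- function(deg, config = screen_config()) deg * config$px_per_deg

#' @rdname deg_to_px
#' @export
px_to_deg <- function(px, config = screen_config()) px / config$px_per_deg

quadrant_signs <- function(quadrant) {
  switch(quadrant,
    UR = c(1, 1), UL = c(-1, 1), LR = c(1, -1), LL = c(-1, -1),
    stop("unknown quadrant: ", quadrant)
  )
}

#' Build the target layout for one double-saccade trial
#'
#' The first target (T1) sits at a fixed eccentricity (default 16 degrees) in
#' one of the four screen quadrants; the second target (T2) lies on the
#' horizontal meridian on the same side of the screen, at one of four
#' candidate horizontal positions spaced `t2_spacing_deg` apart and centred
#' under T1.
#'
#' @param config A [screen_config()].
#' @param quadrant One of `"UR"`, `"UL"`, `"LR"`, `"LL"`.
#' @param t2_index Which of the four T2 candidates (1..4, left to right).
#' @param polar_angle T1 direction within its quadrant, degrees from the
#'   horizontal, strictly inside (0, 90).
#' @param eccentricity_deg T1 eccentricity in degrees.
#' @param t2_spacing_deg Spacing of the T2 candidates in degrees (the task's
#'   minimum separation).
#'
#' @return A one-row tibble of class `trial_layout` with target positions in
#'   pixels and the trial timing constants (T1 500 ms, T2 130 ms, fixation
#'   1200-1500 ms).
#' @export
#' @examples
#' make_layout(screen_config(), "UR", t2_index = 2)
make_layout <- function(config = screen_config(), quadrant = "UR",
                        t2_index = 1, polar_angle = 45,
                        eccentricity_deg = 16, t2_spacing_deg = 2.4) {
  stopifnot(t2_index %in% 1:4)
  if (polar_angle <= 0 || polar_angle >= 90) {
    stop("polar_angle must lie strictly inside (0, 90) degrees")
  }
  s <- quadrant_signs(quadrant)
  ecc_px <- deg_to_px(eccentricity_deg, config)
  theta <- polar_angle * pi / 180
  t1 <- c(s[1] * ecc_px * cos(theta), s[2] * ecc_px * sin(theta))
  if (abs(t1[1]) > config$width_px / 2 || abs(t1[2]) > config$height_px / 2) {
    stop("polar_angle places T1 off-screen")
  }
  offsets <- (seq_len(4) - 2.5) * deg_to_px(t2_spacing_deg, config)
  t2x <- t1[1] + offsets[t2_index]
  if (sign(t2x) != sign(t1[1])) {
    stop("T2 candidate crosses the vertical midline; reduce t2_spacing_deg")
  }
  tibble::new_tibble(
    tibble::tibble(
      quadrant = quadrant, t2_index = as.integer(t2_index),
      t1_x = t1[1], t1_y = t1[2], t2_x = t2x, t2_y = 0,
      t1_duration_ms = 500, t2_duration_ms = 130,
      fixation_duration_ms = list(c(1200, 1500))
    ),
    class = "trial_layout"
  )
}

#' Transpose coordinates to the canonical upper-right arrangement
#'
#' Reflects points so every trial looks as if the first target had been in
#' the upper-right quadrant (x flipped for left-side quadrants, y flipped for
#' lower quadrants). The map is an involution: applying it twice is the
#' identity, and it preserves distances and unsigned angle differences.
#'
#' @param x,y Point coordinates in pixels (vectors of equal length).
#' @param quadrant Quadrant of the trial's first target (vectorised).
#' @return A tibble with columns `x`, `y` in the canonical frame.
#' @export
#' @examples
#' to_canonical(-100, -50, "LL")
to_canonical <- function(x, y, quadrant) {
  sx <- ifelse(quadrant %in% c("UL", "LL"), -1, 1)
  sy <- ifelse(quadrant %in% c("LR", "LL"), -1, 1)
  tibble::tibble(x = x * sx, y = y * sy)
}
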