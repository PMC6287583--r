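#' Specific binding ratio
#'
#' `SBR = (ROI - OCC) / OCC`: regional tracer uptake relative to the
#' occipital reference region.
#'
#' @param roi_uptake Uptake in the region of interest (vectorised).
#' @param occ_uptake Uptake in the occipital reference; must be > 0.
#' @return Numeric vector of binding ratios.
#' @export
#' @examples
#' sbr(2.5, 1.0)
sbr <- function(roi_uptake, occ_uptake) {
  if (any(!is.finite(occ_uptake)) || any(occ_uptake <= 0)) {
    stop("occipital reference uptake must be positive")
  }
  (roi_uptake - occ_uptake) / occ_uptake
}

striatal_regions <- c("caudate", "anterior_putamen", "posterior_putamen")

#' Summarise striatal DAT binding per subject
#'
#' Computes regional specific binding ratios, the mean striatal value
#' (caudate, anterior putamen, posterior putamen) per hemisphere, the
#' lower-binding hemisphere, and the cohort-centred lower-hemisphere mean
#' used as the DAT covariate in the mixed models.
#'
#' @param uptakes Long tibble with columns `subject_id`, `hemisphere`
#'   (`"left"`/`"right"`), `region` (caudate / anterior_putamen /
#'   posterior_putamen), `uptake`, and `occ` (occipital reference uptake,
#'   one value per subject).
#' @return A tibble, one row per subject: `sbr_<hemisphere>_<region>`
#'   columns, `dat_left`, `dat_right` (hemispheric mean striatal SBR),
#'   `dat_low`, `low_binding_hemisphere` (ties resolved to left with a
#'   warning and flagged in `dat_tie`), and `dat_low_centered` (cohort mean
#'   subtracted).
#' @export
#' @examples
#' up <- tidyr::expand_grid(subject_id = "S01",
#'                          hemisphere = c("left", "right"),
#'                          region = c("caudate", "anterior_putamen",
#'                                     "posterior_putamen"))
#' up$uptake <- c(3.1, 2.8, 2.2, 3.3, 3.0, 2.5)
#' up$occ <- 1.0
#' summarize_dat(up)
summarize_dat <- function(uptakes) {
  stopifnot(all(c("subject_id", "hemisphere", "region", "uptake", "occ")
                %in% names(uptakes)))
  if (!all(uptakes$region %in% striatal_regions)) {
    stop("unknown region; expected ", paste(striatal_regions, collapse = ", "))
  }
  wide <- uptakes |>
    dplyr::mutate(sbr = sbr(.data$uptake, .data$occ)) |>
    dplyr::select("subject_id", "hemisphere", "region", "sbr") |>
    tidyr::pivot_wider(names_from = c("hemisphere", "region"),
                       values_from = "sbr", names_prefix = "sbr_")
  needed <- paste0("sbr_", rep(c("left", "right"), each = 3), "_",
                   rep(striatal_regions, 2))
  missing <- setdiff(needed, names(wide))
  if (length(missing) > 0) {
    stop("incomplete uptake table; missing: ", paste(missing, collapse = ", "))
  }
  out <- wide |>
    dplyr::mutate(
      dat_left = (.data$sbr_left_caudate + .data$sbr_left_anterior_putamen +
                    .data$sbr_left_posterior_putamen) / 3,
      dat_right = (.data$sbr_right_caudate + .data$sbr_right_anterior_putamen +
                     .data$sbr_right_posterior_putamen) / 3,
      dat_low = pmin(.data$dat_left, .data$dat_right),
      dat_tie = .data$dat_left == .data$dat_right,
      low_binding_hemisphere = ifelse(.data$dat_left <= .data$dat_right,
                                      "left", "right")
    )
  if (any(out$dat_tie)) {
    warning("hemispheric binding tie for ",
            paste(out$subject_id[out$dat_tie], collapse = ", "),
            "; lower-binding hemisphere set to left")
  }
  dplyr::mutate(out, dat_low_centered = .data$dat_low - mean(.data$dat_low))
}

#' Simulate an ROI uptake table consistent with subject-level binding
#'
#' Synthesis helper for end-to-end runs: converts each subject's hemispheric
#' mean striatal binding ratios back into regional uptake values around a
#' fixed occipital reference, with a caudate > anterior putamen > posterior
#' putamen gradient and optional measurement noise. [summarize_dat()] applied
#' to the result recovers the hemispheric means (up to the noise).
#'
#' @param subjects Subject tibble with `subject_id`, `dat_left`, `dat_right`
#'   (rows with `NA` binding are skipped).
#' @param occ Occipital reference uptake.
#' @param gradient Additive regional offsets (SBR units) around the
#'   hemispheric mean, summing to zero.
#' @param noise_sd SD of Gaussian noise added to regional SBRs.
#' @return A long uptake tibble suitable for [summarize_dat()].
#' @export
simulate_roi_uptake <- function(subjects, occ = 1,
                                gradient = c(caudate = 0.3,
                                             anterior_putamen = 0,
                                             posterior_putamen = -0.3),
                                noise_sd = 0) {
  stopifnot(abs(sum(gradient)) < 1e-8,
            setequal(names(gradient), striatal_regions))
  subs <- dplyr::filter(subjects, !is.na(.data$dat_left), !is.na(.data$dat_right))
  grid <- tidyr::expand_grid(
    subject_id = subs$subject_id,
    hemisphere = c("left", "right"),
    region = striatal_regions
  ) |>
    dplyr::left_join(dplyr::select(subs, "subject_id", "dat_left", "dat_right"),
                     by = "subject_id")
  grid |>
    dplyr::mutate(
      sbr_true = ifelse(.data$hemisphere == "left", .data$dat_left, .data$dat_right) +
        unname(gradient[.data$region]) + rnorm(dplyr::n(), 0, noise_sd),
      uptake = occ * (1 + pmax(.data$sbr_true, 0)),
      occ = occ
    ) |>
    dplyr::select("subject_id", "hemisphere", "region", "uptake", "occ")
}
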