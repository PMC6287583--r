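#' Default run configuration
#'
#' Nested configuration for an end-to-end run, mirroring the YAML layout
#' accepted by [read_run_config()]: `screen`, `task`, `generator`, `cohort`,
#' `preprocess`, `psychophysics`, `inference` blocks plus the global `seed`
#' and per-stage toggles. Defaults reproduce the study conditions: 14 + 14
#' subjects, 30 trials per condition, 16-degree first target, four
#' second-target positions 2.4 degrees apart, 81% 2AFC threshold staircases.
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    screen = list(width_px = 1024, height_px = 768, px_per_deg = 22,
                  refresh_hz = 85, viewing_distance_cm = 70),
    task = list(polar_angle = 45, eccentricity_deg = 16, t2_spacing_deg = 2.4),
    generator = list(
      cd_gain_control = 1.0, cd_gain_pd = 1.1,
      motor_gain_1 = 0.9, motor_gain_2 = 1.0,
      motor_noise_cv = 0.05, memory_noise_deg = 1.0,
      invalid_rate = 0.06, subject_sd = 0.05,
      dat_coupling_lambda = -0.2, dat_coupling_gain = 0.1,
      laterality_delta_lambda = 0.05, laterality_delta_gain = -0.03
    ),
    cohort = list(n_pd = 14, n_control = 14, trials_per_condition = 30),
    preprocess = list(angle_tol = 45, min_amp_deg = 2),
    psychophysics = list(
      true_threshold = -1.5, elevation_saccade = 1.96, elevation_after = 0.78,
      subject_sd = 0.2, n_trials = 64,
      prior_mean = -1.5, prior_sd = 1, grain = 0.01,
      slope = 3.5, guess = 0.5, lapse = 0.01, target_p = 0.81
    ),
    inference = list(centering = "grand"),
    stages = list(simulate = TRUE, preprocess = TRUE, compensate = TRUE,
                  imaging = TRUE, inference = TRUE, psychophysics = TRUE,
                  report = TRUE)
  ), class = "run_config")
}

merge_config <- function(default, user, path = "") {
  unknown <- setdiff(names(user), names(default))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (k in names(user)) {
    default[[k]] <- if (is.list(default[[k]]) && is.list(user[[k]])) {
      merge_config(default[[k]], user[[k]], paste0(path, ".", k))
    } else {
      user[[k]]
    }
  }
  default
}

#' Read and validate a YAML run configuration
#'
#' Reads a YAML file whose blocks follow [default_config()]; unknown keys
#' are rejected, missing keys keep their defaults.
#'
#' @param path Path to a YAML file, or a list already in memory.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  structure(merge_config(unclass(default_config()), user), class = "run_config")
}

config_gen_params <- function(config) {
  g <- config$generator
  t <- config$task
  gen_params(
    cd_gain = c(control = g$cd_gain_control, pd = g$cd_gain_pd),
    motor_gain_1 = g$motor_gain_1, motor_gain_2 = g$motor_gain_2,
    motor_noise_cv = g$motor_noise_cv, memory_noise_deg = g$memory_noise_deg,
    invalid_rate = g$invalid_rate, subject_sd = g$subject_sd,
    dat_coupling = c(lambda = g$dat_coupling_lambda, gain = g$dat_coupling_gain),
    laterality_delta = c(lambda = g$laterality_delta_lambda,
                         gain = g$laterality_delta_gain),
    polar_angle = t$polar_angle, eccentricity_deg = t$eccentricity_deg,
    t2_spacing_deg = t$t2_spacing_deg
  )
}

config_screen <- function(config) {
  do.call(screen_config, config$screen)
}

stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647L)
}

format_model_md <- function(model, caption) {
  tab <- tidy(model)
  lines <- c(
    paste0("### ", caption),
    "",
    "| Predictor | Estimate | 95% CI | t value |",
    "|---|---|---|---|",
    sprintf("| %s | %.2f | [%.2f, %.2f] | %.2f |",
            tab$term, tab$estimate, tab$conf.low, tab$conf.high,
            tab$statistic)
  )
  if (nrow(model$trace) > 0) {
    lines <- c(lines, "",
               paste0("Pruned terms: ", paste(model$trace$removed, collapse = ", "),
                      "."))
  }
  if (model$singular) lines <- c(lines, "", "*Note: singular fit.*")
  c(lines, "")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> compensation -> imaging ->
#' mixed-model inference -> psychophysics -> report, with one global seed
#' expanded into independent per-stage seeds (so disabling a stage does not
#' perturb the randomness of the others). When `outdir` is given, every
#' stage's tables are written as CSV, model summaries as JSON (when jsonlite
#' is installed) plus a Markdown report, and an MD5 manifest of all outputs;
#' identical config and seed reproduce identical outputs. A stage toggled
#' off in `config$stages` reads its inputs back from `outdir` (written by a
#' previous run) instead of recomputing them.
#'
#' @param config A `run_config` ([default_config()], possibly via
#'   [read_run_config()]).
#' @param outdir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `cohort`, `observations`, `compensation`,
#'   `dat_summary`, `models` (pruned `saccade_model`s for horizontal /
#'   vertical errors and angle / amplitude compensation), `thresholds`,
#'   `suppression` and `report` (character vector of Markdown lines).
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$cohort <- list(n_pd = 3, n_control = 3, trials_per_condition = 8)
#' cfg$psychophysics$n_trials <- 16
#' res <- run_pipeline(cfg, quiet = TRUE)
#' names(res$models)
run_pipeline <- function(config = default_config(), outdir = NULL,
                         quiet = FALSE) {
  config <- read_run_config(unclass(config))  # validate
  say <- function(...) if (!quiet) message("[saccadecd] ", ...)
  stages <- config$stages
  screen <- config_screen(config)
  out <- list(config = config)
  csv_in <- function(name) {
    if (is.null(outdir)) stop("stage '", name, "' disabled but no outdir to read from")
    f <- file.path(outdir, paste0(name, ".csv"))
    if (!file.exists(f)) stop("missing previous output: ", f)
    tibble::as_tibble(utils::read.csv(f))
  }

  if (isTRUE(stages$simulate)) {
    say("simulating cohort")
    out$cohort <- simulate_cohort(
      config_gen_params(config),
      n_pd = config$cohort$n_pd, n_control = config$cohort$n_control,
      trials_per_condition = config$cohort$trials_per_condition,
      config = screen, seed = stage_seed(config$seed, 1)
    )
    subjects <- out$cohort$subjects
    fixations <- out$cohort$fixations
  } else {
    subjects <- csv_in("subjects")
    fixations <- csv_in("fixations")
  }

  if (isTRUE(stages$preprocess)) {
    say("preprocessing fixation table")
    out$observations <- preprocess_trials(
      fixations, config = screen,
      angle_tol = config$preprocess$angle_tol,
      min_amp_deg = config$preprocess$min_amp_deg,
      polar_angle = config$task$polar_angle,
      eccentricity_deg = config$task$eccentricity_deg,
      t2_spacing_deg = config$task$t2_spacing_deg
    )
  } else {
    out$observations <- csv_in("observations")
  }

  if (isTRUE(stages$compensate)) {
    say("computing compensation records")
    out$compensation <- compensation_records(out$observations, subjects) |>
      center_predictors(grouping = config$inference$centering)
  } else {
    out$compensation <- csv_in("compensation")
  }

  if (isTRUE(stages$imaging)) {
    say("summarising DAT binding")
    set.seed(stage_seed(config$seed, 2))
    uptake <- simulate_roi_uptake(subjects, noise_sd = 0.02)
    out$dat_summary <- if (nrow(uptake) > 0) summarize_dat(uptake) else NULL
  }

  if (isTRUE(stages$inference)) {
    say("fitting mixed models")
    err <- errors_long(out$observations, subjects)
    out$models <- list(
      horizontal_error = prune_model(fit_error_model(err, "dx")),
      vertical_error = prune_model(fit_error_model(err, "dy")),
      angle_compensation = prune_model(
        fit_compensation_model(out$compensation, "actual_angle")),
      amplitude_compensation = prune_model(
        fit_compensation_model(out$compensation, "actual_amp"))
    )
  }

  if (isTRUE(stages$psychophysics)) {
    say("running threshold staircases")
    p <- config$psychophysics
    n_sub <- config$cohort$n_pd + config$cohort$n_control
    out$thresholds <- simulate_threshold_study(
      n_subjects = n_sub,
      true_threshold = p$true_threshold,
      elevation_saccade = p$elevation_saccade,
      elevation_after = p$elevation_after,
      subject_sd = p$subject_sd, n_trials = p$n_trials,
      group = rep(c("pd", "control"),
                  c(config$cohort$n_pd, config$cohort$n_control)),
      seed = stage_seed(config$seed, 3),
      prior_mean = p$prior_mean, prior_sd = p$prior_sd, grain = p$grain,
      slope = p$slope, guess = p$guess, lapse = p$lapse, target_p = p$target_p
    )
    out$suppression <- suppression_model(out$thresholds)
  }

  if (isTRUE(stages$report)) {
    report <- c(
      "# Double-saccade CD analysis report", "",
      sprintf("Seed %d; %d PD + %d control subjects, %d trials per condition.",
              config$seed, config$cohort$n_pd, config$cohort$n_control,
              config$cohort$trials_per_condition), ""
    )
    if (!is.null(out$observations)) {
      excl <- mean(!out$observations$valid)
      report <- c(report,
                  sprintf("Preprocessing excluded %.1f%% of trials.", 100 * excl),
                  "")
    }
    if (!is.null(out$models)) {
      report <- c(
        report,
        format_model_md(out$models$horizontal_error,
                        "Endpoint model, horizontal errors (px)"),
        format_model_md(out$models$vertical_error,
                        "Endpoint model, vertical errors (px)"),
        format_model_md(out$models$angle_compensation,
                        "Compensation model, second-saccade angle (deg)"),
        format_model_md(out$models$amplitude_compensation,
                        "Compensation model, second-saccade amplitude (px)")
      )
    }
    if (!is.null(out$suppression)) {
      report <- c(report,
                  format_model_md(out$suppression,
                                  "Saccadic suppression (log10 contrast threshold)"))
    }
    out$report <- report
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(obj, name) {
      if (!is.null(obj)) {
        write.csv(obj, file.path(outdir, paste0(name, ".csv")), row.names = FALSE)
      }
    }
    if (!is.null(out$cohort)) {
      wr(out$cohort$subjects, "subjects")
      wr(out$cohort$trials, "trials")
      wr(out$cohort$fixations, "fixations")
    }
    wr(out$observations, "observations")
    wr(out$compensation, "compensation")
    wr(out$dat_summary, "dat_summary")
    wr(out$thresholds, "thresholds")
    if (!is.null(out$models) && requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        lapply(out$models, function(m) list(coefficients = tidy(m),
                                            fit = glance(m),
                                            pruned = m$trace)),
        file.path(outdir, "models.json"), dataframe = "rows", auto_unbox = TRUE,
        digits = NA
      )
    }
    if (!is.null(out$report)) {
      writeLines(out$report, file.path(outdir, "report.md"))
    }
    files <- setdiff(list.files(outdir, full.names = TRUE),
                     file.path(outdir, "MANIFEST"))
    manifest <- sprintf("%s  %s", tools::md5sum(files), basename(files))
    writeLines(manifest, file.path(outdir, "MANIFEST"))
  }
  say("done")
  invisible(out)
}

#' Deterministic test fixtures in named regimes
#'
#' Small cohorts (at most 200 trials) embodying the canonical regimes of
#' the CD-gain model: `veridical` (unit gains, zero noise: every trial ends
#' exactly on target), `amplified_cd` (CD gain 1.2, hypometric first
#' saccades, zero noise: second saccades biased inward), `diminished_cd`
#' (CD gain 0.8: biased outward), and `null_cohort` (both groups share the
#' veridical-CD parameters, with realistic noise).
#'
#' @param kind Regime name.
#' @param seed Integer seed.
#' @param dir Optional directory: writes the CSV bundle via [write_cohort()].
#' @return A `saccade_cohort`.
#' @export
#' @examples
#' fx <- make_fixtures("amplified_cd")
#' mean(compensation_records(preprocess_trials(fx$fixations))$angle_error)
make_fixtures <- function(kind = c("veridical", "amplified_cd",
                                   "diminished_cd", "null_cohort"),
                          seed = 1, dir = NULL) {
  kind <- match.arg(kind)
  gen <- switch(kind,
    veridical = gen_params(cd_gain = 1, motor_gain_1 = 1, motor_gain_2 = 1,
                           motor_noise_cv = 0, memory_noise_deg = 0,
                           invalid_rate = 0, subject_sd = 0,
                           dat_coupling = c(lambda = 0, gain = 0),
                           laterality_delta = c(lambda = 0, gain = 0)),
    amplified_cd = gen_params(cd_gain = 1.2, motor_gain_1 = 0.85,
                              motor_gain_2 = 1, motor_noise_cv = 0,
                              memory_noise_deg = 0, invalid_rate = 0,
                              subject_sd = 0,
                              dat_coupling = c(lambda = 0, gain = 0),
                              laterality_delta = c(lambda = 0, gain = 0)),
    diminished_cd = gen_params(cd_gain = 0.8, motor_gain_1 = 0.85,
                               motor_gain_2 = 1, motor_noise_cv = 0,
                               memory_noise_deg = 0, invalid_rate = 0,
                               subject_sd = 0,
                               dat_coupling = c(lambda = 0, gain = 0),
                               laterality_delta = c(lambda = 0, gain = 0)),
    null_cohort = gen_params(cd_gain = 1, motor_gain_1 = 0.9,
                             dat_coupling = c(lambda = 0, gain = 0),
                             laterality_delta = c(lambda = 0, gain = 0))
  )
  n_side <- if (kind == "null_cohort") 5 else 2
  trials <- if (kind == "null_cohort") 10 else 10
  cohort <- simulate_cohort(gen, n_pd = n_side, n_control = n_side,
                            trials_per_condition = trials, seed = seed)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}
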