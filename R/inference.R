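split_formula <- function(formula) {
  # separate fixed-effect term labels from random-effect terms
  rhs_terms <- attr(terms(lme4::nobars(formula)), "term.labels")
  bars <- lme4::findbars(formula)
  list(
    response = deparse(formula[[2]]),
    fixed = rhs_terms,
    random = vapply(bars, function(b) paste0("(", deparse(b), ")"), character(1))
  )
}

build_formula <- function(response, fixed, random) {
  rhs <- paste(c(if (length(fixed) > 0) fixed else "1", random), collapse = " + ")
  as.formula(paste(response, "~", rhs))
}

model_result_table <- function(fit) {
  cf <- summary(fit)$coefficients
  se <- cf[, "Std. Error"]
  est <- cf[, "Estimate"]
  z <- qnorm(0.975)
  asg <- attr(model.matrix(fit), "assign")
  labels <- attr(terms(fit, fixed.only = TRUE), "term.labels")
  term_of <- c("(Intercept)", labels)[asg + 1]
  tibble::tibble(
    term = rownames(cf),
    model_term = term_of,
    estimate = unname(est),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se),
    statistic = unname(cf[, "t value"]),
    significant = unname(est - z * se > 0 | est + z * se < 0)
  )
}

#' Fit a linear mixed-effects model at trial level
#'
#' Thin wrapper around [lme4::lmer()] (REML, Wald 95% confidence intervals
#' and t statistics) returning a `saccade_model` object that the pruning,
#' tidying and reporting functions understand. Following the reporting
#' convention used throughout the package, a term is labelled significant iff
#' its 95% CI excludes zero; no p values are computed.
#'
#' @param data Trial-level tibble.
#' @param formula An lme4-style formula with random-effect terms.
#' @param reml Use REML (default) or ML.
#' @return A list of class `saccade_model`: the lme4 `fit`, a `result` tibble
#'   (`term`, `estimate`, `conf.low`, `conf.high`, `statistic`,
#'   `significant`), convergence/singularity flags, and an empty pruning
#'   `trace`.
#' @export
#' @examples
#' coh <- simulate_cohort(gen_params(), 3, 3, 10, seed = 1)
#' err <- errors_long(preprocess_trials(coh$fixations), coh$subjects)
#' m <- fit_mixed_model(err, dx ~ group * target + (1 | subject_id))
#' tidy(m)
fit_mixed_model <- function(data, formula, reml = TRUE) {
  parts <- split_formula(formula)
  fit <- suppressMessages(
    lme4::lmer(formula, data = data, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE))
  )
  messages <- unlist(fit@optinfo$conv$lme4$messages)
  # singularity is reported separately via the `singular` flag
  conv_messages <- messages[!grepl("boundary \\(singular\\)", messages)]
  structure(
    list(
      fit = fit,
      response = parts$response, fixed = parts$fixed, random = parts$random,
      data = data, reml = reml,
      result = model_result_table(fit),
      converged = length(conv_messages) == 0,
      messages = messages,
      singular = lme4::isSingular(fit),
      n_obs = nrow(fit@frame),
      n_groups = lme4::ngrps(fit),
      trace = tibble::tibble(step = integer(), removed = character(),
                             statistic = numeric())
    ),
    class = "saccade_model"
  )
}

#' @export
print.saccade_model <- function(x, digits = 2, ...) {
  cat("<saccade_model> ", x$response, " ~ ",
      paste(c(x$fixed, x$random), collapse = " + "), "\n", sep = "")
  cat("  n = ", x$n_obs, " observations, ",
      paste(names(x$n_groups), x$n_groups, collapse = ", "), " groups",
      if (x$singular) " [singular fit]", if (!x$converged) " [not converged]",
      "\n\n", sep = "")
  tab <- x$result
  out <- data.frame(
    Predictor = tab$term,
    Estimate = round(tab$estimate, digits),
    `95% CI` = sprintf("[%s, %s]", round(tab$conf.low, digits),
                       round(tab$conf.high, digits)),
    `t value` = round(tab$statistic, digits),
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  if (nrow(x$trace) > 0) {
    cat("\npruned:", paste(x$trace$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit the endpoint-error model
#'
#' The error-model family for double-saccade endpoint errors: the chosen
#' error component is modelled on single trials with fixed effects
#' `group * target * condition` (all interactions) and, by default, a random
#' intercept and condition slope per participant.
#'
#' @param data Long error table from [errors_long()] (columns `dx`, `dy`,
#'   `group`, `target`, `condition`, `subject_id`).
#' @param response `"dx"` (horizontal error) or `"dy"` (vertical error).
#' @param fixed Right-hand-side string for the fixed effects.
#' @param random Random-effects term string.
#' @param reml Use REML.
#' @return A `saccade_model`.
#' @export
fit_error_model <- function(data, response = c("dx", "dy"),
                            fixed = "group * target * condition",
                            random = "(1 + condition | subject_id)",
                            reml = TRUE) {
  response <- match.arg(response)
  data <- dplyr::mutate(
    data,
    group = factor(.data$group, levels = intersect(c("control", "pd"),
                                                   unique(.data$group))),
    condition = factor(.data$condition, levels = c("Baseline", "Memory"))
  )
  fit_mixed_model(data, build_formula(response, fixed, random), reml = reml)
}

#' Fit the trial-by-trial compensation model
#'
#' Models the executed second-saccade angle (or amplitude) as a function of
#' the centred ideal angle (or amplitude) and its interactions with group,
#' condition, and optionally laterality / DAT / UPDRS covariates, with
#' subject random effects. Rows with `laterality == "none"` are excluded
#' whenever `laterality` appears among the predictors (symmetric subjects
#' carry no laterality contrast).
#'
#' @param records Output of [compensation_records()] passed through
#'   [center_predictors()].
#' @param response `"actual_angle"` or `"actual_amp"`.
#' @param fixed Fixed-effects right-hand side; defaults to the centred ideal
#'   predictor crossed with group and condition.
#' @param random Random-effects term string.
#' @param reml Use REML.
#' @return A `saccade_model`.
#' @export
fit_compensation_model <- function(records,
                                   response = c("actual_angle", "actual_amp"),
                                   fixed = NULL,
                                   random = "(1 + condition | subject_id)",
                                   reml = TRUE) {
  response <- match.arg(response)
  predictor <- if (response == "actual_angle") "centered_ideal_angle"
               else "centered_ideal_amp"
  if (is.null(fixed)) fixed <- paste(predictor, "* group * condition")
  if (!predictor %in% names(records)) {
    stop("records lack ", predictor, "; run center_predictors() first")
  }
  records <- dplyr::filter(records, !.data$degenerate)
  if (grepl("laterality", fixed)) {
    records <- dplyr::filter(records, .data$laterality != "none")
  }
  if ("condition" %in% names(records)) {
    records <- dplyr::mutate(
      records, condition = factor(.data$condition,
                                  levels = c("Baseline", "Memory"))
    )
  }
  fit_mixed_model(records, build_formula(response, fixed, random), reml = reml)
}

removable_terms <- function(fixed) {
  # a term may be removed only if no retained higher-order term contains it
  if (length(fixed) == 0) return(character())
  vars <- lapply(strsplit(fixed, ":", fixed = TRUE), sort)
  contained <- vapply(seq_along(fixed), function(i) {
    any(vapply(seq_along(fixed), function(j) {
      j != i && length(vars[[j]]) > length(vars[[i]]) &&
        all(vars[[i]] %in% vars[[j]])
    }, logical(1)))
  }, logical(1))
  fixed[!contained]
}

#' Prune a mixed model by the |t| < 2 rule
#'
#' Iteratively removes the fixed-effect term with the smallest absolute t
#' statistic among terms that (a) have all their coefficients at `|t| <
#' threshold` and (b) are not contained in a retained higher-order
#' interaction (marginality is respected: a main effect is never dropped
#' while its interaction stays). The model is refitted after each removal;
#' pruning stops when every removable term contributes, or only the
#' intercept remains. The full trace is recorded, making the procedure
#' deterministic and auditable.
#'
#' @param model A `saccade_model`.
#' @param threshold Absolute-t threshold below which a term is a candidate
#'   for removal.
#' @return The pruned `saccade_model`, with `$trace` listing each removed
#'   term and its t statistic at removal.
#' @export
prune_model <- function(model, threshold = 2) {
  stopifnot(inherits(model, "saccade_model"))
  step <- nrow(model$trace)
  repeat {
    fixed <- model$fixed
    if (length(fixed) == 0) break
    cand <- removable_terms(fixed)
    term_stat <- vapply(cand, function(tm) {
      max(abs(model$result$statistic[model$result$model_term == tm]))
    }, numeric(1))
    weak <- term_stat[term_stat < threshold]
    if (length(weak) == 0) break
    drop <- names(weak)[which.min(weak)]
    step <- step + 1
    trace_row <- tibble::tibble(step = step, removed = drop,
                                statistic = unname(weak[which.min(weak)]))
    refit <- fit_mixed_model(
      model$data,
      build_formula(model$response, setdiff(fixed, drop), model$random),
      reml = model$reml
    )
    refit$trace <- dplyr::bind_rows(model$trace, trace_row)
    model <- refit
  }
  model
}

#' Cluster (subject-level) bootstrap percentile confidence interval
#'
#' Resamples subjects with replacement and returns the percentile interval
#' of the resampled statistic; the package default of 1,000 bootstrap
#' samples matches the convention used for all figure error bars.
#'
#' @param subject_means Numeric vector, one value per subject.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param statistic Function applied to each resample.
#' @param seed Optional integer seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' bootstrap_ci(rnorm(14), seed = 1)
bootstrap_ci <- function(subject_means, n_boot = 1000, level = 0.95,
                         statistic = mean, seed = NULL) {
  n <- length(subject_means)
  if (n < 2) stop("need at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  stats <- vapply(seq_len(n_boot), function(i) {
    statistic(subject_means[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  setNames(quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7),
           c("lower", "upper"))
}

#' Mann-Whitney U with tie-corrected normal approximation
#'
#' Computes the rank-sum U statistic for `x` (relative to `y`), the
#' tie-corrected normal-approximation Z, and the two-sided p value. When
#' every observation is identical (zero rank variance, e.g. an all-zero
#' questionnaire item in both groups) the statistic degenerates to Z = 0,
#' p = 1.
#'
#' @param x,y Numeric score vectors for the two groups.
#' @return A tibble with `u`, `z`, `p`, `n_x`, `n_y`. `z < 0` means `x`
#'   tends to score lower than `y`.
#' @export
#' @examples
#' mann_whitney(c(0, 0, 1), c(1, 2, 2))
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(tibble::tibble(u = u, z = 0, p = 1, n_x = n1, n_y = n2))
  }
  z <- (u - mu) / sqrt(sigma2)
  tibble::tibble(u = u, z = z, p = min(1, 2 * pnorm(-abs(z))),
                 n_x = n1, n_y = n2)
}

#' Group comparison of questionnaire items
#'
#' Two-sided Mann-Whitney tests per questionnaire item plus a `total` row
#' (per-subject mean score across items), comparing the two groups on
#' ordinal 0-3 symptom ratings.
#'
#' @param scores Long tibble with columns `subject_id`, `group`, `item`,
#'   `score`.
#' @param reference Group whose ranks define the sign of Z (defaults to the
#'   first level encountered); `z < 0` means the reference group scores
#'   lower.
#' @return A tibble, one row per item plus `total`: group means and SDs, `u`,
#'   `z`, `p`.
#' @export
questionnaire_test <- function(scores, reference = NULL) {
  stopifnot(all(c("subject_id", "group", "item", "score") %in% names(scores)))
  groups <- unique(scores$group)
  if (length(groups) != 2) stop("exactly two groups required")
  if (is.null(reference)) reference <- groups[1]
  other <- setdiff(groups, reference)
  totals <- scores |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    dplyr::mutate(item = "total")
  per_item <- dplyr::bind_rows(
    dplyr::select(scores, "subject_id", "group", "item", "score"), totals
  )
  per_item |>
    dplyr::group_by(.data$item) |>
    dplyr::group_modify(function(d, key) {
      x <- d$score[d$group == reference]
      y <- d$score[d$group == other]
      res <- mann_whitney(x, y)
      tibble::tibble(
        mean_ref = mean(x), sd_ref = sd(x),
        mean_other = mean(y), sd_other = sd(y),
        u = res$u, z = res$z, p = res$p
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(!!paste0("mean_", reference) := "mean_ref",
                  !!paste0("sd_", reference) := "sd_ref",
                  !!paste0("mean_", other) := "mean_other",
                  !!paste0("sd_", other) := "sd_other")
}
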