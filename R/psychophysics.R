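#' Anchored Weibull psychometric function
#'
#' Probability of a correct 2AFC response as a function of stimulus intensity
#' (log10 Michelson contrast). The function is anchored so that
#' `P(correct) = target_p` exactly at `threshold`:
#' `P(x) = guess + (1 - guess - lapse) * (1 - exp(-10^(slope * (x - x0))))`,
#' with `x0` shifted so the curve passes through (`threshold`, `target_p`).
#'
#' @param x Intensity (log10 Michelson contrast), vectorised.
#' @param threshold Intensity at which performance equals `target_p`.
#' @param slope Weibull slope (beta) in log10 units.
#' @param guess Guess rate (0.5 for 2AFC).
#' @param lapse Lapse rate.
#' @param target_p Performance level that defines the threshold.
#' @return Probability of a correct response.
#' @export
#' @examples
#' weibull_p(-1.5, threshold = -1.5)  # = 0.81 by construction
weibull_p <- function(x, threshold, slope = 3.5, guess = 0.5, lapse = 0.01,
                      target_p = 0.81) {
  f_star <- (target_p - guess) / (1 - guess - lapse)
  stopifnot(f_star > 0, f_star < 1)
  x0 <- threshold - log10(-log(1 - f_star)) / slope
  guess + (1 - guess - lapse) * (1 - exp(-10^(slope * (x - x0))))
}

#' Create a simulated 2AFC observer
#'
#' Returns a function of intensity that emits 1 (correct) or 0 (incorrect)
#' with probability given by the anchored Weibull psychometric function, so
#' that the observer is exactly at `target_p` correct at
#' `true_log_threshold`. Uses the current RNG state.
#'
#' @param true_log_threshold Observer's true threshold (log10 contrast).
#' @inheritParams weibull_p
#' @return A function `f(intensity) -> integer in {0, 1}` with the
#'   psychometric parameters attached as attributes.
#' @export
#' @examples
#' set.seed(1)
#' obs <- simulate_observer(-1.5)
#' mean(replicate(2000, obs(-1.5)))  # about 0.81
simulate_observer <- function(true_log_threshold, slope = 3.5, guess = 0.5,
                              lapse = 0.01, target_p = 0.81) {
  stopifnot(lapse >= 0, lapse < 0.1, guess >= 0, guess < 1)
  f <- function(intensity) {
    rbinom(1, 1, weibull_p(intensity, true_log_threshold, slope, guess,
                           lapse, target_p))
  }
  structure(f, threshold = true_log_threshold, slope = slope, guess = guess,
            lapse = lapse, target_p = target_p)
}

#' Initialise a QUEST staircase
#'
#' QUEST maintains a discretised posterior over the (log10 contrast)
#' threshold of an anchored Weibull psychometric function. The prior is
#' Gaussian on a grid covering the prior mean plus/minus four prior SDs.
#'
#' @param prior_mean,prior_sd Gaussian prior over the threshold.
#' @param grain Grid spacing (log10 units).
#' @inheritParams weibull_p
#' @return A list of class `quest_state`: `grid`, `posterior` (sums to 1),
#'   psychometric parameters, and a `history` tibble.
#' @export
#' @examples
#' q <- quest_init(-1.5, 1)
#' quest_next(q)
quest_init <- function(prior_mean = -1.5, prior_sd = 1, grain = 0.01,
                       slope = 3.5, guess = 0.5, lapse = 0.01,
                       target_p = 0.81) {
  stopifnot(prior_sd > 0, grain > 0, grain < prior_sd)
  grid <- seq(prior_mean - 4 * prior_sd, prior_mean + 4 * prior_sd, by = grain)
  posterior <- dnorm(grid, prior_mean, prior_sd)
  posterior <- posterior / sum(posterior)
  structure(
    list(
      grid = grid, posterior = posterior,
      slope = slope, guess = guess, lapse = lapse, target_p = target_p,
      history = tibble::tibble(intensity = numeric(), response = integer())
    ),
    class = "quest_state"
  )
}

#' @export
print.quest_state <- function(x, ...) {
  cat("<quest_state> ", nrow(x$history), " trials, estimate ",
      format(quest_estimate(x), digits = 4), " log10 contrast\n", sep = "")
  invisible(x)
}

#' QUEST update, placement and estimate
#'
#' `quest_update()` performs the Bayes update of the threshold posterior with
#' the Weibull likelihood of the observed response; `quest_next()` returns
#' the posterior-mean threshold as the next test intensity (posterior-mean
#' QUEST variant); `quest_estimate()` returns the posterior mean.
#'
#' @param state A `quest_state`.
#' @param intensity Tested intensity (log10 contrast); must be finite.
#' @param response 1 (correct) or 0 (incorrect).
#' @return `quest_update()`: the updated state; `quest_next()` /
#'   `quest_estimate()`: a scalar intensity.
#' @export
quest_update <- function(state, intensity, response) {
  stopifnot(inherits(state, "quest_state"), is.finite(intensity),
            response %in% c(0L, 1L))
  p_correct <- weibull_p(intensity, state$grid, state$slope, state$guess,
                         state$lapse, state$target_p)
  lik <- if (response == 1) p_correct else 1 - p_correct
  post <- state$posterior * lik
  total <- sum(post)
  if (!is.finite(total) || total <= 0) stop("degenerate QUEST posterior")
  state$posterior <- post / total
  state$history <- dplyr::bind_rows(
    state$history,
    tibble::tibble(intensity = intensity, response = as.integer(response))
  )
  state
}

#' @rdname quest_update
#' @export
quest_next <- function(state) {
  sum(state$grid * state$posterior)
}

#' @rdname quest_update
#' @export
quest_estimate <- function(state) {
  sum(state$grid * state$posterior)
}

#' Run one adaptive threshold session
#'
#' Runs an `n_trials` QUEST staircase against an observer function (e.g.
#' [simulate_observer()]), placing each trial at the current posterior mean.
#'
#' @param observer A function `f(intensity) -> 0/1`.
#' @param condition Label stored with the result (`"fixation"`, `"saccade"`,
#'   `"after_saccade"`).
#' @param n_trials Number of staircase trials.
#' @param subject_id Optional subject label.
#' @param state Optional pre-built [quest_init()] state.
#' @param ... Passed to [quest_init()] when `state` is `NULL`.
#' @return A one-row tibble of class `threshold_result`: `subject_id`,
#'   `condition`, `log10_threshold`, `n_trials`, plus the final `quest_state`
#'   in the attribute `"state"`.
#' @export
#' @examples
#' set.seed(1)
#' run_threshold_session(simulate_observer(-1.5), "fixation")
run_threshold_session <- function(observer, condition = "fixation",
                                  n_trials = 64, subject_id = NA_character_,
                                  state = NULL, ...) {
  stopifnot(is.function(observer), n_trials >= 1)
  if (is.null(state)) state <- quest_init(...)
  for (i in seq_len(n_trials)) {
    x <- quest_next(state)
    state <- quest_update(state, x, observer(x))
  }
  out <- tibble::new_tibble(
    tibble::tibble(
      subject_id = subject_id, condition = condition,
      log10_threshold = quest_estimate(state), n_trials = n_trials
    ),
    class = "threshold_result"
  )
  attr(out, "state") <- state
  out
}

#' Simulate a saccadic-suppression threshold study
#'
#' Gives each simulated subject a true fixation threshold plus fixed
#' elevations during and right after saccades, runs one QUEST session per
#' condition ([run_threshold_session()]) with block order counterbalanced
#' across subjects, and returns the stacked threshold results.
#'
#' @param n_subjects Number of subjects.
#' @param true_threshold Mean fixation-condition threshold (log10 contrast).
#' @param elevation_saccade,elevation_after True threshold elevations (log10
#'   units) during and right after saccades.
#' @param subject_sd Between-subject SD of the fixation threshold.
#' @param n_trials Staircase trials per condition.
#' @param group Optional group label column value (vectorised over subjects).
#' @param seed Optional integer seed.
#' @param ... Passed to [run_threshold_session()] / [quest_init()].
#' @return A tibble of threshold results (3 rows per subject).
#' @export
#' @examples
#' res <- simulate_threshold_study(4, n_trials = 16, seed = 1)
#' dplyr::count(res, condition)
simulate_threshold_study <- function(n_subjects, true_threshold = -1.5,
                                     elevation_saccade = 1.96,
                                     elevation_after = 0.78,
                                     subject_sd = 0.2, n_trials = 64,
                                     group = NULL, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  conditions <- c("fixation", "saccade", "after_saccade")
  elev <- c(fixation = 0, saccade = elevation_saccade,
            after_saccade = elevation_after)
  if (!is.null(group)) group <- rep_len(group, n_subjects)
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    base <- rnorm(1, true_threshold, subject_sd)
    order_i <- if (i %% 2 == 1) conditions else rev(conditions)
    res <- purrr::map_dfr(order_i, function(cond) {
      obs <- simulate_observer(base + elev[[cond]])
      run_threshold_session(obs, cond, n_trials = n_trials,
                            subject_id = sprintf("S%02d", i), ...)
    })
    if (!is.null(group)) res$group <- group[i]
    res
  })
}

#' Saccadic-suppression mixed model over threshold results
#'
#' Fits `log10_threshold ~ condition (+ group and its interactions) +
#' (1 | subject_id)` by REML and prunes non-contributing terms by the
#' `|t| < 2` rule (see [prune_model()]); the fixation condition is the
#' reference level, so condition coefficients are threshold elevations
#' during and right after saccades.
#'
#' @param results Tibble of threshold results (columns `subject_id`,
#'   `condition`, `log10_threshold`, optionally `group`).
#' @param prune Apply the pruning rule to the group terms.
#' @return A `saccade_model` (see [fit_mixed_model()]).
#' @export
suppression_model <- function(results, prune = TRUE) {
  stopifnot(all(c("subject_id", "condition", "log10_threshold")
                %in% names(results)))
  results <- dplyr::mutate(
    results,
    condition = factor(.data$condition,
                       levels = c("fixation", "saccade", "after_saccade"))
  )
  rhs <- if ("group" %in% names(results) &&
             dplyr::n_distinct(results$group) > 1) {
    "condition * group"
  } else {
    "condition"
  }
  fit <- fit_mixed_model(
    results, as.formula(paste("log10_threshold ~", rhs, "+ (1 | subject_id)"))
  )
  if (prune) prune_model(fit) else fit
}
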