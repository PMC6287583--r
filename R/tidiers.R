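#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted saccade model
#'
#' @param x A `saccade_model` from [fit_mixed_model()] and friends.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect coefficient: `term`,
#'   `estimate`, `conf.low`, `conf.high` (Wald 95%), `statistic` (t value)
#'   and `significant` (CI excludes zero).
#' @export
tidy.saccade_model <- function(x, ...) {
  dplyr::select(x$result, -"model_term")
}

#' @rdname tidy.saccade_model
#' @return For `glance()`: a one-row tibble with fit metadata (`n_obs`,
#'   `n_subjects`, `sigma`, `logLik`, `converged`, `singular`, `n_pruned`).
#' @export
glance.saccade_model <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_subjects = unname(x$n_groups[1]),
    sigma = stats::sigma(x$fit),
    logLik = as.numeric(stats::logLik(x$fit)),
    converged = x$converged,
    singular = x$singular,
    n_pruned = nrow(x$trace)
  )
}

#' @rdname tidy.saccade_model
#' @export
tidy.quest_state <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x$history),
    estimate = quest_estimate(x),
    posterior_sd = sqrt(sum(x$posterior * (x$grid - quest_estimate(x))^2)),
    grid_lower = min(x$grid),
    grid_upper = max(x$grid)
  )
}
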