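sim_lmm_data <- function(n_sub = 12, n_per = 20, slope = 2, noise = 1,
                         seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = rep(sprintf("S%02d", seq_len(n_sub)), each = n_per),
    intercept = rep(rnorm(n_sub, 0, 1), each = n_per),
    x = rnorm(n_sub * n_per),
    z = rnorm(n_sub * n_per)
  ) |>
    dplyr::mutate(y = intercept + slope * x + rnorm(dplyr::n(), 0, noise))
}

test_that("mixed-model wrapper reports Wald CIs and fit metadata", {
  d <- sim_lmm_data()
  m <- fit_mixed_model(d, y ~ x + (1 | subject_id))
  tab <- tidy(m)
  expect_named(tab, c("term", "estimate", "conf.low", "conf.high",
                      "statistic", "significant"))
  expect_true(all(tab$conf.low < tab$estimate & tab$estimate < tab$conf.high))
  expect_equal(tab$significant, tab$conf.low > 0 | tab$conf.high < 0)
  sl <- tab[tab$term == "x", ]
  expect_lt(abs(sl$estimate - 2), 3 * (sl$conf.high - sl$conf.low) / 3.92)
  g <- glance(m)
  expect_equal(g$n_obs, nrow(d))
  expect_equal(g$n_subjects, 12)
  expect_true(g$converged)
})

test_that("pruning respects the |t| < 2 rule and marginality", {
  d <- sim_lmm_data(slope = 3)
  m <- fit_mixed_model(d, y ~ x + (1 | subject_id))
  pruned <- prune_model(m)
  expect_equal(pruned$fixed, "x")          # strong term: fixed point
  expect_equal(nrow(pruned$trace), 0)

  m2 <- fit_mixed_model(d, y ~ x + z + (1 | subject_id))
  p2 <- prune_model(m2)
  expect_equal(p2$fixed, "x")              # pure-noise z removed
  expect_equal(p2$trace$removed, "z")
  expect_lt(abs(p2$trace$statistic), 2)
  # deterministic trace
  p2b <- prune_model(fit_mixed_model(d, y ~ x + z + (1 | subject_id)))
  expect_identical(p2$trace, p2b$trace)

  # strong interaction with null mains: marginality keeps the mains
  set.seed(2)
  d3 <- sim_lmm_data(slope = 0) |>
    dplyr::mutate(y = intercept + 5 * x * z + rnorm(dplyr::n(), 0, 1))
  p3 <- prune_model(fit_mixed_model(d3, y ~ x * z + (1 | subject_id)))
  expect_setequal(p3$fixed, c("x", "z", "x:z"))
  expect_equal(nrow(p3$trace), 0)
})

test_that("cluster bootstrap matches the normal closed form", {
  expect_equal(unname(bootstrap_ci(rep(3.5, 10), seed = 1)), c(3.5, 3.5))
  set.seed(4)
  x <- rnorm(100)
  ci <- bootstrap_ci(x, n_boot = 4000, seed = 5)
  want <- mean(x) + c(-1, 1) * qnorm(0.975) * sd(x) / 10
  expect_equal(unname(ci), want, tolerance = 0.05)
  expect_identical(bootstrap_ci(x, seed = 9), bootstrap_ci(x, seed = 9))
  expect_false(identical(bootstrap_ci(x, seed = 9), bootstrap_ci(x, seed = 10)))
  expect_error(bootstrap_ci(1))
})

test_that("Mann-Whitney agrees with enumeration and handles degeneracy", {
  x <- c(0, 1, 3); y <- c(2, 2, 4)
  res <- mann_whitney(x, y)
  expect_equal(res$u, oracle_u(x, y))
  expect_equal(res$u, unname(suppressWarnings(
    wilcox.test(x, y)$statistic)))
  # hand-computed tie-corrected Z for this fixture
  r <- rank(c(x, y))
  mu <- 4.5
  ties <- table(c(x, y))
  sigma <- sqrt(9 / 12 * (7 - sum(ties^3 - ties) / 30))
  expect_equal(res$z, (res$u - mu) / sigma)
  # no-ties fixtures: normal-approximation p tracks the exact enumeration p
  set.seed(8)
  for (i in 1:20) {
    v <- sample(100, 6)
    res_i <- mann_whitney(v[1:3], v[4:6])
    expect_equal(res_i$u, oracle_u(v[1:3], v[4:6]))
    expect_lt(abs(res_i$p - oracle_u_exact_p(v[1:3], v[4:6])), 0.25)
  }
  # identical groups: perfectly symmetric ranks
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$z, 0)
  # all-zero scores in both groups: degenerate null
  zero <- mann_whitney(rep(0, 14), rep(0, 11))
  expect_equal(zero$z, 0)
  expect_equal(zero$p, 1)
  expect_error(mann_whitney(numeric(0), 1))
})

test_that("questionnaire comparison returns per-item and total rows", {
  scores <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", 1:8),
    item = c("hallucinations", "spatial_shift", "motion")
  ) |>
    dplyr::mutate(
      group = ifelse(subject_id <= "S04", "control", "pd"),
      score = dplyr::case_when(
        item == "hallucinations" ~ 0,                      # all-zero item
        item == "spatial_shift" & group == "pd" ~ 2,
        TRUE ~ 1
      )
    )
  out <- questionnaire_test(scores, reference = "control")
  expect_setequal(out$item, c("hallucinations", "spatial_shift", "motion",
                              "total"))
  hall <- out[out$item == "hallucinations", ]
  expect_equal(hall$z, 0)
  expect_equal(hall$p, 1)
  shift <- out[out$item == "spatial_shift", ]
  expect_lt(shift$z, 0)   # controls score lower
  expect_equal(out$mean_control[out$item == "total"], 2 / 3)
  expect_error(questionnaire_test(dplyr::mutate(scores, group = "one")))
})

test_that("injected group-by-target-by-condition effects are recovered", {
  gen <- gen_params(cd_gain = 1, motor_gain_1 = 0.9,
                    dat_coupling = c(lambda = 0, gain = 0),
                    laterality_delta = c(lambda = 0, gain = 0),
                    invalid_rate = 0)
  coh <- simulate_cohort(gen, 10, 10, 20, seed = 14)
  err <- errors_long(preprocess_trials(coh$fixations), coh$subjects) |>
    dplyr::mutate(dx = dx - 20 * (group == "pd" & target == "T2" &
                                    condition == "Memory"))
  m <- fit_error_model(err, "dx")
  tri <- dplyr::filter(tidy(m), term == "grouppd:targetT2:conditionMemory")
  se <- (tri$conf.high - tri$conf.low) / (2 * qnorm(0.975))
  expect_lt(abs(tri$estimate - (-20)), 2 * se)
  expect_true(tri$significant)
})
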