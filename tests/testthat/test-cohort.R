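test_that("veridical zero-noise trials land exactly on both targets", {
  lay <- make_layout(screen_config(), "UR", 2)
  tr <- simulate_trial(lay, "Baseline", lambda = 1, gain_1 = 1, gain_2 = 1)
  expect_equal(c(tr$truth$e1_x, tr$truth$e1_y), c(lay$t1_x, lay$t1_y))
  expect_equal(c(tr$truth$e2_x, tr$truth$e2_y), c(lay$t2_x, lay$t2_y))
  expect_equal(nrow(tr$fixations), 4)
})

test_that("CD gain biases the second saccade per the hand arithmetic", {
  # second target directly below the first, as in the canonical arrangement
  lay <- tibble::tibble(quadrant = "UR", t2_index = 1L,
                        t1_x = 248.9, t1_y = 248.9, t2_x = 248.9, t2_y = 0)
  tr <- simulate_trial(lay, "Baseline", lambda = 1.2, gain_1 = 0.85)$truth
  e1 <- 0.85 * c(248.9, 248.9)
  e2 <- e1 + (c(248.9, 0) - 1.2 * e1)     # E2 = E1 + (T2 - lambda * E1)
  expect_equal(c(tr$e1_x, tr$e1_y), e1)
  expect_equal(c(tr$e2_x, tr$e2_y), e2)
  expect_equal(tr$e2_x - 248.9, -42.313, tolerance = 1e-3)  # inward
  tr8 <- simulate_trial(lay, "Baseline", lambda = 0.8, gain_1 = 0.85)$truth
  expect_gt(tr8$e2_x - 248.9, 0)                            # outward
})

test_that("horizontal second-target error decreases monotonically in lambda", {
  lay <- make_layout(screen_config(), "UR", 3)
  errs <- vapply(seq(0.6, 1.4, by = 0.1), function(lam) {
    simulate_trial(lay, "Baseline", lambda = lam, gain_1 = 0.85)$truth$e2_x -
      lay$t2_x
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("hypometric first saccades with veridical CD still hit the target", {
  lay <- make_layout(screen_config(), "UR", 2)
  tr <- simulate_trial(lay, "Memory", lambda = 1, gain_1 = 0.85)$truth
  expect_lt(tr$e1_x - lay$t1_x, 0)
  expect_lt(tr$e1_y - lay$t1_y, 0)
  expect_equal(c(tr$e2_x, tr$e2_y), c(lay$t2_x, lay$t2_y))
})

test_that("cohorts are counterbalanced, sized and seed-reproducible", {
  coh <- simulate_cohort(gen_params(), n_pd = 3, n_control = 3,
                         trials_per_condition = 5, seed = 7)
  counts <- dplyr::count(coh$trials, subject_id, condition)
  expect_true(all(counts$n == 5))
  expect_equal(nrow(coh$subjects), 6)
  first_cond <- coh$trials |>
    dplyr::group_by(subject_id) |>
    dplyr::slice_min(trial_id, n = 1) |>
    dplyr::pull(condition)
  expect_equal(first_cond, rep(c("Baseline", "Memory"), 3))

  coh2 <- simulate_cohort(gen_params(), 3, 3, 5, seed = 7)
  expect_identical(coh$fixations, coh2$fixations)
  expect_identical(coh$subjects, coh2$subjects)
  coh3 <- simulate_cohort(gen_params(), 3, 3, 5, seed = 8)
  expect_false(identical(coh$fixations, coh3$fixations))
})

test_that("subject covariates follow the group structure", {
  coh <- simulate_cohort(gen_params(), 10, 10, 2, seed = 3)
  sub <- coh$subjects
  ctrl <- sub[sub$group == "control", ]
  pd <- sub[sub$group == "pd", ]
  expect_true(all(is.na(ctrl$symptom_side)))
  expect_true(all(is.na(ctrl$dat_left)))
  expect_true(all(ctrl$motor_updrs == 0))
  expect_true(all(pd$symptom_side %in% c("left", "right", "symmetric")))
  expect_true(all(pd$dat_left > 0 & pd$dat_right > 0))
  expect_true(all(pd$motor_updrs >= 5))
  # binding deficit is contralateral to the symptomatic side
  left_sym <- pd[pd$symptom_side == "left", ]
  right_sym <- pd[pd$symptom_side == "right", ]
  expect_true(all(left_sym$dat_right < left_sym$dat_left))
  expect_true(all(right_sym$dat_left < right_sym$dat_right))
})

test_that("the observer psychometric anchors at 81% with 2AFC limits", {
  expect_equal(weibull_p(-1.5, threshold = -1.5), 0.81)
  expect_equal(weibull_p(-30, threshold = -1.5), 0.5, tolerance = 1e-9)
  expect_equal(weibull_p(30, threshold = -1.5), 0.99, tolerance = 1e-9)
  x <- seq(-3, 0, by = 0.1)
  expect_true(all(diff(weibull_p(x, -1.5)) >= 0))
  expect_true(all(diff(weibull_p(seq(-1.8, -1.3, by = 0.05), -1.5)) > 0))

  set.seed(5)
  obs <- simulate_observer(-1.5)
  draws <- replicate(4000, obs(-1.5))
  expect_true(all(draws %in% c(0L, 1L)))
  expect_equal(mean(draws), 0.81, tolerance = 0.02)
})

test_that("per-subject CD gain estimates recover the latent values", {
  gen <- gen_params(cd_gain = 1, motor_gain_1 = 0.9, motor_gain_2 = 1,
                    motor_noise_cv = 0.02, memory_noise_deg = 0.2,
                    invalid_rate = 0, subject_sd = 0.08,
                    dat_coupling = c(lambda = 0, gain = 0),
                    laterality_delta = c(lambda = 0, gain = 0))
  coh <- simulate_cohort(gen, 10, 10, 30, seed = 21)
  est <- estimate_cd_gain(preprocess_trials(coh$fixations))
  d <- dplyr::left_join(est, coh$subjects, by = "subject_id")
  fit <- summary(lm(lambda_hat ~ lambda, data = d))$coefficients
  expect_lt(abs(fit["lambda", "Estimate"] - 1),
            2 * fit["lambda", "Std. Error"])
})
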