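test_that("ideal and actual saccade polar forms match the trig oracle", {
  straight <- ideal_second_saccade(248.9, 248.9, 248.9, 0)
  expect_equal(straight$amp, 248.9)
  expect_equal(straight$angle, -90)

  cases <- list(c(211.6, 211.6, 248.9, 0), c(220, 230, 270, 0))
  for (cs in cases) {
    got <- ideal_second_saccade(cs[1], cs[2], cs[3], cs[4])
    want <- oracle_polar(cs[1:2], cs[3:4])
    expect_equal(got$amp, want$amp)
    expect_equal(got$angle, want$angle)
  }
  # frozen values from the trig oracle
  expect_equal(ideal_second_saccade(211.6, 211.6, 248.9, 0)$amp, 214.864,
               tolerance = 1e-4)
  expect_equal(ideal_second_saccade(211.6, 211.6, 248.9, 0)$angle, -79.998,
               tolerance = 1e-4)
  expect_equal(ideal_second_saccade(220, 230, 270, 0)$amp, 235.372,
               tolerance = 1e-4)
  expect_equal(ideal_second_saccade(220, 230, 270, 0)$angle, -77.735,
               tolerance = 1e-4)
  # perfect compensation: actual equals ideal
  expect_equal(actual_second_saccade(211.6, 211.6, 248.9, 0),
               ideal_second_saccade(211.6, 211.6, 248.9, 0))
  # degenerate zero-length vector
  deg <- ideal_second_saccade(10, 10, 10, 10)
  expect_equal(deg$amp, 0)
  expect_true(is.na(deg$angle))

  set.seed(17)
  for (i in 1:1000) {
    f1 <- runif(2, -400, 400)
    p2 <- runif(2, -400, 400)
    got <- ideal_second_saccade(f1[1], f1[2], p2[1], p2[2])
    want <- oracle_polar(f1, p2)
    expect_equal(got$amp, want$amp, tolerance = 1e-12)
    expect_equal(got$angle, want$angle, tolerance = 1e-12)
  }
})

test_that("the amplified-CD worked example rotates the saccade inward", {
  f1 <- c(211.565, 211.565)
  f2 <- c(206.587, -42.313)
  t2 <- c(248.9, 0)
  actual <- actual_second_saccade(f1[1], f1[2], f2[1], f2[2])
  ideal <- ideal_second_saccade(f1[1], f1[2], t2[1], t2[2])
  expect_equal(actual$angle, oracle_polar(f1, f2)$angle)
  expect_equal(actual$angle, -91.12, tolerance = 0.01)
  expect_equal(ideal$angle, -80.0, tolerance = 0.01)
  expect_equal(actual$angle - ideal$angle, -11.12, tolerance = 0.01)
})

test_that("angle error sign tracks the CD regime at zero noise", {
  for (lam in c(1.2, 0.8, 1.0)) {
    coh <- simulate_cohort(zero_noise_gen(lam), 2, 2, 6, seed = 4)
    rec <- compensation_records(preprocess_trials(coh$fixations))
    if (lam > 1) expect_true(all(rec$angle_error < 0))
    if (lam < 1) expect_true(all(rec$angle_error > 0))
    if (lam == 1) expect_lt(max(abs(rec$angle_error)), 1e-9)
  }
})

test_that("centering behaves under grand and per-subject grouping", {
  rec <- tibble::tibble(
    subject_id = rep(c("A", "B"), each = 3),
    ideal_angle = c(-80, -80, -80, -100, -90, -95),
    ideal_amp = c(200, 210, 190, 300, 310, 290)
  )
  grand <- center_predictors(rec, "grand")
  expect_equal(mean(grand$centered_ideal_angle), 0)
  expect_equal(mean(grand$centered_ideal_amp), 0)
  expect_equal(grand$centered_ideal_angle,
               rec$ideal_angle - mean(rec$ideal_angle))

  per <- center_predictors(rec, "subject")
  expect_equal(per$centered_ideal_angle[1:3], rep(0, 3))  # constant within A
  expect_equal(per$centered_ideal_angle[4:6], c(-100, -90, -95) + 95)
  expect_false(isTRUE(all.equal(grand$centered_ideal_angle,
                                per$centered_ideal_angle)))
  expect_error(center_predictors(rec[0, ]))
})

test_that("laterality coding covers the truth table", {
  # symptom-side reference
  expect_equal(laterality_code("left", symptom_side = "left"), "ipsi")
  expect_equal(laterality_code("right", symptom_side = "left"), "contra")
  expect_equal(laterality_code("right", symptom_side = "right"), "ipsi")
  expect_equal(laterality_code("left", symptom_side = "right"), "contra")
  expect_equal(laterality_code("left", symptom_side = "symmetric"), "none")
  expect_equal(laterality_code("left", symptom_side = NA), "none")
  # low-binding-hemisphere reference: all 8 side x hemisphere cases
  grid <- expand.grid(side = c("left", "right"),
                      low = c("left", "right"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    dl <- if (grid$low[i] == "left") 1.2 else 1.8
    dr <- if (grid$low[i] == "left") 1.8 else 1.2
    want <- if (grid$side[i] == grid$low[i]) "ipsi" else "contra"
    expect_equal(
      laterality_code(grid$side[i], dat_left = dl, dat_right = dr,
                      reference = "low_dat_hemisphere"),
      want
    )
  }
  expect_equal(laterality_code("left", dat_left = 1.5, dat_right = 1.5,
                               reference = "low_dat_hemisphere"), "none")
})

test_that("compensation slope is unity under veridical CD", {
  gen <- gen_params(cd_gain = 1, motor_gain_1 = 0.9, motor_gain_2 = 1,
                    motor_noise_cv = 0.03, memory_noise_deg = 0,
                    invalid_rate = 0, subject_sd = 0,
                    dat_coupling = c(lambda = 0, gain = 0),
                    laterality_delta = c(lambda = 0, gain = 0))
  coh <- simulate_cohort(gen, 6, 6, 15, seed = 31)
  rec <- compensation_records(preprocess_trials(coh$fixations),
                              coh$subjects) |>
    center_predictors()
  m <- fit_compensation_model(rec, "actual_angle",
                              fixed = "centered_ideal_angle",
                              random = "(1 | subject_id)")
  slope <- dplyr::filter(tidy(m), term == "centered_ideal_angle")
  se <- (slope$conf.high - slope$conf.low) / (2 * qnorm(0.975))
  expect_lt(abs(slope$estimate - 1), 2 * se)
})
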