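cfg <- screen_config()

test_that("misdirected and missing saccades are screened out with reasons", {
  lay <- make_layout(cfg, "UR", 2)
  # first saccade into the opposite quadrant
  bad <- tibble::tibble(x = c(0, -lay$t1_x, lay$t2_x, 0),
                        y = c(0, -lay$t1_y, 0, 0))
  scr <- screen_trial(bad, lay, cfg)
  expect_false(scr$valid)
  expect_equal(scr$reason, "t1_misdirected")
  # exact aim is valid
  good <- tibble::tibble(x = c(0, lay$t1_x, lay$t2_x, 0),
                         y = c(0, lay$t1_y, 0, 0))
  expect_true(screen_trial(good, lay, cfg)$valid)
  # no saccade at all
  expect_equal(screen_trial(tibble::tibble(x = 0, y = 0), lay, cfg)$reason,
               "no_saccade")
  expect_equal(screen_trial(good[0, ], lay, cfg)$reason, "no_saccade")
  # reaches T1 but never heads to T2
  stuck <- tibble::tibble(x = c(0, lay$t1_x, lay$t1_x + 5),
                          y = c(0, lay$t1_y, lay$t1_y + 5))
  expect_equal(screen_trial(stuck, lay, cfg)$reason, "no_t2_saccade")
})

test_that("closest-fixation matching agrees with a brute-force scan", {
  lay <- tibble::tibble(t1_x = 248.9, t1_y = 248.9, t2_x = 248.9, t2_y = 0)
  fx <- tibble::tibble(x = c(240, 250, 0), y = c(240, 10, 0))
  m <- match_fixations(fx, lay)
  expect_equal(unname(m$f1), c(240, 240))
  expect_equal(unname(m$f2), c(250, 10))
  # single fixation: nothing can follow f1
  expect_null(match_fixations(tibble::tibble(x = 240, y = 240), lay)$f2)

  set.seed(13)
  for (i in 1:200) {
    fx <- tibble::tibble(x = runif(5, -400, 400), y = runif(5, -350, 350))
    m <- match_fixations(fx, lay)
    d1 <- (fx$x - lay$t1_x)^2 + (fx$y - lay$t1_y)^2
    i1 <- which.min(d1)
    expect_equal(m$i1, i1)
    if (i1 < 5) {
      d2 <- (fx$x - lay$t2_x)^2 + (fx$y - lay$t2_y)^2
      d2[seq_len(i1)] <- Inf
      expect_equal(m$i2, which.min(d2))
    } else {
      expect_null(m$f2)
    }
  }
})

test_that("signed errors follow the hypometria sign convention", {
  lay <- make_layout(cfg, "LL", 2)
  # undershoot T1; stop short of the meridian at T2 (12 px above, i.e. below
  # zero in LL screen coordinates)
  fx <- fixation_table(
    rbind(c(0, 0),
          c(0.95 * lay$t1_x, 0.95 * lay$t1_y),
          c(lay$t2_x, -12),
          c(0, 0)),
    quadrant = "LL", t2_index = 2
  )
  obs <- preprocess_trials(fx)
  expect_true(obs$valid)
  expect_lt(obs$t1_dx, 0)                       # hypometric T1: negative
  expect_lt(obs$t1_dy, 0)
  expect_equal(obs$t2_dy, 12)                   # hypometric T2: positive dy
  expect_equal(obs$t2_dx, 0)
  # exact landing gives zero error everywhere
  fx0 <- fixation_table(rbind(c(0, 0), c(lay$t1_x, lay$t1_y),
                              c(lay$t2_x, 0), c(0, 0)),
                        quadrant = "LL", t2_index = 2)
  obs0 <- preprocess_trials(fx0)
  expect_equal(c(obs0$t1_dx, obs0$t1_dy, obs0$t2_dx, obs0$t2_dy),
               rep(0, 4))
})

test_that("preprocessing is deterministic given its input", {
  coh <- simulate_cohort(gen_params(), 3, 3, 8, seed = 5)
  a <- preprocess_trials(coh$fixations)
  b <- preprocess_trials(coh$fixations)
  expect_identical(a, b)
})

test_that("exclusions match the generator's invalid labels", {
  coh <- simulate_cohort(gen_params(), 8, 8, 20, seed = 9)
  obs <- preprocess_trials(coh$fixations)
  lab <- dplyr::left_join(obs,
                          dplyr::select(coh$trials, trial_id, invalid),
                          by = "trial_id")
  sens <- mean(!lab$valid[lab$invalid])
  false_excl <- mean(!lab$valid[!lab$invalid])
  expect_gte(sens, 0.95)
  expect_lte(false_excl, 0.02)
  expect_equal(mean(!obs$valid), 0.06, tolerance = 0.35)
  # the vectorised pipeline agrees with the per-trial screening primitive
  lay_cache <- list()
  for (k in sample(nrow(obs), 25)) {
    tid <- obs$trial_id[k]
    rows <- coh$fixations[coh$fixations$trial_id == tid, ]
    lay <- make_layout(cfg, obs$quadrant[k], obs$t2_index[k])
    expect_equal(screen_trial(rows, lay, cfg)$valid, obs$valid[k])
  }
})

test_that("veridical simulations lose no trials and carry zero error", {
  fx <- make_fixtures("veridical", seed = 2)
  obs <- preprocess_trials(fx$fixations)
  expect_true(all(obs$valid))
  errs <- c(obs$t1_dx, obs$t1_dy, obs$t2_dx, obs$t2_dy)
  expect_lt(max(abs(errs)), 1e-9)
})
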