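test_that("cohort counts match the study conditions", {
  co <- small_cohort()
  expect_length(co$subjects, 6)
  expect_equal(n_cycles(co), 6 * 2)
  tiny <- simulate_cohort(cohort_spec(n_per_group = 1,
                                      cycles_per_subject = 1, seed = 3))
  expect_length(tiny$subjects, 2)
  expect_equal(n_cycles(tiny), 2)
  expect_setequal(unique(tiny$metadata$group), c("normal", "sarcopenia"))
})

test_that("the cohort is a pure function of the master seed", {
  a <- simulate_cohort(cohort_spec(n_per_group = 2, cycles_per_subject = 2,
                                   seed = 9))
  b <- simulate_cohort(cohort_spec(n_per_group = 2, cycles_per_subject = 2,
                                   seed = 9))
  expect_equal(a$metadata, b$metadata)
  expect_equal(tibble::as_tibble(a$subjects$N01$recording$left),
               tibble::as_tibble(b$subjects$N01$recording$left))
  c <- simulate_cohort(cohort_spec(n_per_group = 2, cycles_per_subject = 2,
                                   seed = 10))
  expect_false(identical(a$metadata$speed, c$metadata$speed))
})

test_that("ground-truth anchors sit at the profile's cycle fractions", {
  sim <- quiet_sim(cycles = 3)
  ev <- sim$truth$left
  n <- ev$next_hs[1] - ev$hs[1]
  expect_equal(ev$hr - ev$hs, rep(round(0.32 * n), 3))
  expect_equal(ev$fa - ev$hs, rep(round(0.77 * n), 3))
  expect_equal(ev$tv - ev$hs, rep(round(0.86 * n), 3))
})

test_that("planted group effects appear exactly in the realized parameters", {
  spec <- cohort_spec(n_per_group = 2, cycles_per_subject = 1, seed = 4,
                      noise_acc = 0, noise_gyro = 0,
                      normal = list(speed = c(1.2, 0), stride_time = c(1, 0),
                                    stance = c(0.62, 0),
                                    stance_drl = c(0, 0)),
                      sarcopenia = list(speed = c(1.0, 0),
                                        stride_time = c(1, 0),
                                        stance = c(0.62, 0),
                                        stance_drl = c(0.04, 0)))
  co <- simulate_cohort(spec)
  m <- co$metadata
  expect_equal(mean(m$speed[m$group == "normal"]) -
                 mean(m$speed[m$group == "sarcopenia"]), 0.2)
  expect_equal(m$stance_time_drl[m$group == "sarcopenia"], c(0.04, 0.04))
  # effect_scale = 0 removes all group mean differences
  null_spec <- cohort_spec(n_per_group = 2, cycles_per_subject = 1,
                           seed = 4, effect_scale = 0)
  expect_equal(null_spec$sarcopenia$speed[1], null_spec$normal$speed[1])
})

test_that("profiles that cannot embed the event morphology are refused", {
  expect_error(simulate_stride(gait_profile(stride_time = 0.3)),
               "too short")
  expect_error(gait_profile(stance_fraction = 0.45), "stance")
  expect_error(gait_profile(fa_frac = 0.9, tv_frac = 0.96), "dip|anchors")
})

test_that("event-detection error grows with sensor noise", {
  grid <- c(0, 0.05, 0.25)
  err <- purrr::map_dbl(grid, function(s) {
    e <- purrr::map_dbl(1:3, function(seed) {
      sim <- simulate_recording(
        gait_profile(noise_acc = s, noise_gyro = s, stance_drl = 0.03),
        cycles = 4, seed = seed)
      det <- detect_gait_events(sim$recording)
      cols <- c("hs", "o_to", "hr", "o_hs", "to", "fa", "tv", "next_hs")
      if (nrow(det$left) != nrow(sim$truth$left)) return(NA_real_)
      mean(abs(as.matrix(det$left[, cols]) -
                 as.matrix(sim$truth$left[, cols])))
    })
    mean(e, na.rm = TRUE)
  })
  expect_equal(err[1], 0)             # noise-free detection is exact
  expect_true(all(diff(err) >= -0.05))
})
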