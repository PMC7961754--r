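test_that("descriptive statistics match their closed forms", {
  d <- descriptive_stats(c(1, 5, 3), sample_rate = 1)
  expect_equal(d$max, 5); expect_equal(d$min, 1)
  expect_equal(d$dmm, 4); expect_equal(d$mdif, 4)
  expect_equal(d$ab_sum, 9)
  expect_equal(d$mmgr, 4)                  # argmax 2, argmin 1, dt = 1 s
  expect_equal(descriptive_stats(c(3, 4))$rms, sqrt(12.5))
  expect_equal(descriptive_stats(c(-2, 0, 2))$skewness, 0)
  const <- descriptive_stats(rep(2, 10))
  expect_equal(const$skewness, 0)
  expect_equal(const$kurtosis, 0)
  expect_true(attr(const, "constant"))
  expect_error(descriptive_stats(3), "at least 2")
  # excess kurtosis convention: near 0 for a large normal sample
  expect_lt(abs(descriptive_stats(withr::with_seed(1, rnorm(5000)))$kurtosis),
            0.2)
})

test_that("spatiotemporal parameters follow their event definitions", {
  fs <- 100
  mk_ev <- function(foot, shift = 0) {
    gait_events(data.frame(hs = 0, o_to = 10, hr = 32, o_hs = 50, to = 60,
                           fa = 77, tv = 86, next_hs = 100) + shift,
                foot, fs)
  }
  st <- spatiotemporal_params(mk_ev("left"), mk_ev("right"),
                              stride_length = 1.2)
  expect_equal(ncol(st), 23)
  expect_equal(st$stance_phase_r, 60)
  expect_equal(st$swing_phase_r, 40)
  expect_equal(st$cadence, 120)            # 1 s stride
  expect_equal(st$single_support_phase_r, 40)   # o_to..o_hs
  expect_equal(st$double_support_phase_r, 20)
  expect_equal(st$speed, 1.2)
  expect_equal(st$stance_phase_drl, 0)     # symmetric events
  expect_equal(st$stance_time_drl, 0)
  expect_equal(st$stance_phase_r + st$swing_phase_r, 100)
  expect_error(spatiotemporal_params(NULL, mk_ev("right")), "both feet")
})

test_that("noise-free extraction recovers the planted gait parameters", {
  prof <- gait_profile(noise_acc = 0, noise_gyro = 0, speed = 1.15,
                       stride_time = 1.1, stance_fraction = 0.63,
                       stance_drl = 0.04)
  sim <- simulate_recording(prof, cycles = 3, seed = 2)
  det <- detect_gait_events(sim$recording)
  st <- spatiotemporal_params(det$left, det$right,
                              recording = sim$recording)
  n <- sim$truth$left$next_hs[1] - sim$truth$left$hs[1]
  quantum <- 100 / n                       # one sample as % of the cycle
  expect_equal(st$cadence, 120 / (n / 100))
  expect_equal(st$speed, 1.15, tolerance = 0.02)
  expect_equal(st$stance_phase_l, 100 * sim$params$stance_left,
               tolerance = quantum)
  expect_equal(st$single_support_phase_r,
               100 * sim$params$single_support_right, tolerance = quantum)
  expect_equal(st$stance_time_drl, sim$params$stance_time_drl,
               tolerance = 1 / n)
  expect_equal(st$stance_phase_r + st$swing_phase_r, 100)
  expect_equal(st$stance_phase_l + st$swing_phase_l, 100)
})

test_that("computed stance-time asymmetry increases with the planted one", {
  drl <- c(0, 0.03, 0.06)
  got <- purrr::map_dbl(drl, function(d) {
    sim <- quiet_sim(cycles = 2, stance_drl = d)
    det <- detect_gait_events(sim$recording)
    spatiotemporal_params(det$left, det$right,
                          stride_length = 1.2)$stance_time_drl
  })
  expect_true(all(diff(got) > 0))
})

test_that("zero-velocity-update stride length is exact without noise", {
  still <- mk_trial <- imu_trial(
    tibble::tibble(acc_x = numeric(200), acc_y = 0, acc_z = 0, gyro_x = 0,
                   gyro_y = 0, gyro_z = 0), "left")
  ev <- gait_events(data.frame(hs = 0, o_to = 12, hr = 32, o_hs = 50,
                               to = 60, fa = 77, tv = 86, next_hs = 100),
                    "left")
  expect_equal(stride_length_zupt(still, ev)$stride_length, 0)

  prof <- gait_profile(noise_acc = 0, noise_gyro = 0, speed = 1.3 / 1.05)
  sim <- simulate_recording(prof, cycles = 3, seed = 1)
  sl <- stride_length_zupt(sim$recording$left, sim$truth$left)
  expect_equal(sl$stride_length, rep(1.3, 3), tolerance = 0.02 / 1.3)
  expect_true(all(sl$zupt_applied))

  prof2 <- gait_profile(noise_acc = 0, noise_gyro = 0,
                        speed = 2 * 1.3 / 1.05)
  sim2 <- simulate_recording(prof2, cycles = 2, seed = 1)
  sl2 <- stride_length_zupt(sim2$recording$left, sim2$truth$left)
  expect_equal(sl2$stride_length / sl$stride_length[1:2], c(2, 2),
               tolerance = 1e-6)
})

test_that("feature tables have the contracted shapes at any size or noise", {
  co <- small_cohort()
  ft7 <- build_feature_table(co, "seven")
  ft2 <- build_feature_table(co, "two")
  fst <- build_feature_table(co, "spatiotemporal")
  expect_length(feature_columns(ft7), 840)
  expect_length(feature_columns(ft2), 240)
  expect_length(feature_columns(fst), 23)
  expect_false(anyNA(ft7))
  expect_true(all(c("subject_id", "group") %in% names(ft7)))

  tiny <- simulate_cohort(cohort_spec(n_per_group = 1,
                                      cycles_per_subject = 1, seed = 2,
                                      noise_acc = 0.15, noise_gyro = 0.15))
  expect_length(feature_columns(build_feature_table(tiny, "seven",
                                                    use = "truth")), 840)
  agg <- aggregate_by_subject(ft7)
  expect_equal(nrow(agg), 6)
})

test_that("stride resampling is spline interpolation onto 100 points", {
  sim <- quiet_sim(cycles = 2, stride_time = 1.0)   # exactly 100 samples
  a <- resample_strides(sim$recording, sim$truth$right, n = 100)
  expect_equal(dim(a), c(2, 12, 100))
  m <- bilateral_matrix(sim$recording)
  src <- (sim$truth$right$hs[1] + 1):(sim$truth$right$next_hs[1])
  expect_equal(a[1, , ], t(m[src, ]), tolerance = 1e-9,
               ignore_attr = TRUE)                  # identity grid
  # linear ramps are reproduced exactly by a cubic spline
  z <- numeric(57)
  ramp <- imu_trial(tibble::tibble(acc_x = seq(0, 1, length.out = 57),
                                   acc_y = z, acc_z = z, gyro_x = z,
                                   gyro_y = z, gyro_z = z), "left")
  rampr <- imu_trial(tibble::as_tibble(ramp)[imu_channels()], "right")
  rec <- bilateral_recording(ramp, rampr)
  ev <- gait_events(data.frame(hs = 0, o_to = 10, hr = 18, o_hs = 25,
                               to = 30, fa = 40, tv = 45, next_hs = 56),
                    "right")
  out <- resample_strides(rec, ev, n = 100)
  expect_equal(dim(out)[3], 100)
  grid <- (0:99) * 56 / 100
  expect_equal(out[1, 1, ], grid / 56, tolerance = 1e-9)
})
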