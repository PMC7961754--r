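# helper: wrap channel vectors (0-based semantics) into a trial
mk_trial <- function(n = 100, acc_x = NULL, gyro_y = NULL, foot = "left") {
  z <- numeric(n)
  imu_trial(tibble::tibble(acc_x = acc_x %||% z, acc_y = z, acc_z = z,
                           gyro_x = z, gyro_y = gyro_y %||% z, gyro_z = z),
            foot = foot)
}

test_that("noise-free synthetic strides are recovered exactly by every rule", {
  sim <- quiet_sim(cycles = 4, stance_drl = 0.04, speed = 0.9,
                   stride_time = 1.12)
  det <- detect_gait_events(sim$recording)
  expect_equal(nrow(det$dropped), 0)
  cols <- c("hs", "o_to", "hr", "o_hs", "to", "fa", "tv", "next_hs")
  for (side in c("left", "right")) {
    expect_equal(as.matrix(det[[side]][, cols]),
                 as.matrix(sim$truth[[side]][, cols]),
                 ignore_attr = TRUE)
    expect_false(any(nzchar(det[[side]]$flags)))
  }
})

test_that("heel strike is the max first difference after the acc minimum", {
  # parabolic dip bottoming at sample 50, sharp step rise into sample 53
  acc <- numeric(100)
  acc[46:54] <- -2 * (1 - ((45:53 - 50) / 5)^2)     # 0-based 45..53
  acc[54:100] <- 1.5                                 # step rise at sample 53
  gy <- numeric(100); gy[19:23] <- c(1, 2, 4, 2, 1)  # swing peak for windowing
  tr <- mk_trial(acc_x = acc, gyro_y = gy)
  expect_equal(detect_hs(tr), 53)
  # degenerate flat signal: empty result plus a warning, never an error
  expect_warning(out <- detect_hs(mk_trial()), "no swing")
  expect_length(out, 0)
})

test_that("toe-off is the per-window gyro-y argmax, earliest on ties", {
  gy <- sin(pi * (0:99) / 140)                       # rises to max at 70
  gy[72:100] <- 0
  gy <- gy * (seq_len(100) > 50)
  tr <- mk_trial(gyro_y = c(gy[1:71], numeric(29)))
  expect_equal(detect_to(tr, cbind(50, 90)), 70)
  gy2 <- numeric(100); gy2[c(61, 71)] <- 3           # two equal maxima
  expect_equal(detect_to(mk_trial(gyro_y = gy2), cbind(50, 90)), 60)
  expect_warning(out <- detect_to(mk_trial(), cbind(50, 51)), "empty")
  expect_length(out, 0)
})

test_that("heel rise is the first 0.25 rad/s crossing after quiescence", {
  gy <- seq(0, 0.5, length.out = 101)[1:100]         # 0.005/sample ramp
  hr <- detect_hr(mk_trial(gyro_y = gy), hs = 0, to = 99, next_hs = 100)
  expect_equal(as.integer(hr), 50)                   # first sample >= 0.25
  expect_false(attr(hr, "fallback"))
  capped <- detect_hr(mk_trial(gyro_y = pmin(gy, 0.2)), hs = 0, to = 60,
                      next_hs = 100)
  expect_equal(as.integer(capped), 32)               # 32% anchor fallback
  expect_true(attr(capped, "fallback"))
})

test_that("feet adjacent is the rounded swing zero crossing of acc-x", {
  acc <- numeric(100); acc[62:77] <- 1; acc[78:100] <- -1
  fa <- detect_fa(mk_trial(acc_x = acc), to = 60, next_hs = 99, hs = 0)
  expect_equal(as.integer(fa), 77)                   # midway tie -> later
  expect_false(attr(fa, "fallback"))
  fb <- detect_fa(mk_trial(acc_x = abs(acc) + 0.1), to = 60, next_hs = 100,
                  hs = 0)
  expect_equal(as.integer(fb), 77)                   # 77% anchor fallback
  expect_true(attr(fb, "fallback"))
})

test_that("tibia vertical is where re-integrated velocity returns to zero", {
  gy <- numeric(100); gy[12:20] <- 1                 # zero from sample 20 on
  acc <- numeric(100); acc[22:31] <- 1; acc[32:41] <- -1
  tv <- detect_tv(mk_trial(acc_x = acc, gyro_y = gy), to = 10, fa = 28,
                  next_hs = 99, hs = 0)
  expect_equal(as.integer(tv), 40)                   # symmetric +a/-a lobes
  expect_false(attr(tv, "fallback"))
  fb <- detect_tv(mk_trial(acc_x = rep(0.5, 100), gyro_y = gy), to = 10,
                  fa = 28, next_hs = 100, hs = 0)
  expect_equal(as.integer(fb), 86)                   # 86% anchor fallback
  expect_true(attr(fb, "fallback"))
})

test_that("assembly requires the contralateral foot and reports drops", {
  sim <- quiet_sim(cycles = 2)
  expect_error(detect_gait_events(sim$recording$left),
               "contralateral trial required")
  ipsi <- list(strides = tibble::tibble(hs = 0L, hr = 32L, to = 60L,
                                        fa = 77L, tv = 86L, next_hs = 100L,
                                        flags = ""),
               hs = c(0L, 100L), to = 60L)
  contra_empty <- list(strides = tibble::tibble(), hs = integer(),
                       to = integer())
  out <- assemble_events(ipsi, contra_empty)
  expect_equal(nrow(out$left), 0)
  expect_equal(out$dropped$reason[1], "unmatched contralateral events")
})

test_that("phase segmentation tiles each stride without gap or overlap", {
  ev <- gait_events(data.frame(hs = 0, o_to = 12, hr = 32, o_hs = 50,
                               to = 60, fa = 77, tv = 86, next_hs = 100),
                    "left")
  seven <- segment_phases(ev, "seven")
  expect_equal(nrow(seven), 7)
  expect_equal(seven$start, c(0, 12, 32, 50, 60, 77, 86))
  expect_equal(seven$end, c(12, 32, 50, 60, 77, 86, 100))
  expect_equal(sum(seven$end - seven$start), 100)
  expect_equal(as.character(seven$phase[1]), "loading_response")

  two <- segment_phases(ev, "two")
  expect_equal(two$end - two$start, c(60, 40))

  # property: tiling holds for every detected stride of a simulated subject
  sim <- quiet_sim(cycles = 3, stance_drl = 0.02)
  det <- detect_gait_events(sim$recording)
  for (side in c("left", "right")) {
    seg <- segment_phases(det[[side]], "seven")
    for (s in unique(seg$stride)) {
      ph <- seg[seg$stride == s, ]
      expect_equal(ph$start[-1], ph$end[-nrow(ph)])
      expect_equal(ph$start[1], det[[side]]$hs[det[[side]]$stride == s])
      expect_equal(ph$end[nrow(ph)],
                   det[[side]]$next_hs[det[[side]]$stride == s])
    }
  }
})

test_that("default-noise detection stays within the 3-sample bound", {
  sim <- simulate_recording(gait_profile(stance_drl = 0.03), cycles = 4,
                            seed = 12)
  det <- detect_gait_events(sim$recording)
  cols <- c("hs", "to")
  err <- abs(as.matrix(det$left[, cols]) - as.matrix(sim$truth$left[, cols]))
  expect_lt(mean(err), 3)
})
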