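#' Define a single-subject gait waveform profile
#'
#' A `gait_profile` parameterizes the canonical stride waveform emitted by the
#' simulator: one pendulum-like forward-velocity hump in swing, a flat-foot
#' quiescent mid stance, a sagittal (gyro-y) push-off peak at toe-off, and the
#' pre-heel-strike dip/impact morphology in walking-direction acceleration.
#' The deterministic (noise-free) waveform satisfies every detector's defining
#' rule exactly at the planted event index: the x-acceleration minimum and
#' maximal first difference at heel strike, the gyro-y global maximum at
#' toe-off, the 0.25 rad/s gyro-y crossing at heel rise, the x-acceleration
#' zero crossing at feet adjacent, and the zero of forward velocity
#' (integrated from the in-swing gyro-y zero crossing) at tibia vertical.
#'
#' @param stride_time Stride (full cycle) duration in seconds.
#' @param speed Walking speed in m/s; stride length = `speed * stride_time`.
#' @param stance_fraction Mean stance fraction of the cycle (toe-off anchor).
#' @param stance_drl Planted absolute left-right stance-time difference in
#'   seconds; split evenly between the feet.
#' @param drl_sign `+1` puts the longer stance on the left foot (reducing
#'   right single support), `-1` the mirror image.
#' @param hr_frac,fa_frac,tv_frac Cycle-fraction anchors of heel rise, feet
#'   adjacent and tibia vertical (defaults 0.32, 0.77, 0.86).
#' @param noise_acc,noise_gyro White-noise standard deviations added to every
#'   accelerometer (g) and gyroscope (rad/s) sample.
#' @param sample_rate Sampling rate in Hz.
#' @param gyro_peak Gyro-y amplitude at toe-off (rad/s).
#' @return A list of class `gait_profile`.
#' @export
gait_profile <- function(stride_time = 1.05, speed = 1.10,
                         stance_fraction = 0.62, stance_drl = 0,
                         drl_sign = 1,
                         hr_frac = 0.32, fa_frac = 0.77, tv_frac = 0.86,
                         noise_acc = 0.05, noise_gyro = 0.05,
                         sample_rate = 100, gyro_peak = 4.0) {
  p <- list(stride_time = stride_time, speed = speed,
            stance_fraction = stance_fraction, stance_drl = stance_drl,
            drl_sign = sign(drl_sign %||% 1),
            hr_frac = hr_frac, fa_frac = fa_frac, tv_frac = tv_frac,
            noise_acc = noise_acc, noise_gyro = noise_gyro,
            sample_rate = sample_rate, gyro_peak = gyro_peak)
  for (nm in c("stride_time", "speed", "sample_rate", "gyro_peak")) {
    if (!is_number(p[[nm]]) || p[[nm]] <= 0) stopf("`%s` must be > 0", nm)
  }
  if (p$noise_acc < 0 || p$noise_gyro < 0) stopf("noise sd must be >= 0")
  half_drl <- stance_drl / (2 * stride_time)
  p$stance_left <- stance_fraction + p$drl_sign * half_drl
  p$stance_right <- stance_fraction - p$drl_sign * half_drl
  for (s in c(p$stance_left, p$stance_right)) {
    # contralateral toe-off must land after heel strike and before heel rise
    if (s <= 0.5 + 1e-9 || s >= 0.80) {
      stopf("per-side stance fraction %.3f outside supported range (0.5, 0.8)",
            s)
    }
    if (!(hr_frac < 0.5 && 0.5 < min(p$stance_left, p$stance_right))) {
      stopf("phase anchors must satisfy hr_frac < 0.5 < stance fraction")
    }
  }
  if (!(0 < hr_frac && hr_frac < stance_fraction && stance_fraction < fa_frac
        && fa_frac < tv_frac && tv_frac < 1)) {
    stopf("phase anchors must satisfy 0 < hr < stance < fa < tv < 1")
  }
  if (2 * tv_frac - fa_frac >= 0.97) {
    stopf("tv_frac/fa_frac leave no room for the pre-heel-strike dip")
  }
  structure(p, class = "gait_profile")
}

# anchor sample indices (0-based) of one stride of n samples for one side
stride_anchors <- function(profile, n, side) {
  stance <- if (side == "left") profile$stance_left else profile$stance_right
  to_i <- round(stance * n)
  fa_i <- round(profile$fa_frac * n)
  tv_i <- round(profile$tv_frac * n)
  hr_i <- round(profile$hr_frac * n)
  z <- round((to_i + fa_i) / 2)
  t_stop <- min(2L * tv_i - fa_i, n - 5L)
  if (n < 40L) stopf("stride of %d samples is too short to embed all events",
                     n)
  if (t_stop < tv_i + 2L) stopf("tv anchor too late for the heel-strike dip")
  stopifnot(0 < hr_i, hr_i < to_i, to_i < z, z < fa_i, fa_i < tv_i)
  list(n = n, hr = hr_i, to = to_i, z = z, fa = fa_i, tv = tv_i,
       t_stop = t_stop)
}

# forward (walking-direction) velocity of one canonical stride, unit peak.
# The peak plateaus over [fa-1, fa] so acceleration is exactly zero at the
# feet-adjacent sample (its detection rule is the x-acc zero crossing).
canon_velocity <- function(a) {
  k <- 0:(a$n - 1L)
  v <- numeric(a$n)
  rise <- k > a$to & k <= a$fa - 1L
  v[rise] <- sin((pi / 2) * (k[rise] - a$to) / (a$fa - 1L - a$to))^2
  v[k == a$fa] <- 1
  v_z <- sin((pi / 2) * (a$z - a$to) / (a$fa - 1L - a$to))^2
  desc <- k > a$fa & k <= a$tv
  v[desc] <- v_z + (1 - v_z) * cos((pi / 2) * (k[desc] - a$fa) / (a$tv - a$fa))
  land <- k > a$tv & k <= a$t_stop
  v[land] <- v_z * cos((pi / 2) * (k[land] - a$tv) / (a$t_stop - a$tv))^2
  # pre-heel-strike dip: acceleration minimum 4 samples before the impact,
  # sharpest rise (max first difference of acceleration) at the next HS
  v[a$n - 3:0] <- -0.2 * c(0.6, 1.0, 0.95, 0.9)
  v
}

# all six canonical channels for one stride; v scaled to v_max (m/s)
canon_stride <- function(a, v_max, gyro_peak) {
  k <- 0:(a$n - 1L)
  v <- canon_velocity(a) * v_max

  g <- numeric(a$n)
  lr_end <- max(3L, round(0.10 * a$n))
  q <- max(2L, round(0.04 * a$n))
  early <- k < lr_end
  g[early] <- -0.5 * sin(pi * k[early] / lr_end)       # loading transient
  ramp <- k >= (a$hr - q) & k < a$hr
  g[ramp] <- 0.25 * (k[ramp] - (a$hr - q)) / q          # reaches 0.25 at hr
  # linear rise to a cusp-like push-off peak at toe-off (sharp peaks keep the
  # argmax well-localized under sensor noise, as in real push-off transients)
  push <- k >= a$hr & k <= a$to
  g[push] <- 0.25 + (gyro_peak - 0.25) * (k[push] - a$hr) / (a$to - a$hr)
  fall <- k > a$to & k < a$z
  g[fall] <- gyro_peak *
    (1 - ((k[fall] - a$to) / (a$z - a$to))^0.7)          # zero exactly at z
  sw <- k >= a$z
  g[sw] <- -0.45 * gyro_peak * sin(pi * (k[sw] - a$z) / (a$n - a$z))

  swing <- k > a$to
  u <- (k - a$to) / (a$n - a$to)
  az <- numeric(a$n)
  az[k < 3] <- 0.3 * v_max * (1 - k[k < 3] / 3)         # impact transient
  az[swing] <- az[swing] + 0.35 * sin(2 * pi * u[swing])
  ay <- 0.08 * sin(2 * pi * k / a$n)
  gx <- numeric(a$n); gx[swing] <- 0.5 * sin(pi * u[swing])
  gz <- numeric(a$n); gz[swing] <- -0.35 * sin(pi * u[swing])

  list(v = v, gy = g, gx = gx, gz = gz, ay = ay, az = az)
}

# one foot's sample stream over `cycles` strides plus lead-in/extension.
# Returns channel vectors, the true velocity, and 0-based truth indices.
foot_stream <- function(profile, side, cycles, lead_pad = 0L) {
  fs <- profile$sample_rate
  n <- round(profile$stride_time * fs)
  a <- stride_anchors(profile, n, side)
  stride_len <- profile$speed * n / fs
  unit_disp <- sum(canon_velocity(a)) / fs
  v_max <- stride_len / unit_disp
  cs <- canon_stride(a, v_max, profile$gyro_peak)

  lead_from <- a$to - 3L                    # keep the push-off peak in lead-in
  lead <- (a$n - lead_from) + lead_pad
  ext <- min(12L, a$n)                      # impact + early stance tail
  idx <- c(rep(0L, lead_pad), (lead_from + 1L):a$n,
           rep(1:a$n, cycles), 1:ext)
  pad_mask <- c(rep(TRUE, lead_pad), rep(FALSE, length(idx) - lead_pad))
  take <- function(ch) { out <- ch[pmax(idx, 1L)]; out[pad_mask] <- 0; out }

  v <- take(cs$v)
  acc_x <- diff(c(0, v)) * fs / 9.81       # g units; telescopes back to v
  hs <- lead + (0:cycles) * a$n            # 0-based heel strikes
  list(acc_x = acc_x, acc_y = take(cs$ay), acc_z = take(cs$az),
       gyro_x = take(cs$gx), gyro_y = take(cs$gy), gyro_z = take(cs$gz),
       v = v, hs = hs, anchors = a, n = n, v_max = v_max,
       stride_length = stride_len)
}

#' Simulate a bilateral gait recording with ground-truth events
#'
#' Generates synchronized left- and right-foot 6-channel streams over
#' `cycles` gait cycles at the profile's sampling rate, with the right foot
#' phase-shifted by half a cycle, plus the per-stride ground-truth event
#' annotation for both feet. Additive white noise uses the supplied seed;
#' the same seed always reproduces the same recording.
#'
#' @param profile A [gait_profile()].
#' @param cycles Number of gait cycles (strides per foot).
#' @param seed Integer seed for the measurement noise.
#' @param subject_id Subject identifier stored on the trials.
#' @return A list with elements `recording` ([bilateral_recording()]),
#'   `truth` (list of left/right [gait_events()]), and `params` (one-row
#'   tibble of realized stride parameters).
#' @export
simulate_recording <- function(profile, cycles = 4, seed = 1,
                               subject_id = "sim") {
  stopifnot(inherits(profile, "gait_profile"), cycles >= 1)
  fs <- profile$sample_rate
  left <- foot_stream(profile, "left", cycles)
  offset <- round(left$n / 2)
  right0 <- foot_stream(profile, "right", cycles)
  # align right heel strikes to left hs + half stride on a shared clock
  pad_r <- left$hs[1] + offset - right0$hs[1]
  if (pad_r < 0) stopf("internal: negative right-foot alignment pad")
  right <- foot_stream(profile, "right", cycles, lead_pad = pad_r)

  len <- max(length(left$acc_x), length(right$acc_x))
  grow <- function(x, m) c(x, numeric(m - length(x)))
  chans <- imu_channels()
  lmat <- purrr::map(left[chans], grow, m = len)
  rmat <- purrr::map(right[chans], grow, m = len)

  noisy <- withr::with_seed(seed, {
    addn <- function(x, s) x + rnorm(length(x), 0, s)
    list(
      l = purrr::imap(lmat, ~ addn(.x, if (grepl("^acc", .y))
        profile$noise_acc else profile$noise_gyro)),
      r = purrr::imap(rmat, ~ addn(.x, if (grepl("^acc", .y))
        profile$noise_acc else profile$noise_gyro))
    )
  })
  trial_l <- imu_trial(tibble::as_tibble(noisy$l), "left", fs, subject_id)
  trial_r <- imu_trial(tibble::as_tibble(noisy$r), "right", fs, subject_id)
  rec <- bilateral_recording(trial_l, trial_r)

  truth <- list(
    left = truth_events(left, right, "left", fs),
    right = truth_events(right, left, "right", fs)
  )
  n <- left$n
  params <- tibble::tibble(
    subject_id = subject_id,
    stride_time = n / fs,
    speed = profile$speed,
    stride_length = left$stride_length,
    stance_left = left$anchors$to / n,
    stance_right = right$anchors$to / n,
    stance_time_drl = abs(left$anchors$to - right$anchors$to) / fs,
    single_support_right = (n - left$anchors$to) / n,
    single_support_left = (n - right$anchors$to) / n
  )
  list(recording = rec, truth = truth, params = params)
}

# ground-truth event table for one foot, using the contralateral stream for
# the opposite-foot events
truth_events <- function(ipsi, contra, side, fs) {
  cycles <- length(ipsi$hs) - 1L
  a <- ipsi$anchors
  b <- contra$anchors
  rows <- purrr::map_dfr(seq_len(cycles), function(k) {
    hs <- ipsi$hs[k]
    contra_to <- contra$hs + b$to        # contralateral toe-offs (all strides
    contra_to <- c(contra$hs[1] - b$n + b$to, contra_to)  # incl. lead-in one)
    contra_hs <- contra$hs
    in_stride <- function(x) x[x > hs & x < hs + a$n]
    tibble::tibble(
      stride = k, hs = hs,
      o_to = in_stride(contra_to)[1],
      hr = hs + a$hr,
      o_hs = in_stride(contra_hs)[1],
      to = hs + a$to, fa = hs + a$fa, tv = hs + a$tv,
      next_hs = hs + a$n
    )
  })
  gait_events(rows, foot = side, sample_rate = fs)
}

#' Simulate a single bilateral stride
#'
#' Convenience wrapper around [simulate_recording()] with one cycle; refuses
#' profiles whose stride would span fewer than 40 samples, since the event
#' morphology cannot be embedded in shorter strides.
#'
#' @inheritParams simulate_recording
#' @return As [simulate_recording()].
#' @export
simulate_stride <- function(profile, seed = 1, subject_id = "sim") {
  simulate_recording(profile, cycles = 1, seed = seed,
                     subject_id = subject_id)
}

#' Define a synthetic cohort specification
#'
#' The default specification emulates the study conditions of a 20-subject
#' bilateral insole cohort: 10 normal and 10 sarcopenic elderly women, four
#' gait cycles per subject (80 walking cycles in total), 100 Hz sampling.
#' Group-level effects are planted on walking speed (lower in sarcopenia),
#' stance fraction (higher), right single support (lower, via a longer left
#' stance) and left-right stance-time asymmetry (larger). `effect_scale`
#' scales all group mean differences (0 = null cohort for type-I-error
#' checks). Anthropometrics are drawn from per-group normal distributions
#' truncated at three standard deviations.
#'
#' @param n_per_group Subjects per group (default 10).
#' @param cycles_per_subject Gait cycles per subject (default 4).
#' @param seed Master seed; the full cohort is a pure function of it.
#' @param noise_acc,noise_gyro Sensor noise standard deviations (g, rad/s).
#' @param effect_scale Multiplier on all group mean differences.
#' @param sample_rate Sampling rate in Hz.
#' @param normal,sarcopenia Per-group gait parameter distributions: lists
#'   with `speed`, `stride_time`, `stance`, `stance_drl`, each `c(mean, sd)`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10, cycles_per_subject = 4, seed = 1,
                        noise_acc = 0.05, noise_gyro = 0.05,
                        effect_scale = 1, sample_rate = 100,
                        normal = list(speed = c(1.10, 0.08),
                                      stride_time = c(1.05, 0.05),
                                      stance = c(0.62, 0.010),
                                      stance_drl = c(0.010, 0.006)),
                        sarcopenia = list(speed = c(0.82, 0.08),
                                          stride_time = c(1.18, 0.06),
                                          stance = c(0.655, 0.012),
                                          stance_drl = c(0.045, 0.012))) {
  if (n_per_group < 1) stopf("`n_per_group` must be >= 1")
  if (cycles_per_subject < 1) stopf("`cycles_per_subject` must be >= 1")
  e <- effect_scale
  sarc <- purrr::map2(normal, sarcopenia, function(nv, sv) {
    c(nv[1] + e * (sv[1] - nv[1]), sv[2])
  })
  if (e > 0 && sarc$speed[1] >= normal$speed[1]) {
    stopf("sarcopenia mean speed must be below the normal group's")
  }
  structure(list(n_per_group = n_per_group,
                 cycles_per_subject = cycles_per_subject, seed = seed,
                 noise_acc = noise_acc, noise_gyro = noise_gyro,
                 effect_scale = effect_scale, sample_rate = sample_rate,
                 normal = normal, sarcopenia = sarc,
                 anthropometrics = default_anthropometrics()),
            class = "cohort_spec")
}

# per-group anthropometric means/sds (age yr, height cm, weight kg, feet mm,
# right/left grip kg) and right-leg-dominance probability
default_anthropometrics <- function() {
  list(
    normal = list(age = c(69.6, 3.0), height = c(153.5, 5.0),
                  weight = c(60.8, 5.1), feet = c(238.0, 5.1),
                  grasp_r = c(22.5, 2.6), grasp_l = c(22.3, 2.8),
                  p_right_dominant = 0.7),
    sarcopenia = list(age = c(71.1, 2.0), height = c(151.0, 4.8),
                      weight = c(52.7, 5.0), feet = c(232.0, 5.5),
                      grasp_r = c(14.4, 3.5), grasp_l = c(14.2, 3.7),
                      p_right_dominant = 0.6)
  )
}

#' Simulate a full bilateral cohort
#'
#' Draws one gait profile and one anthropometric record per subject from the
#' group distributions in the spec, simulates each subject's recording with
#' ground truth, and returns a `gait_cohort`: a list with `subjects` (each
#' holding `recording`, `truth`, `profile`), a `metadata` tibble (group
#' labels, anthropometrics, realized gait parameters) and the `spec`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `gait_cohort`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_per_group = 2,
#'                                       cycles_per_subject = 2, seed = 7))
#' cohort$metadata[, c("subject_id", "group", "speed")]
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("normal", "sarcopenia")
  subjects <- list()
  meta <- list()
  i <- 0L
  for (g in groups) {
    gp <- spec[[g]]
    an <- spec$anthropometrics[[g]]
    for (j in seq_len(spec$n_per_group)) {
      i <- i + 1L
      sid <- sprintf("%s%02d", if (g == "normal") "N" else "S", j)
      sub_seed <- derive_seed(spec$seed, i)
      drawn <- withr::with_seed(sub_seed, {
        drl_sign <- if (g == "sarcopenia") 1 else sample(c(-1, 1), 1)
        list(
          profile = gait_profile(
            stride_time = rnorm_trunc3(1, gp$stride_time[1], gp$stride_time[2]),
            speed = max(0.3, rnorm_trunc3(1, gp$speed[1], gp$speed[2])),
            stance_fraction = rnorm_trunc3(1, gp$stance[1], gp$stance[2]),
            stance_drl = abs(rnorm_trunc3(1, gp$stance_drl[1],
                                          gp$stance_drl[2])),
            drl_sign = drl_sign,
            noise_acc = spec$noise_acc, noise_gyro = spec$noise_gyro,
            sample_rate = spec$sample_rate),
          age = rnorm_trunc3(1, an$age[1], an$age[2]),
          height = rnorm_trunc3(1, an$height[1], an$height[2]),
          weight = rnorm_trunc3(1, an$weight[1], an$weight[2]),
          feet = rnorm_trunc3(1, an$feet[1], an$feet[2]),
          grasp_r = rnorm_trunc3(1, an$grasp_r[1], an$grasp_r[2]),
          grasp_l = rnorm_trunc3(1, an$grasp_l[1], an$grasp_l[2]),
          dominant_leg = if (runif(1) < an$p_right_dominant) "right" else
            "left"
        )
      })
      sim <- simulate_recording(drawn$profile, spec$cycles_per_subject,
                                seed = derive_seed(sub_seed, 1L),
                                subject_id = sid)
      subjects[[sid]] <- list(subject_id = sid, group = g,
                              recording = sim$recording, truth = sim$truth,
                              profile = drawn$profile)
      meta[[sid]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = sid, group = g, age = drawn$age,
                       height = drawn$height, weight = drawn$weight,
                       feet = drawn$feet, grasp_r = drawn$grasp_r,
                       grasp_l = drawn$grasp_l,
                       dominant_leg = drawn$dominant_leg),
        sim$params[, setdiff(names(sim$params), "subject_id")]
      )
    }
  }
  structure(list(subjects = subjects,
                 metadata = dplyr::bind_rows(meta), spec = spec),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf(
    "<gait_cohort> %d subjects (%s), %d cycles each, seed %d\n",
    length(x$subjects),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    x$spec$cycles_per_subject, x$spec$seed))
  invisible(x)
}

#' Total number of simulated walking cycles in a cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Integer count of gait cycles (one bilateral cycle per stride).
#' @export
n_cycles <- function(cohort) {
  sum(purrr::map_int(cohort$subjects, ~ nrow(.x$truth$left)))
}
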