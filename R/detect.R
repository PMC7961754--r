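#' Detector configuration
#'
#' Collects every threshold used by the rule-based event detectors. Defaults
#' are the published values: heel rise is the first gyro-y sample at or above
#' 0.25 rad/s after mid-stance quiescence, heel strike is the largest first
#' difference of walking-direction acceleration within the 10 samples
#' following its pre-stance minimum.
#'
#' @param hr_threshold Heel-rise gyro-y threshold in rad/s (default 0.25).
#' @param hr_quiescence Mid-stance quiescence gate in rad/s: gyro-y magnitude
#'   must fall below this after loading response before the heel-rise
#'   threshold is armed (default 0.05).
#' @param hs_window Heel-strike search window in samples after the
#'   acceleration minimum (default 10).
#' @param peak_height_frac Swing-peak finder: minimum peak height as a
#'   fraction of the global gyro-y maximum (default 0.5).
#' @param peak_min_dist Swing-peak finder: minimum peak spacing in seconds
#'   (default 0.4).
#' @param zupt_gyro_threshold Angular-rate magnitude (rad/s) below which a
#'   window counts as flat-foot stance for the zero-velocity update
#'   (default 0.3).
#' @param zupt_window Flat-foot detection window length in seconds
#'   (default 0.1).
#' @param fa_arm_frac Feet-adjacent arming level: the descending zero
#'   crossing is only accepted after `acc_x` has exceeded this fraction of
#'   its swing maximum (default 0.25), so near-zero flicker at the
#'   stance-swing boundary cannot trigger it.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(hr_threshold = 0.25, hr_quiescence = 0.05,
                            hs_window = 10, peak_height_frac = 0.5,
                            peak_min_dist = 0.4,
                            zupt_gyro_threshold = 0.3, zupt_window = 0.1,
                            fa_arm_frac = 0.25) {
  structure(list(hr_threshold = hr_threshold, hr_quiescence = hr_quiescence,
                 hs_window = as.integer(hs_window),
                 peak_height_frac = peak_height_frac,
                 peak_min_dist = peak_min_dist,
                 zupt_gyro_threshold = zupt_gyro_threshold,
                 zupt_window = zupt_window, fa_arm_frac = fa_arm_frac),
            class = "detector_config")
}

# local maxima of g above height, at least min_dist samples apart (greedy by
# height, ties to the earliest index); returns 0-based indices sorted
find_gyro_peaks <- function(g, min_height, min_dist) {
  n <- length(g)
  if (n < 3L) return(integer())
  cand <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n]) + 1L
  cand <- cand[g[cand] >= min_height]
  if (length(cand) == 0L) return(integer())
  cand <- cand[order(-g[cand], cand)]
  kept <- integer()
  for (i in cand) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept) - 1L
}

#' Detect heel strikes from walking-direction acceleration
#'
#' Gait cycles are first coarsely delimited by the swing-phase gyro-y
#' (push-off) peaks. Between consecutive peaks the pre-stance minimum of
#' `acc_x` is located, and the heel strike is the index of the maximum first
#' difference of `acc_x` within the `hs_window` samples that follow the
#' minimum (earliest index on ties).
#'
#' @param trial An [imu_trial()].
#' @param config A [detector_config()].
#' @return Strictly increasing 0-based sample indices; an empty vector (with
#'   a warning) when no swing peaks are found.
#' @export
detect_hs <- function(trial, config = detector_config()) {
  g <- trial$gyro_y
  x <- trial$acc_x
  fs <- trial_rate(trial)
  peaks <- find_gyro_peaks(g, config$peak_height_frac * max(g),
                           round(config$peak_min_dist * fs))
  if (length(peaks) == 0L) {
    warnf("no swing-phase gyro-y peaks found; no heel strikes detected")
    return(integer())
  }
  bounds <- c(peaks, length(x) - 1L)
  hs <- integer()
  for (i in seq_along(peaks)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    if (hi - lo < 3L) next
    win <- (lo + 1L):hi                       # 0-based candidate range
    min_idx <- win[which.min(x[win + 1L])]
    dmax <- min(min_idx + config$hs_window, length(x) - 1L)
    if (dmax <= min_idx) next
    cand <- (min_idx + 1L):dmax
    d <- x[cand + 1L] - x[cand]               # first difference at cand
    hs <- c(hs, cand[which.max(d)])
  }
  unique(sort(hs))
}

#' Detect toe-offs as per-cycle gyro-y maxima
#'
#' @param trial An [imu_trial()].
#' @param windows Two-column matrix or data frame of 0-based `(start, end)`
#'   pairs, one per cycle (typically consecutive heel strikes); the maximum
#'   is searched strictly inside each interval, earliest index on ties.
#' @return 0-based toe-off indices, one per non-empty window; empty windows
#'   are skipped with a warning.
#' @export
detect_to <- function(trial, windows) {
  g <- trial$gyro_y
  windows <- as.matrix(windows)
  out <- integer()
  for (i in seq_len(nrow(windows))) {
    lo <- windows[i, 1]; hi <- windows[i, 2]
    if (hi - lo < 2L) {
      warnf("toe-off window %d is empty; cycle skipped", i)
      next
    }
    win <- (lo + 1L):(hi - 1L)
    out <- c(out, win[which.max(g[win + 1L])])
  }
  out
}

#' Detect heel rise in a single stride
#'
#' After gyro-y magnitude has fallen below the quiescence gate (mid-stance
#' flat foot), the heel rise is the first sample in `(hs, to)` at or above
#' the 0.25 rad/s threshold. If the threshold is never crossed the 32%-cycle
#' anchor is returned with attribute `fallback = TRUE`.
#'
#' @param trial An [imu_trial()].
#' @param hs,to 0-based heel-strike and toe-off indices of the stride.
#' @param next_hs 0-based closing heel strike (used only for the fallback
#'   anchor).
#' @param config A [detector_config()].
#' @return A 0-based index with logical attribute `fallback`.
#' @export
detect_hr <- function(trial, hs, to, next_hs = NULL,
                      config = detector_config()) {
  g <- trial$gyro_y
  armed <- FALSE
  for (k in (hs + 1L):(to - 1L)) {
    gk <- g[k + 1L]
    if (!armed && abs(gk) <= config$hr_quiescence) armed <- TRUE
    if (armed && gk >= config$hr_threshold) {
      return(structure(k, fallback = FALSE))
    }
  }
  stride_n <- (next_hs %||% (hs + round((to - hs) / 0.62))) - hs
  structure(min(hs + round(0.32 * stride_n), to - 1L), fallback = TRUE)
}

#' Detect feet adjacent as the swing x-acceleration zero crossing
#'
#' Returns the first zero crossing of `acc_x` strictly inside `(to,
#' next_hs)`, linearly interpolated and rounded to the nearest sample. With
#' no crossing, the 77%-cycle anchor is returned with `fallback = TRUE`.
#'
#' @inheritParams detect_hr
#' @param to,next_hs 0-based toe-off and closing heel-strike indices.
#' @return A 0-based index with logical attribute `fallback`.
#' @export
detect_fa <- function(trial, to, next_hs, hs = NULL,
                      config = detector_config()) {
  x <- trial$acc_x
  arm_level <- config$fa_arm_frac * max(x[(to + 2L):(next_hs - 1L)])
  armed <- FALSE
  for (k in (to + 2L):(next_hs - 1L)) {
    x0 <- x[k]; x1 <- x[k + 1L]                 # samples k-1 and k (0-based)
    if (!armed && x0 >= arm_level) armed <- TRUE
    if (armed && x0 > 0 && x1 <= 0) {
      cross <- (k - 1L) + x0 / (x0 - x1)
      # nearest sample, half-up: a midway crossing belongs to the sample
      # where the acceleration has reached zero
      fa <- max(to + 1L, min(next_hs - 1L, floor(cross + 0.5)))
      return(structure(as.integer(fa), fallback = FALSE))
    }
  }
  hs0 <- hs %||% (next_hs - round((next_hs - to) / 0.38))
  structure(min(hs0 + round(0.77 * (next_hs - hs0)), next_hs - 1L),
            fallback = TRUE)
}

#' Detect tibia vertical from re-integrated swing velocity
#'
#' Forward velocity is obtained by integrating `acc_x` from the first in-swing
#' gyro-y zero crossing after toe-off (where the foot's forward speed is taken
#' as zero); tibia vertical is the first sample after feet adjacent where that
#' velocity returns to zero. With no zero return, the 86%-cycle anchor is
#' returned with `fallback = TRUE`.
#'
#' @inheritParams detect_fa
#' @param fa 0-based feet-adjacent index of the stride.
#' @return A 0-based index with logical attribute `fallback`.
#' @export
detect_tv <- function(trial, to, fa, next_hs, hs = NULL,
                      config = detector_config()) {
  g <- trial$gyro_y
  x <- trial$acc_x
  fs <- trial_rate(trial)
  z <- NA_integer_
  for (k in (to + 1L):(next_hs - 2L)) {
    if (g[k + 1L] <= 0) { z <- k; break }
  }
  if (!is.na(z)) {
    v <- 0
    for (k in (z + 1L):(next_hs - 1L)) {
      v <- v + x[k + 1L] * 9.81 / fs
      if (k > fa && v <= 0) return(structure(k, fallback = FALSE))
    }
  }
  hs0 <- hs %||% (next_hs - round((next_hs - to) / 0.38))
  structure(min(hs0 + round(0.86 * (next_hs - hs0)), next_hs - 1L),
            fallback = TRUE)
}

# detect hs/to/hr/fa/tv for one foot. Returns the per-stride table plus the
# full hs/to index vectors (including the toe-off of the partial cycle before
# the first heel strike, needed as a contralateral event by the other foot).
detect_one_foot <- function(trial, config) {
  empty <- list(strides = tibble::tibble(
    hs = integer(), hr = integer(), to = integer(), fa = integer(),
    tv = integer(), next_hs = integer(), flags = character()),
    hs = integer(), to = integer())
  hs <- detect_hs(trial, config)
  if (length(hs) < 2L) return(empty)
  g <- trial$gyro_y
  peaks <- find_gyro_peaks(g, config$peak_height_frac * max(g),
                           round(config$peak_min_dist * trial_rate(trial)))
  to_lead <- tail(peaks[peaks < hs[1]], 1L)
  windows <- cbind(hs[-length(hs)], hs[-1])
  strides <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    h <- windows[i, 1]; nh <- windows[i, 2]
    to <- detect_to(trial, windows[i, , drop = FALSE])
    if (length(to) == 0L) return(NULL)
    hr <- detect_hr(trial, h, to, nh, config)
    fa <- detect_fa(trial, to, nh, h, config)
    tv <- detect_tv(trial, to, fa, nh, h, config)
    flags <- c(if (attr(hr, "fallback")) "hr_fallback",
               if (attr(fa, "fallback")) "fa_fallback",
               if (attr(tv, "fallback")) "tv_fallback")
    tibble::tibble(hs = h, hr = as.integer(hr), to = to,
                   fa = as.integer(fa), tv = as.integer(tv), next_hs = nh,
                   flags = paste(flags, collapse = ","))
  })
  if (nrow(strides) == 0L) return(empty)
  list(strides = strides, hs = hs, to = sort(c(to_lead, strides$to)))
}

#' Pair ipsilateral and contralateral events into full per-stride event sets
#'
#' For each ipsilateral stride `[hs, next_hs)` the contralateral toe-off and
#' heel strike falling strictly inside it become `o_to` and `o_hs`. Strides
#' with unmatched contralateral events or any ordering violation are dropped
#' and reported.
#'
#' @param left,right Per-foot detections: lists with `strides` (tibble with
#'   columns `hs`, `hr`, `to`, `fa`, `tv`, `next_hs`, `flags`) and full
#'   0-based `hs` and `to` index vectors, as produced by the per-foot
#'   detector stage.
#' @param sample_rate Sampling rate in Hz.
#' @return A list with `left` and `right` [gait_events()] and a `dropped`
#'   tibble (`foot`, `stride`, `reason`).
#' @export
assemble_events <- function(left, right, sample_rate = 100) {
  pair_side <- function(ipsi, contra, side) {
    dropped <- list()
    rows <- list()
    for (i in seq_len(nrow(ipsi$strides))) {
      st <- ipsi$strides[i, ]
      inside <- function(x) unique(x[x > st$hs & x < st$next_hs])
      o_to <- inside(contra$to)
      o_hs <- inside(contra$hs)
      if (length(o_to) != 1L || length(o_hs) != 1L) {
        dropped[[length(dropped) + 1L]] <- tibble::tibble(
          foot = side, stride = i, reason = "unmatched contralateral events")
        next
      }
      idx <- c(st$hs, o_to, st$hr, o_hs, st$to, st$fa, st$tv, st$next_hs)
      if (any(diff(idx) <= 0)) {
        dropped[[length(dropped) + 1L]] <- tibble::tibble(
          foot = side, stride = i, reason = "event ordering violated")
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        hs = st$hs, o_to = o_to, hr = st$hr, o_hs = o_hs, to = st$to,
        fa = st$fa, tv = st$tv, next_hs = st$next_hs, flags = st$flags)
    }
    ev <- if (length(rows) > 0) dplyr::bind_rows(rows) else
      tibble::tibble(hs = integer(), o_to = integer(), hr = integer(),
                     o_hs = integer(), to = integer(), fa = integer(),
                     tv = integer(), next_hs = integer(),
                     flags = character())
    list(events = gait_events(ev, foot = side, sample_rate = sample_rate),
         dropped = dplyr::bind_rows(dropped))
  }
  l <- pair_side(left, right, "left")
  r <- pair_side(right, left, "right")
  list(left = l$events, right = r$events,
       dropped = dplyr::bind_rows(l$dropped, r$dropped))
}

#' Detect all seven gait events in a bilateral recording
#'
#' Runs the heel-strike, toe-off, heel-rise, feet-adjacent and tibia-vertical
#' detectors on both feet and pairs contralateral events via
#' [assemble_events()].
#'
#' @param recording A [bilateral_recording()]; both feet are required.
#' @param config A [detector_config()].
#' @return A list of class `gait_detection` with `left`/`right`
#'   [gait_events()] and a `dropped` tibble.
#' @export
detect_gait_events <- function(recording, config = detector_config()) {
  if (!inherits(recording, "bilateral_recording")) {
    stopf("contralateral trial required: pass a bilateral_recording")
  }
  l <- detect_one_foot(recording$left, config)
  r <- detect_one_foot(recording$right, config)
  out <- assemble_events(l, r, recording$sample_rate)
  structure(out, class = "gait_detection")
}

#' @export
print.gait_detection <- function(x, ...) {
  cat(sprintf("<gait_detection> left %d / right %d strides, %d dropped\n",
              nrow(x$left), nrow(x$right), nrow(x$dropped)))
  invisible(x)
}
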