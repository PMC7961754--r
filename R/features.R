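#' The ten descriptive statistics of a signal segment
#'
#' Computes max, min, sample standard deviation, absolute sum, RMS, excess
#' kurtosis, skewness (adjusted Fisher-Pearson, as in [e1071::skewness()]
#' type 2), the signed max-to-min gradient `mmgr = (max - min) /
#' ((argmax - argmin) / sample_rate)`, the range `dmm = max - min`, and the
#' largest absolute successive difference `mdif`. For a constant segment,
#' skewness and kurtosis are defined as 0 and the result carries attribute
#' `constant = TRUE`.
#'
#' @param x Numeric vector, length >= 2.
#' @param sample_rate Sampling rate in Hz (enters only `mmgr`).
#' @return A one-row tibble with columns `max`, `min`, `std`, `ab_sum`,
#'   `rms`, `kurtosis`, `skewness`, `mmgr`, `dmm`, `mdif`.
#' @examples
#' descriptive_stats(c(1, 5, 3), sample_rate = 1)
#' @export
descriptive_stats <- function(x, sample_rate = 100) {
  if (length(x) < 2L) stopf("segment must have at least 2 samples")
  constant <- var(x) == 0
  i_max <- which.max(x)
  i_min <- which.min(x)
  mmgr <- if (i_max == i_min) 0 else
    (max(x) - min(x)) / ((i_max - i_min) / sample_rate)
  out <- tibble::tibble(
    max = max(x), min = min(x),
    std = sd(x),
    ab_sum = sum(abs(x)),
    rms = sqrt(mean(x^2)),
    kurtosis = if (constant || length(x) < 4L) 0 else
      e1071::kurtosis(x, type = 2),
    skewness = if (constant || length(x) < 3L) 0 else
      e1071::skewness(x, type = 2),
    mmgr = mmgr,
    dmm = max(x) - min(x),
    mdif = max(abs(diff(x)))
  )
  attr(out, "constant") <- constant
  out
}

stat_names <- function() c("max", "min", "std", "ab_sum", "rms", "kurtosis",
                           "skewness", "mmgr", "dmm", "mdif")

# per-stride temporal quantities for one foot's event table (times in s)
stride_timings <- function(ev, fs) {
  tibble::tibble(
    stride = ev$stride,
    stride_time = (ev$next_hs - ev$hs) / fs,
    stance_time = (ev$to - ev$hs) / fs,
    swing_time = (ev$next_hs - ev$to) / fs,
    single_support_time = (ev$o_hs - ev$o_to) / fs,
    double_support_time = ((ev$o_to - ev$hs) + (ev$to - ev$o_hs)) / fs,
    step_time_contra = (ev$o_hs - ev$hs) / fs,
    step_time_ipsi = (ev$next_hs - ev$o_hs) / fs
  )
}

#' The 23 spatiotemporal gait parameters
#'
#' Computes the canonical 23-parameter set from bilateral event tables:
#' cadence (steps/min); stance, swing, single-support and double-support
#' phase (% of cycle) and time (s) per side; step time per side; stride
#' length (m); the left-right asymmetries `stance_phase_drl` (%) and
#' `stance_time_drl` (s) as absolute right-left differences; and speed
#' (stride length / cycle time). Percentages are computed per stride then
#' averaged; `stance% + swing% = 100` per side by construction.
#'
#' @param left,right [gait_events()] tables for the two feet (both
#'   required).
#' @param stride_length Optional numeric vector of per-stride lengths (m)
#'   for the right (reference) foot; if `NULL`, lengths are estimated with
#'   [stride_length_zupt()] from `recording`.
#' @param recording A [bilateral_recording()], required when
#'   `stride_length` is `NULL`.
#' @param config A [detector_config()] (flat-foot detection for the
#'   zero-velocity update).
#' @return A one-row tibble with the 23 named parameters.
#' @export
spatiotemporal_params <- function(left, right, stride_length = NULL,
                                  recording = NULL,
                                  config = detector_config()) {
  if (is.null(left) || is.null(right) || nrow(left) == 0 ||
      nrow(right) == 0) {
    stopf(paste("both feet are required: single/double support, step time",
                "and dRL parameters are undefined without the contralateral",
                "stride"))
  }
  fs <- attr(right, "sample_rate")
  tl <- stride_timings(left, fs)
  tr <- stride_timings(right, fs)
  if (is.null(stride_length)) {
    if (is.null(recording)) {
      stopf("supply `stride_length` or a `recording` to estimate it from")
    }
    stride_length <- stride_length_zupt(recording$right, right,
                                        config)$stride_length
  }
  pct <- function(x, stride) 100 * x / stride
  side_summary <- function(tt) {
    c(stance_phase = mean(pct(tt$stance_time, tt$stride_time)),
      swing_phase = mean(pct(tt$swing_time, tt$stride_time)),
      single_support_phase = mean(pct(tt$single_support_time,
                                      tt$stride_time)),
      double_support_phase = mean(pct(tt$double_support_time,
                                      tt$stride_time)),
      stance_time = mean(tt$stance_time),
      swing_time = mean(tt$swing_time),
      single_support_time = mean(tt$single_support_time),
      double_support_time = mean(tt$double_support_time))
  }
  r <- side_summary(tr)
  l <- side_summary(tl)
  tibble::tibble(
    cadence = mean(120 / c(tl$stride_time, tr$stride_time)),
    stance_phase_r = r[["stance_phase"]], stance_phase_l = l[["stance_phase"]],
    swing_phase_r = r[["swing_phase"]], swing_phase_l = l[["swing_phase"]],
    single_support_phase_r = r[["single_support_phase"]],
    single_support_phase_l = l[["single_support_phase"]],
    double_support_phase_r = r[["double_support_phase"]],
    double_support_phase_l = l[["double_support_phase"]],
    stance_time_r = r[["stance_time"]], stance_time_l = l[["stance_time"]],
    swing_time_r = r[["swing_time"]], swing_time_l = l[["swing_time"]],
    single_support_time_r = r[["single_support_time"]],
    single_support_time_l = l[["single_support_time"]],
    double_support_time_r = r[["double_support_time"]],
    double_support_time_l = l[["double_support_time"]],
    step_time_r = mean(tl$step_time_contra),
    step_time_l = mean(tr$step_time_contra),
    stride_length = mean(stride_length),
    stance_phase_drl = abs(r[["stance_phase"]] - l[["stance_phase"]]),
    stance_time_drl = abs(r[["stance_time"]] - l[["stance_time"]]),
    speed = mean(stride_length / tr$stride_time[seq_along(stride_length)])
  )
}

# the 12 bilateral channel names in canonical order
channel_names <- function() {
  c(paste0(imu_channels(), "_l"), paste0(imu_channels(), "_r"))
}

# 12 x T matrix of both feet's channels on the shared clock
bilateral_matrix <- function(recording) {
  len <- min(nrow(recording$left), nrow(recording$right))
  m <- cbind(as.matrix(tibble::as_tibble(recording$left)[1:len,
                                                         imu_channels()]),
             as.matrix(tibble::as_tibble(recording$right)[1:len,
                                                          imu_channels()]))
  colnames(m) <- channel_names()
  m
}

#' Per-stride descriptive-statistic features for two- or seven-phase modes
#'
#' Segments each reference-foot stride into phases ([segment_phases()]) and
#' computes the ten descriptive statistics of all 12 bilateral channels in
#' every phase: 240 features per stride in two-phase mode, 840 in
#' seven-phase mode. Columns are named `channel_phase_stat` (e.g.
#' `gyro_y_r_mid_stance_rms`). Strides carrying detector fallback flags are
#' excluded and counted in the `excluded` attribute.
#'
#' @param recording A [bilateral_recording()].
#' @param events A [gait_events()] for the reference foot (with opposite-foot
#'   events filled in).
#' @param mode `"two"` or `"seven"`.
#' @return A tibble with one row per retained stride (`stride` column plus
#'   240 or 840 feature columns).
#' @export
stride_features <- function(recording, events, mode = c("seven", "two")) {
  mode <- match.arg(mode)
  fs <- recording$sample_rate
  m <- bilateral_matrix(recording)
  keep <- !nzchar(events$flags)
  seg <- segment_phases(events[keep, ], mode)
  rows <- purrr::map(events$stride[keep], function(s) {
    ph <- seg[seg$stride == s, ]
    vals <- purrr::map(seq_len(nrow(ph)), function(j) {
      lo <- ph$start[j] + 1L            # 1-based, half-open [start, end)
      hi <- ph$end[j]
      purrr::map(as.data.frame(m[lo:hi, , drop = FALSE]), function(ch) {
        st <- descriptive_stats(ch, fs)
        setNames(as.numeric(st), stat_names())
      })
    })
    out <- unlist(unname(purrr::map2(vals, ph$phase, function(v, phase) {
      unlist(unname(purrr::imap(v, function(stats, ch) {
        setNames(stats, paste(ch, phase, names(stats), sep = "_"))
      })))
    })))
    c(stride = s, out)
  })
  tab <- tibble::as_tibble(do.call(rbind, rows))
  # canonical column order: channel (outer) x phase x stat (inner)
  ordered <- c("stride",
               as.vector(outer(stat_names(),
                               as.vector(outer(phase_labels(mode),
                                               channel_names(),
                                               function(p, ch)
                                                 paste(ch, p, sep = "_"))),
                               function(s, cp) paste(cp, s, sep = "_"))))
  tab <- tab[, ordered]
  attr(tab, "excluded") <- sum(!keep)
  tab
}

#' Build a cohort-level feature table
#'
#' Runs feature extraction for every subject of a synthetic or annotated
#' cohort and stacks the results with `subject_id` and `group` columns:
#' exactly 23 feature columns in `"spatiotemporal"` mode, 240 in `"two"`,
#' 840 in `"seven"`. By default events come from the rule-based detectors;
#' `use = "truth"` uses the simulator's ground-truth annotation instead.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param mode `"spatiotemporal"`, `"two"` or `"seven"`.
#' @param use `"detected"` or `"truth"` event source.
#' @param config A [detector_config()].
#' @return A tibble with identifier columns `subject_id`, `group` (and
#'   `stride` for the descriptive modes) followed by the feature columns;
#'   attribute `excluded` counts strides dropped for quality flags.
#' @export
build_feature_table <- function(cohort,
                                mode = c("seven", "two", "spatiotemporal"),
                                use = c("detected", "truth"),
                                config = detector_config()) {
  mode <- match.arg(mode)
  use <- match.arg(use)
  excluded <- 0L
  rows <- purrr::map(cohort$subjects, function(sub) {
    ev <- if (use == "truth") sub$truth else
      detect_gait_events(sub$recording, config)
    if (mode == "spatiotemporal") {
      out <- spatiotemporal_params(ev$left, ev$right,
                                   recording = sub$recording,
                                   config = config)
    } else {
      out <- stride_features(sub$recording, ev$right, mode)
      excluded <<- excluded + (attr(out, "excluded") %||% 0L)
    }
    dplyr::bind_cols(tibble::tibble(subject_id = sub$subject_id,
                                    group = sub$group)[rep(1, nrow(out)), ],
                     out)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  out
}

#' Feature column names of a feature table
#'
#' @param table A feature table from [build_feature_table()].
#' @return Character vector of feature column names (identifier columns
#'   `subject_id`, `group`, `stride` removed).
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "group", "stride"))
}

#' Average stride-level features per subject
#'
#' @param table A feature table with a `subject_id` column.
#' @return A tibble with one row per subject, features averaged.
#' @export
aggregate_by_subject <- function(table) {
  dplyr::summarise(dplyr::group_by(table, .data$subject_id, .data$group),
                   dplyr::across(dplyr::where(is.numeric) &
                                   !dplyr::any_of("stride"), mean),
                   .groups = "drop")
}

#' Resample strides to a fixed length by cubic-spline interpolation
#'
#' Interpolates every bilateral channel of each reference-foot stride onto
#' `n` uniformly spaced points over `[hs, next_hs)`; a stride of exactly `n`
#' samples is returned unchanged. Strides shorter than 4 samples are
#' excluded.
#'
#' @param recording A [bilateral_recording()].
#' @param events Reference-foot [gait_events()].
#' @param n Output samples per stride (default 100).
#' @return A numeric array `strides x 12 channels x n` with stride ids in
#'   `dimnames`; excluded stride count in attribute `excluded`.
#' @export
resample_strides <- function(recording, events, n = 100) {
  m <- bilateral_matrix(recording)
  keep <- (events$next_hs - events$hs) >= 4L &
    events$next_hs <= nrow(m)
  ev <- events[keep, ]
  out <- array(NA_real_,
               dim = c(nrow(ev), length(channel_names()), n),
               dimnames = list(ev$stride, channel_names(), NULL))
  for (i in seq_len(nrow(ev))) {
    len <- ev$next_hs[i] - ev$hs[i]
    src <- (ev$hs[i] + 1L):ev$next_hs[i]
    xout <- (0:(n - 1L)) * len / n
    for (j in seq_along(channel_names())) {
      out[i, j, ] <- spline(x = 0:(len - 1L), y = m[src, j],
                            xout = xout, method = "fmm")$y
    }
  }
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Resample every stride of a cohort for deep-learning input
#'
#' @inheritParams build_feature_table
#' @param n Output samples per stride.
#' @return A list with `x` (array `strides x 12 x n`), `subject_id`, `group`.
#' @export
cohort_tensors <- function(cohort, n = 100, use = c("detected", "truth"),
                           config = detector_config()) {
  use <- match.arg(use)
  xs <- list(); sid <- character(); grp <- character()
  for (sub in cohort$subjects) {
    ev <- if (use == "truth") sub$truth else
      detect_gait_events(sub$recording, config)
    a <- resample_strides(sub$recording, ev$right, n)
    if (dim(a)[1] == 0L) next
    xs[[length(xs) + 1L]] <- a
    sid <- c(sid, rep(sub$subject_id, dim(a)[1]))
    grp <- c(grp, rep(sub$group, dim(a)[1]))
  }
  x <- do.call(abind_first, xs)
  list(x = x, subject_id = sid, group = grp)
}

# bind arrays along the first dimension (avoids an abind dependency)
abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(purrr::map_int(parts, ~ dim(.x)[1]))
  out <- array(NA_real_, dim = c(total, d[2], d[3]),
               dimnames = list(NULL, dimnames(parts[[1]])[[2]], NULL))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    if (k > 0) out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}
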