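#' Construct a single-foot IMU trial
#'
#' An `imu_trial` is a tibble with one row per sample and columns `t` (seconds),
#' `acc_x`, `acc_y`, `acc_z` (acceleration, g) and `gyro_x`, `gyro_y`, `gyro_z`
#' (angular velocity, rad/s), plus metadata attributes. The axis convention is
#' x = anterior-posterior (walking direction), y = mediolateral (the sagittal
#' pitch rotation axis), z = vertical; heel-strike detection reads `acc_x` and
#' toe-off detection reads `gyro_y` under this convention.
#'
#' @param data A data frame with numeric columns `acc_x`, `acc_y`, `acc_z`,
#'   `gyro_x`, `gyro_y`, `gyro_z` (one row per sample). A `t` column, if
#'   present, is ignored and recomputed as `(row - 1) / sample_rate`.
#' @param foot `"left"` or `"right"`.
#' @param sample_rate Sampling rate in Hz (default 100).
#' @param subject_id Subject identifier string.
#' @return A tibble of class `imu_trial`.
#' @examples
#' raw <- tibble::tibble(
#'   acc_x = rnorm(50), acc_y = 0, acc_z = 1,
#'   gyro_x = 0, gyro_y = rnorm(50), gyro_z = 0
#' )
#' trial <- imu_trial(raw, foot = "left", subject_id = "s01")
#' @export
imu_trial <- function(data, foot = c("left", "right"), sample_rate = 100,
                      subject_id = "unknown") {
  foot <- match.arg(foot)
  if (!is_number(sample_rate) || sample_rate <= 0) {
    stopf("`sample_rate` must be a single positive number, got %s",
          deparse(sample_rate))
  }
  data <- as.data.frame(data)
  for (col in imu_channels()) {
    if (!col %in% names(data)) {
      stopf("IMU data is missing required column '%s'", col)
    }
    if (!is.numeric(data[[col]])) {
      stopf("IMU column '%s' is not numeric", col)
    }
    if (anyNA(data[[col]]) || any(!is.finite(data[[col]]))) {
      bad <- which(!is.finite(data[[col]]))
      stopf("IMU column '%s' contains non-finite values at row(s) %s",
            col, paste(head(bad, 5L), collapse = ", "))
    }
  }
  n <- nrow(data)
  if (n < 2L) stopf("IMU trial must contain at least 2 samples, got %d", n)
  out <- tibble::tibble(
    t = (seq_len(n) - 1) / sample_rate,
    acc_x = data$acc_x, acc_y = data$acc_y, acc_z = data$acc_z,
    gyro_x = data$gyro_x, gyro_y = data$gyro_y, gyro_z = data$gyro_z
  )
  structure(out,
            class = c("imu_trial", class(out)),
            foot = foot, sample_rate = sample_rate, subject_id = subject_id)
}

imu_channels <- function() {
  c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
}

#' Trial metadata accessors
#'
#' @param trial An [imu_trial()].
#' @return The foot side, sampling rate (Hz) or subject id of the trial.
#' @export
trial_foot <- function(trial) attr(trial, "foot")

#' @rdname trial_foot
#' @export
trial_rate <- function(trial) attr(trial, "sample_rate")

#' @rdname trial_foot
#' @export
trial_subject <- function(trial) attr(trial, "subject_id")

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> subject %s, %s foot, %g Hz, %d samples (%.2f s)\n",
              trial_subject(x), trial_foot(x), trial_rate(x), nrow(x),
              nrow(x) / trial_rate(x)))
  NextMethod()
}

#' Read a single-foot IMU recording from CSV
#'
#' The CSV must have a header with columns `acc_x,acc_y,acc_z,gyro_x,gyro_y,
#' gyro_z`, one row per sample. Angular velocity may be declared in deg/s and
#' is converted to rad/s on read.
#'
#' @inheritParams imu_trial
#' @param path Path to the CSV file.
#' @param gyro_unit Unit of the gyroscope columns on disk; `"rad/s"` (default)
#'   or `"deg/s"`.
#' @param acc_unit Unit of the accelerometer columns on disk; `"g"` (default)
#'   or `"m/s2"`.
#' @return An [imu_trial()].
#' @export
read_imu_csv <- function(path, foot = c("left", "right"), sample_rate = 100,
                         subject_id = "unknown",
                         gyro_unit = c("rad/s", "deg/s"),
                         acc_unit = c("g", "m/s2")) {
  gyro_unit <- match.arg(gyro_unit)
  acc_unit <- match.arg(acc_unit)
  if (!file.exists(path)) stopf("IMU file not found: '%s'", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(imu_channels(), names(raw))
  if (length(missing_cols) > 0L) {
    stopf("IMU file '%s' is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  for (col in imu_channels()) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stopf("IMU file '%s': column '%s' has non-numeric value(s) at row(s) %s",
            path, col, paste(head(bad, 5L), collapse = ", "))
    }
  }
  if (gyro_unit == "deg/s") {
    for (col in c("gyro_x", "gyro_y", "gyro_z")) {
      raw[[col]] <- raw[[col]] * pi / 180
    }
  }
  if (acc_unit == "m/s2") {
    for (col in c("acc_x", "acc_y", "acc_z")) raw[[col]] <- raw[[col]] / 9.81
  }
  imu_trial(raw, foot = foot, sample_rate = sample_rate,
            subject_id = subject_id)
}

#' Write a single-foot IMU trial to CSV
#'
#' Writes the six channel columns (internal units: g, rad/s); reading the file
#' back with [read_imu_csv()] reproduces the trial.
#'
#' @param trial An [imu_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(trial, path) {
  stopifnot(inherits(trial, "imu_trial"))
  readr::write_csv(trial[, imu_channels()], path, progress = FALSE)
  invisible(path)
}

#' Pair left and right foot trials into a bilateral recording
#'
#' Both trials must share one sampling rate; they are assumed to share a
#' common clock (sample index 0 simultaneous) unless `clock_offset` shifts
#' the right trial.
#'
#' @param left,right [imu_trial()] objects for the left and right foot.
#' @param clock_offset Offset of the right trial's clock relative to the
#'   left, in seconds (default 0; the synthetic generator always emits
#'   synchronized pairs).
#' @return A list of class `bilateral_recording` with elements `left`,
#'   `right`, `clock_offset`, `sample_rate`.
#' @export
bilateral_recording <- function(left, right, clock_offset = 0) {
  stopifnot(inherits(left, "imu_trial"), inherits(right, "imu_trial"))
  if (trial_foot(left) != "left" || trial_foot(right) != "right") {
    stopf("`left` must be a left-foot trial and `right` a right-foot trial")
  }
  if (!isTRUE(all.equal(trial_rate(left), trial_rate(right)))) {
    stopf("left (%g Hz) and right (%g Hz) trials have different sample rates",
          trial_rate(left), trial_rate(right))
  }
  span_l <- c(0, nrow(left) / trial_rate(left))
  span_r <- clock_offset + c(0, nrow(right) / trial_rate(right))
  if (min(span_l[2], span_r[2]) <= max(span_l[1], span_r[1])) {
    stopf("left and right trials have no overlapping time span")
  }
  structure(list(left = left, right = right, clock_offset = clock_offset,
                 sample_rate = trial_rate(left)),
            class = "bilateral_recording")
}

#' @export
print.bilateral_recording <- function(x, ...) {
  cat(sprintf(
    "<bilateral_recording> subject %s, %g Hz, left %d / right %d samples\n",
    trial_subject(x$left), x$sample_rate, nrow(x$left), nrow(x$right)))
  invisible(x)
}

#' Plot the channels of an IMU trial
#'
#' Draws the six channels in facets against time; detected or ground-truth
#' events can be overlaid as vertical lines.
#'
#' @param object An [imu_trial()].
#' @param events Optional [gait_events()] tibble whose index columns are drawn
#'   as vertical lines (converted to seconds with the trial's sampling rate).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot imu_trial
#' @export
autoplot.imu_trial <- function(object, events = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = imu_channels())
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s foot, subject %s", trial_foot(object),
                                  trial_subject(object)))
  if (!is.null(events)) {
    fs <- trial_rate(object)
    marks <- tidyr::pivot_longer(
      events[, c("hs", "o_to", "hr", "o_hs", "to", "fa", "tv")],
      dplyr::everything(), names_to = "event", values_to = "index")
    marks$t <- marks$index / fs
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$t,
                                              colour = .data$event),
                                 linewidth = 0.25, alpha = 0.7)
  }
  p
}
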