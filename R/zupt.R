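#' Stride length by strap-down integration with zero-velocity updates
#'
#' Integrates walking-direction acceleration over each stride and corrects
#' integration drift with an error-state Kalman filter: during detected
#' flat-foot intervals (angular-rate magnitude below
#' `config$zupt_gyro_threshold` over a `config$zupt_window`-second window) a
#' zero-velocity pseudo-measurement is applied and the position/velocity
#' error estimate is fed back. Acceleration channels are assumed
#' gravity-compensated (units g); the returned length is the horizontal
#' displacement per stride.
#'
#' @param trial An [imu_trial()].
#' @param events A [gait_events()] for the same foot (only `hs`/`next_hs`
#'   are used).
#' @param config A [detector_config()].
#' @return A tibble with columns `stride`, `stride_length` (m, `>= 0`) and
#'   `zupt_applied` (FALSE marks strides that fell back to uncorrected
#'   double integration).
#' @export
stride_length_zupt <- function(trial, events, config = detector_config()) {
  fs <- trial_rate(trial)
  acc <- trial$acc_x * 9.81
  gmag <- sqrt(trial$gyro_x^2 + trial$gyro_y^2 + trial$gyro_z^2)
  w <- max(1L, round(config$zupt_window * fs))
  # centered moving RMS of angular rate; stance = below threshold
  g2 <- stats::filter(gmag^2, rep(1 / w, w), sides = 2)
  g2[is.na(g2)] <- gmag[is.na(g2)]^2
  still <- sqrt(as.numeric(g2)) < config$zupt_gyro_threshold

  dt <- 1 / fs
  sigma_a <- 0.5                     # process noise on acceleration, m/s^2
  r_v <- 1e-4                        # zero-velocity measurement variance
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    # 1-based sample range; integration starts after the heel-strike sample
    # so the impact transient is not integrated (v = 0 boundary at HS)
    i0 <- events$hs[i] + 2L
    i1 <- events$next_hs[i]
    idx <- i0:i1
    p <- 0; v <- 0
    P <- diag(c(1e-6, 1e-6))
    Fm <- matrix(c(1, 0, dt, 1), 2)  # state [position; velocity]
    Q <- matrix(c(dt^4 / 4, dt^3 / 2, dt^3 / 2, dt^2), 2) * sigma_a^2
    H <- matrix(c(0, 1), 1)
    any_zupt <- FALSE
    for (k in idx) {
      v <- v + acc[k] * dt
      p <- p + v * dt
      P <- Fm %*% P %*% t(Fm) + Q
      if (still[k]) {
        any_zupt <- TRUE
        S <- P[2, 2] + r_v
        K <- P %*% t(H) / S
        err <- K * v                 # innovation: measured zero minus v
        p <- p - err[1]
        v <- v - err[2]
        P <- (diag(2) - K %*% H) %*% P
      }
    }
    tibble::tibble(stride = events$stride[i],
                   stride_length = max(0, abs(p)),
                   zupt_applied = any_zupt)
  })
}
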