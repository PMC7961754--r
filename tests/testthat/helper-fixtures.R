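# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# noise-free single-subject recording with left/right stance asymmetry
quiet_sim <- function(cycles = 4, seed = 1, ...) {
  simulate_recording(gait_profile(noise_acc = 0, noise_gyro = 0, ...),
                     cycles = cycles, seed = seed)
}

# the default-condition synthetic cohort (study-scale: 10 + 10 x 4 cycles)
default_cohort <- function() {
  memo("default_cohort", simulate_cohort(cohort_spec(seed = 20260925 %% 1000)))
}

# small cohort for shape/contract tests
small_cohort <- function() {
  memo("small_cohort",
       simulate_cohort(cohort_spec(n_per_group = 3, cycles_per_subject = 2,
                                   seed = 42)))
}

# detected events for every subject of a cohort (list per subject)
detect_cohort <- function(cohort, key = NULL) {
  build <- function() purrr::map(cohort$subjects,
                                 ~ detect_gait_events(.x$recording))
  if (is.null(key)) build() else memo(key, build())
}

# absolute |detected - truth| per event across a cohort, in samples
cohort_event_errors <- function(cohort, detections = NULL) {
  detections <- detections %||% detect_cohort(cohort)
  purrr::map_dfr(names(cohort$subjects), function(sid) {
    det <- detections[[sid]]
    purrr::map_dfr(c("left", "right"), function(side) {
      d <- det[[side]]
      g <- cohort$subjects[[sid]]$truth[[side]]
      if (nrow(d) != nrow(g)) return(NULL)
      cols <- c("hs", "o_to", "hr", "o_hs", "to", "fa", "tv", "next_hs")
      err <- abs(as.matrix(d[, cols]) - as.matrix(g[, cols]))
      out <- tibble::as_tibble(err)
      out$subject_id <- sid
      out$side <- side
      out$stride_n <- g$next_hs - g$hs
      out
    })
  })
}

`%||%` <- rlang::`%||%`
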