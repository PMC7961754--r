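#' Construct a per-stride gait event set
#'
#' A `gait_events` object is a tibble with one row per stride and the seven
#' event indices plus the closing heel strike: `hs`, `o_to`, `hr`, `o_hs`,
#' `to`, `fa`, `tv`, `next_hs`. Indices are 0-based sample positions on the
#' ipsilateral clock (time in seconds = index / sample rate); a stride is the
#' half-open interval `[hs, next_hs)`. Rows must satisfy the strict ordering
#' `hs < o_to < hr < o_hs < to < fa < tv < next_hs`.
#'
#' @param data Data frame with the eight integer index columns above. An
#'   optional `flags` character column records per-stride quality flags
#'   (comma-separated detector fallbacks), and an optional `stride` column
#'   numbers the strides.
#' @param foot `"left"` or `"right"`: the ipsilateral foot.
#' @param sample_rate Sampling rate in Hz.
#' @param n_samples Optional signal length used to bounds-check indices.
#' @return A tibble of class `gait_events`.
#' @examples
#' ev <- gait_events(
#'   data.frame(hs = 0, o_to = 12, hr = 32, o_hs = 50, to = 60,
#'              fa = 77, tv = 86, next_hs = 100),
#'   foot = "left", sample_rate = 100
#' )
#' @export
gait_events <- function(data, foot = c("left", "right"), sample_rate = 100,
                        n_samples = NULL) {
  foot <- match.arg(foot)
  data <- as.data.frame(data)
  cols <- event_names()
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stopf("gait events are missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  for (col in cols) {
    if (!is.numeric(data[[col]]) || anyNA(data[[col]])) {
      stopf("event column '%s' must be numeric and complete", col)
    }
  }
  m <- as.matrix(data[, cols])
  if (nrow(m) > 0L) {
    diffs <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    if (any(diffs <= 0)) {
      bad <- which(diffs <= 0, arr.ind = TRUE)[1L, ]
      pair <- sprintf("%s<%s", cols[bad[["col"]] + 1L], cols[bad[["col"]]])
      stopf("event ordering violated in stride %d: expected %s",
            bad[["row"]], pair)
    }
    if (any(m < 0)) stopf("event indices must be non-negative")
    if (!is.null(n_samples) && any(m > n_samples - 1L)) {
      stopf("event indices exceed signal bounds (%d samples)", n_samples)
    }
  }
  out <- tibble::as_tibble(data[, cols])
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  out$stride <- if ("stride" %in% names(data)) as.integer(data$stride) else
    seq_len(nrow(out))
  out$flags <- if ("flags" %in% names(data)) as.character(data$flags) else
    rep("", nrow(out))
  out <- out[, c("stride", cols, "flags")]
  structure(out, class = c("gait_events", class(tibble::tibble())),
            foot = foot, sample_rate = sample_rate)
}

event_names <- function() c("hs", "o_to", "hr", "o_hs", "to", "fa", "tv",
                            "next_hs")

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %s foot, %g Hz, %d stride(s), %d flagged\n",
              attr(x, "foot"), attr(x, "sample_rate"), nrow(x),
              sum(nzchar(x$flags))))
  NextMethod()
}

#' Write gait events to an annotation JSON file
#'
#' Serializes per-stride event indices together with event times in seconds;
#' [read_gait_events()] restores an identical structure. Refuses to write an
#' event set violating the ordering invariant.
#'
#' @param events A [gait_events()] tibble.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_gait_events <- function(events, path) {
  if (!inherits(events, "gait_events")) {
    events <- gait_events(events, foot = attr(events, "foot") %||% "left",
                          sample_rate = attr(events, "sample_rate") %||% 100)
  }
  fs <- attr(events, "sample_rate")
  strides <- purrr::pmap(events, function(stride, flags, ...) {
    idx <- list(...)
    list(stride = stride,
         indices = idx,
         times = purrr::map(idx, ~ .x / fs),
         flags = if (nzchar(flags)) strsplit(flags, ",")[[1]] else character())
  })
  payload <- list(foot = attr(events, "foot"), sample_rate = fs,
                  strides = strides)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read gait events from an annotation JSON file
#'
#' @param path Path to a file written by [write_gait_events()].
#' @return A [gait_events()] tibble.
#' @export
read_gait_events <- function(path) {
  if (!file.exists(path)) stopf("event file not found: '%s'", path)
  payload <- jsonlite::read_json(path)
  rows <- purrr::map_dfr(payload$strides, function(s) {
    idx <- tibble::as_tibble(purrr::map(s$indices, as.integer))
    idx$stride <- as.integer(s$stride)
    idx$flags <- paste(unlist(s$flags), collapse = ",")
    idx
  })
  gait_events(rows, foot = payload$foot, sample_rate = payload$sample_rate)
}

#' Segment strides into the two- or seven-phase decomposition
#'
#' The two-phase mode splits each stride into stance `[hs, to)` and swing
#' `[to, next_hs)`. The seven-phase mode uses the event boundaries
#' `hs, o_to, hr, o_hs, to, fa, tv, next_hs` mapped in order to the Whittle
#' labels loading response, mid stance, terminal stance, pre-swing, initial
#' swing, mid swing, terminal swing. Intervals are half-open `[start, end)`
#' and exactly tile each stride.
#'
#' @param events A [gait_events()] tibble.
#' @param mode `"two"` or `"seven"`.
#' @return A tibble with columns `stride`, `phase` (ordered factor), `start`,
#'   `end` (0-based sample indices, half-open).
#' @export
segment_phases <- function(events, mode = c("seven", "two")) {
  mode <- match.arg(mode)
  labels <- phase_labels(mode)
  per_stride <- purrr::pmap_dfr(events, function(stride, hs, o_to, hr, o_hs,
                                                 to, fa, tv, next_hs, ...) {
    bounds <- if (mode == "two") c(hs, to, next_hs) else
      c(hs, o_to, hr, o_hs, to, fa, tv, next_hs)
    tibble::tibble(stride = stride, phase = labels,
                   start = bounds[-length(bounds)], end = bounds[-1])
  })
  per_stride$phase <- factor(per_stride$phase, levels = labels)
  per_stride
}

phase_labels <- function(mode) {
  if (mode == "two") c("stance", "swing") else
    c("loading_response", "mid_stance", "terminal_stance", "pre_swing",
      "initial_swing", "mid_swing", "terminal_swing")
}
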