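#' Detect single-fluorophore blink frames in a corrected trace
#'
#' Frames with `Y > mu + 3 s` (the region calibration's offset and spread)
#' are grouped into blinking events — maximal runs of consecutive
#' above-threshold frames. The first frame of each event is removed, because
#' a fluorophore is generally not yet bright at the start of the frame in
#' which it switches on, so that frame underestimates the per-bright-frame
#' brightness. Frames at or before `min_frame` are removed as well: early in
#' the recording many fluorophores are still active, and only late events
#' can be attributed to a single fluorophore.
#'
#' @param y Corrected trace: numeric vector or data frame with `frame`,
#'   `value` columns.
#' @param calibration A `region_calibration` (or any list with `mu`, `s`).
#' @param min_frame Retain only frames strictly beyond this index (protocol
#'   default 2000; set 0 to keep all events).
#' @param n_sigma Threshold multiplier: frames with `Y > mu + n_sigma * s`
#'   are blink frames (default 3).
#' @return An object of class `blink_frames`: list with retained `frames`,
#'   the `threshold`, an `events` tibble (`start`, `end`), and the removal
#'   bookkeeping.
#' @export
detect_blink_frames <- function(y, calibration, min_frame = 2000,
                                n_sigma = 3) {
  if (is.data.frame(y)) y <- y$value
  stopifnot(is.numeric(calibration$mu), is.numeric(calibration$s))
  thr <- calibration$mu + n_sigma * calibration$s
  above <- which(y > thr)
  if (length(above) == 0) {
    return(structure(list(frames = integer(0), threshold = thr,
                          events = tibble::tibble(start = integer(0),
                                                  end = integer(0)),
                          removed_first = integer(0),
                          removed_early = integer(0)),
                     class = "blink_frames"))
  }
  brk <- c(0, which(diff(above) > 1), length(above))
  ev_start <- above[brk[-length(brk)] + 1]
  ev_end <- above[brk[-1]]
  retained <- setdiff(above, ev_start)
  removed_early <- retained[retained <= min_frame]
  retained <- retained[retained > min_frame]
  structure(list(frames = as.integer(retained), threshold = thr,
                 events = tibble::tibble(start = as.integer(ev_start),
                                         end = as.integer(ev_end)),
                 removed_first = as.integer(ev_start),
                 removed_early = as.integer(removed_early)),
            class = "blink_frames")
}

#' @export
print.blink_frames <- function(x, ...) {
  cat("<blink_frames>", length(x$frames), "retained frames from",
      nrow(x$events), "events (threshold", format(x$threshold), ")\n")
  invisible(x)
}

#' Mean single-fluorophore blink brightness
#'
#' Arithmetic mean of the corrected trace over the retained blink frames —
#' the empirical estimate of the per-bright-frame brightness `E(Y)`.
#'
#' @param y Corrected trace (vector or data frame with `value`).
#' @param blink_frames A [detect_blink_frames()] result.
#' @return Mean blink brightness (detector units).
#' @export
mean_blink_brightness <- function(y, blink_frames) {
  if (is.data.frame(y)) y <- y$value
  stopifnot(inherits(blink_frames, "blink_frames"))
  if (length(blink_frames$frames) == 0) {
    stop("no usable blink events in this trace", call. = FALSE)
  }
  mean(y[blink_frames$frames])
}

#' Simplified fluorophore count
#'
#' First-frame estimator: with all fluorophores bright at the start of the
#' recording, the first-frame signal is approximately `m` times the mean
#' single-fluorophore blink brightness, so `m ~ Y_1 / Ybar_blink`.
#'
#' @param y1 Corrected signal of the first frame.
#' @param ybar_blink Mean blink brightness ([mean_blink_brightness()]), > 0.
#' @return The estimated count (real; round for integer reporting).
#' @export
#' @examples
#' simplified_count(5000, 500)  # 10
simplified_count <- function(y1, ybar_blink) {
  if (!is.numeric(ybar_blink) || length(ybar_blink) != 1 ||
      ybar_blink <= 0) {
    stop("`ybar_blink` must be a single positive value", call. = FALSE)
  }
  y1 / ybar_blink
}

#' Simplified estimate from a full trace
#'
#' Convenience wrapper: detects blink frames, computes the mean blink
#' brightness and returns the first-frame count estimate with its
#' ingredients.
#'
#' @inheritParams detect_blink_frames
#' @return A list with `m_hat`, `m_int`, `y1`, `ybar_blink` and the
#'   `blink_frames` object, of class `simplified_estimate`.
#' @export
simplified_estimate <- function(y, calibration, min_frame = 2000) {
  v <- if (is.data.frame(y)) y$value else y
  bf <- detect_blink_frames(v, calibration, min_frame)
  yb <- mean_blink_brightness(v, bf)
  m <- simplified_count(v[1], yb)
  structure(list(m_hat = m, m_int = as.integer(round(m)), y1 = v[1],
                 ybar_blink = yb, blink_frames = bf),
            class = "simplified_estimate")
}

#' @export
print.simplified_estimate <- function(x, ...) {
  cat("<simplified_estimate> m_hat =", format(x$m_hat, digits = 4),
      " (Y1 =", format(x$y1), ", Ybar_blink =",
      format(x$ybar_blink, digits = 5), ")\n")
  invisible(x)
}
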