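#' Individual mobility measures
#'
#' Computes the three body-scale-normalised mobility statistics of the head
#' marker P0: *horizontal mobility* (SD of the horizontal coordinate divided
#' by the mean P0--P1 distance), a general indicator of how much a
#' participant moves; *vertical mobility* (SD of the vertical coordinate,
#' same normaliser), which tracks communicative nodding gestures; and their
#' ratio, overall movement relative to nodding. All three are unitless and
#' invariant to translation and to uniform rescaling of the video frame.
#'
#' When the vertical SD is zero the ratio is undefined and reported as
#' `NA`, never as an infinity.
#'
#' @param track A `processed_track` from [preprocess_track()].
#' @param sd_mode `"sample"` (n - 1 denominator, the default and what
#'   mainstream statistics packages compute) or `"population"`.
#' @return One-row tibble: `dyad_id`, `participant_id`, `condition`,
#'   `horizontal`, `vertical`, `hv_ratio`.
#' @export
mobility <- function(track, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(track, "processed_track"), nrow(track) >= 2)
  scale <- track_scale(track)
  sdev <- function(v) {
    s <- stats::sd(v)
    if (sd_mode == "population") s <- s * sqrt((length(v) - 1) / length(v))
    s
  }
  h <- sdev(track$p0_x) / scale
  v <- sdev(track$p0_y) / scale
  m <- track_meta(track)
  tibble::tibble(
    dyad_id = m$dyad_id, participant_id = m$participant_id,
    condition = m$condition,
    horizontal = h, vertical = v,
    hv_ratio = if (v > 0) h / v else NA_real_
  )
}

#' Frame-to-frame movement direction of the head marker
#'
#' For every consecutive frame pair the displacement of P0 is reduced to a
#' unit vector: direction of motion, stripped of amplitude. Frames where
#' the head did not move at all map to the zero vector and are flagged
#' `degenerate` — stillness is its own state rather than a continuation of
#' the previous direction.
#'
#' @param track A `processed_track`.
#' @return A `direction_series`: tibble with columns `step` (1..N-1), `vx`,
#'   `vy`, `degenerate`; attributes `fps`, `smoothed` (FALSE), `meta`.
#' @export
direction_field <- function(track) {
  stopifnot(inherits(track, "processed_track"), nrow(track) >= 2)
  dx <- diff(track$p0_x)
  dy <- diff(track$p0_y)
  nrm <- sqrt(dx^2 + dy^2)
  degen <- nrm == 0
  vx <- ifelse(degen, 0, dx / nrm)
  vy <- ifelse(degen, 0, dy / nrm)
  new_direction_series(
    tibble::tibble(step = seq_along(vx), vx = vx, vy = vy, degenerate = degen),
    fps = track_fps(track), smoothed = FALSE, meta = track_meta(track))
}

new_direction_series <- function(data, fps, smoothed, meta) {
  structure(tibble::as_tibble(data),
            fps = fps, smoothed = smoothed, meta = meta,
            class = c("direction_series", class(tibble::tibble())))
}

#' Zero-phase low-pass smoothing of a direction series
#'
#' Applies a Butterworth low-pass filter forward and backward
#' (zero phase, so neither partner's signal is lagged relative to the
#' other's) to the `vx` and `vy` components independently. Components are
#' not re-normalised to unit length afterwards: the pipeline normalises
#' first and smooths second, and smoothed direction vectors with norm < 1
#' simply encode less consistent motion.
#'
#' @param series A `direction_series`.
#' @param cutoff Cutoff frequency in Hz; must lie in (0, fps/2). Default
#'   2 Hz: conversational head gestures live below ~2 Hz at typical frame
#'   rates.
#' @param order Filter order, default 2.
#' @return The smoothed `direction_series` (`smoothed = TRUE`).
#' @export
lowpass <- function(series, cutoff = 2, order = 2) {
  stopifnot(inherits(series, "direction_series"))
  fps <- track_fps(series)
  if (!(cutoff > 0 && cutoff < fps / 2)) {
    rlang::abort("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  bf <- signal::butter(order, cutoff / (fps / 2), type = "low")
  out <- series
  out$vx <- filtfilt_padded(bf, series$vx)
  out$vy <- filtfilt_padded(bf, series$vy)
  attr(out, "smoothed") <- TRUE
  out
}

# forward-backward filtering with symmetric edge extension, so that the
# startup transient falls on the padding rather than the data; direction
# components are bounded and trend-free, where mirror padding is appropriate
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  p <- min(n - 1, 3 * (max(length(bf$b), length(bf$a)) - 1) * 4)
  if (p < 1) return(as.numeric(signal::filtfilt(bf, x)))
  head_ext <- x[(p + 1):2]
  tail_ext <- x[(n - 1):(n - p)]
  y <- as.numeric(signal::filtfilt(bf, c(head_ext, x, tail_ext)))
  y[(p + 1):(p + n)]
}
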