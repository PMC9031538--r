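#' Fraction of missing frames for a keypoint
#'
#' @param track A [keypoint_track].
#' @param keypoint Keypoint name.
#' @return Fraction in \[0, 1\]: missing frames / total frames.
#' @export
missing_fraction <- function(track, keypoint) {
  s <- kp_series(track, keypoint)
  mean(s$confidence == 0)
}

#' Decide whether a recording is usable
#'
#' A recording is excluded when the missing-value fraction of any required
#' keypoint strictly exceeds `threshold`. Recordings with small numbers of
#' missing values are kept and imputed downstream; recordings where the
#' pose estimator lost the head or torso for a sizeable part of the
#' conversation are dropped entirely.
#'
#' @inheritParams missing_fraction
#' @param threshold Maximum tolerated missing fraction, in (0, 1).
#'   Default 0.10.
#' @param keypoints Keypoints that must pass the check.
#' @return `TRUE` to keep the recording, `FALSE` to exclude it.
#' @export
check_exclusion <- function(track, threshold = 0.10,
                            keypoints = c("nose", "neck")) {
  stopifnot(threshold > 0, threshold < 1)
  fracs <- vapply(keypoints, function(kp) missing_fraction(track, kp), 0)
  all(fracs <= threshold)
}

#' Fill missing values by linear interpolation
#'
#' Interior gaps are filled linearly between the nearest observed
#' neighbours; leading and trailing gaps take the nearest observed value,
#' so the output has the input's length and no missing values. Observed
#' values pass through unchanged.
#'
#' @param x Numeric vector with `NA` gaps.
#' @return Gap-free numeric vector of the same length.
#' @export
interpolate_missing <- function(x) {
  if (all(is.na(x))) rlang::abort("all values missing; nothing to interpolate")
  as.numeric(zoo::na.approx(x, na.rm = FALSE, rule = 2))
}

#' Running median filter
#'
#' Centred running median with an odd window; near the edges the window is
#' truncated to the available samples, preserving length.
#'
#' @param x Numeric vector.
#' @param window Odd window size, between 1 and `length(x)`. Default 5.
#' @return Filtered vector, same length as `x`.
#' @export
running_median <- function(x, window = 5) {
  n <- length(x)
  if (window %% 2 == 0) rlang::abort("window must be odd")
  stopifnot(window >= 1, window <= n)
  h <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, 0)
}

#' Clean a keypoint track and compute its body scale
#'
#' Applies the cleaning chain to the head (P0) and torso (P1) markers: per
#' coordinate, missing values are linearly interpolated and a running
#' median filter (window 5 by default) suppresses estimator glitches. The
#' per-person movement scale is the mean Euclidean P0--P1 distance computed
#' after cleaning, so single-frame outliers cannot corrupt the normaliser.
#'
#' @param track A [keypoint_track] that passed [check_exclusion()].
#' @param median_window Odd window for [running_median()].
#' @param p0,p1 Names of the head and torso keypoints.
#' @return A `processed_track`: tibble with columns `frame`, `p0_x`, `p0_y`,
#'   `p1_x`, `p1_y` and attributes `scale` (pixels), `fps`, `meta`,
#'   `missing_fraction_p0`, `missing_fraction_p1`.
#' @export
preprocess_track <- function(track, median_window = 5,
                             p0 = "nose", p1 = "neck") {
  s0 <- kp_series(track, p0)
  s1 <- kp_series(track, p1)
  mf0 <- mean(s0$confidence == 0)
  mf1 <- mean(s1$confidence == 0)

  clean <- function(v) running_median(interpolate_missing(v), median_window)
  out <- tibble::tibble(
    frame = s0$frame,
    p0_x = clean(s0$x), p0_y = clean(s0$y),
    p1_x = clean(s1$x), p1_y = clean(s1$y)
  )
  scale <- mean(sqrt((out$p0_x - out$p1_x)^2 + (out$p0_y - out$p1_y)^2))
  if (!is.finite(scale) || scale <= 0) {
    rlang::abort("degenerate geometry: P0-P1 distance is zero")
  }
  structure(out,
    scale = scale,
    fps = track_fps(track),
    meta = track_meta(track),
    missing_fraction_p0 = mf0,
    missing_fraction_p1 = mf1,
    class = c("processed_track", class(tibble::tibble())))
}

#' @rdname n_frames
#' @export
track_scale <- function(track) attr(track, "scale")

#' @export
print.processed_track <- function(x, ...) {
  cat(sprintf("<processed_track> %d frames @ %g fps, scale %.2f px\n",
              nrow(x), track_fps(x), track_scale(x)))
  NextMethod()
}
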