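#' Pose-keypoint tracks
#'
#' A keypoint track holds the raw per-frame positions and detection
#' confidences of a set of body keypoints for one participant in one
#' recording. It is stored as a long tibble with one row per keypoint per
#' frame and columns `frame` (0-based), `keypoint`, `x`, `y` (pixels, image
#' coordinates: origin top-left, y increasing downward) and `confidence`
#' (unitless, in \[0, 1\]). The frame rate and recording metadata (dyad,
#' participant, condition) travel as attributes.
#'
#' A keypoint is *missing* on a frame iff its confidence is 0 (the
#' convention pose estimators use for undetected parts) or the record was
#' absent from the input; missing positions are stored as `NA`.
#'
#' @param data A data frame with columns `frame`, `keypoint`, `x`, `y`,
#'   `confidence`.
#' @param fps Frame rate in frames per second (> 0).
#' @param dyad_id,participant_id,condition Recording metadata. `condition`
#'   should be one of `"remote_mirror"`, `"remote_no_mirror"`,
#'   `"live_mirror"`, `"live_no_mirror"` (or `NA` when not applicable).
#' @return A tibble of class `keypoint_track`.
#' @export
keypoint_track <- function(data, fps, dyad_id = NA_character_,
                           participant_id = NA_character_,
                           condition = NA_character_) {
  stopifnot(is.data.frame(data))
  required <- c("frame", "keypoint", "x", "y", "confidence")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(fps) || length(fps) != 1 || is.na(fps) || fps <= 0) {
    rlang::abort("fps must be a single positive number")
  }
  if (!is.na(condition) && !condition %in% dyad_conditions()) {
    rlang::abort(paste0("unknown condition '", condition, "'"))
  }
  out <- tibble::as_tibble(data[required])
  out$frame <- as.integer(out$frame)
  out$keypoint <- as.character(out$keypoint)
  # normalise the missing convention: confidence 0 <=> NA position
  miss <- is.na(out$confidence) | out$confidence == 0 | is.na(out$x) | is.na(out$y)
  out$confidence[miss] <- 0
  out$x[miss] <- NA_real_
  out$y[miss] <- NA_real_
  out <- dplyr::arrange(out, .data$keypoint, .data$frame)

  lens <- table(out$keypoint)
  if (length(unique(as.integer(lens))) != 1) {
    rlang::abort("all keypoints must cover the same set of frames")
  }
  n <- as.integer(lens[[1]])
  if (n < 2) rlang::abort("a track needs at least 2 frames")
  if (anyDuplicated(out[c("keypoint", "frame")]) > 0) {
    rlang::abort("duplicate keypoint-frame records")
  }

  structure(out,
    fps = fps,
    meta = list(dyad_id = dyad_id, participant_id = participant_id,
                condition = condition),
    class = c("keypoint_track", class(tibble::tibble())))
}

dyad_conditions <- function() {
  c("remote_mirror", "remote_no_mirror", "live_mirror", "live_no_mirror")
}

#' @export
print.keypoint_track <- function(x, ...) {
  m <- track_meta(x)
  cat(sprintf("<keypoint_track> %d frames @ %g fps, %d keypoints\n",
              n_frames(x), track_fps(x),
              length(unique(x$keypoint))))
  cat(sprintf("  dyad=%s participant=%s condition=%s\n",
              m$dyad_id, m$participant_id, m$condition))
  NextMethod()
}

#' Track accessors
#'
#' @param track A `keypoint_track` or `processed_track`.
#' @return `n_frames()` the number of frames, `track_fps()` the frame rate,
#'   `track_meta()` the metadata list (`dyad_id`, `participant_id`,
#'   `condition`).
#' @export
n_frames <- function(track) {
  if (inherits(track, "keypoint_track")) {
    length(unique(track$frame))
  } else {
    nrow(track)
  }
}

#' @rdname n_frames
#' @export
track_fps <- function(track) attr(track, "fps")

#' @rdname n_frames
#' @export
track_meta <- function(track) attr(track, "meta")

# per-keypoint series in frame order; errors on unknown keypoint
kp_series <- function(track, keypoint) {
  sub <- track[track$keypoint == keypoint, , drop = FALSE]
  if (nrow(sub) == 0) {
    rlang::abort(paste0("unknown keypoint '", keypoint, "'"))
  }
  sub[order(sub$frame), c("frame", "x", "y", "confidence")]
}

#' Keypoint layout of the 25-point body model
#'
#' Maps keypoint indices of the common 25-point body layout to names; index
#' 0 is the nose tip (the head marker, P0) and index 1 the neck / mid-
#' shoulder point (the torso reference, P1). Pass a different character
#' vector to [read_keypoints()] for other layouts.
#'
#' @return Named character vector: element `i + 1` names keypoint index `i`.
#' @export
openpose_body25_layout <- function() {
  c("nose", "neck",
    "r_shoulder", "r_elbow", "r_wrist",
    "l_shoulder", "l_elbow", "l_wrist",
    "mid_hip", "r_hip", "r_knee", "r_ankle",
    "l_hip", "l_knee", "l_ankle",
    "r_eye", "l_eye", "r_ear", "l_ear",
    "l_bigtoe", "l_smalltoe", "l_heel",
    "r_bigtoe", "r_smalltoe", "r_heel")
}

#' Read a pose-keypoint time series
#'
#' Reads either a directory of OpenPose-style per-frame JSON files (one file
#' per frame, `people[[i]]$pose_keypoints_2d` as flattened x, y, confidence
#' triples) or a flat CSV with columns `frame, keypoint, x, y, confidence`.
#' Frames with no detected person become missing for all keypoints; when a
#' frame contains several detected people, the person with the highest
#' summed confidence is taken (recordings are expected to be single-person
#' crops).
#'
#' @param source Path to a directory of JSON files or to a CSV file.
#' @param fps Frame rate of the recording, frames per second.
#' @inheritParams keypoint_track
#' @param layout Character vector naming keypoint indices for the JSON
#'   format (default [openpose_body25_layout()]).
#' @param required Keypoints that must be detected on at least one frame
#'   (default the nose and neck markers used downstream).
#' @return A [keypoint_track].
#' @export
read_keypoints <- function(source, fps, dyad_id = NA_character_,
                           participant_id = NA_character_,
                           condition = NA_character_,
                           layout = openpose_body25_layout(),
                           required = c("nose", "neck")) {
  if (!file.exists(source)) rlang::abort(paste0("source not found: ", source))
  df <- if (dir.exists(source)) {
    read_openpose_dir(source, layout)
  } else {
    read_keypoint_csv(source)
  }
  if (nrow(df) == 0 || length(unique(df$frame)) == 0) rlang::abort("no frames")

  # make the reader total over frames: every keypoint on every frame
  frames <- sort(unique(df$frame))
  df <- tidyr::complete(df, frame = frames, keypoint = unique(df$keypoint),
                        fill = list(x = NA_real_, y = NA_real_, confidence = 0))
  for (kp in required) {
    sub <- df[df$keypoint == kp, , drop = FALSE]
    if (nrow(sub) == 0 || all(sub$confidence == 0)) {
      rlang::abort(paste0("required keypoint never detected: ", kp))
    }
  }
  keypoint_track(df, fps = fps, dyad_id = dyad_id,
                 participant_id = participant_id, condition = condition)
}

read_keypoint_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(),
    keypoint = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double(),
    confidence = readr::col_double()
  ))
  if (nrow(df) == 0) rlang::abort("no frames")
  df
}

read_openpose_dir <- function(path, layout) {
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0) rlang::abort("no frames")
  rows <- purrr::map(seq_along(files), function(i) {
    doc <- jsonlite::fromJSON(files[[i]], simplifyVector = FALSE)
    people <- doc$people
    if (is.null(people) || length(people) == 0) return(NULL)
    kp_lists <- purrr::map(people, ~ unlist(.x$pose_keypoints_2d))
    conf_sums <- purrr::map_dbl(kp_lists, ~ sum(.x[seq(3, length(.x), by = 3)]))
    flat <- kp_lists[[which.max(conf_sums)]]
    k <- length(flat) %/% 3
    idx <- seq_len(k) - 1L
    nm <- ifelse(idx < length(layout), layout[idx + 1L], paste0("kp", idx))
    tibble::tibble(
      frame = i - 1L,
      keypoint = nm,
      x = flat[3 * seq_len(k) - 2],
      y = flat[3 * seq_len(k) - 1],
      confidence = flat[3 * seq_len(k)]
    )
  })
  detected <- purrr::compact(rows)
  if (length(detected) == 0) rlang::abort("required keypoint never detected: nose")
  df <- dplyr::bind_rows(detected)
  # frames with no detected person must still appear (missing everywhere)
  all_frames <- tibble::tibble(frame = seq_along(files) - 1L)
  tidyr::crossing(all_frames, keypoint = unique(df$keypoint)) |>
    dplyr::left_join(df, by = c("frame", "keypoint")) |>
    dplyr::mutate(confidence = dplyr::coalesce(.data$confidence, 0))
}

#' Write a keypoint track to CSV
#'
#' Writes the flat CSV dialect (`frame, keypoint, x, y, confidence`); missing
#' frames are written with confidence 0 and are read back as missing, so
#' `read_keypoints()` on the written file reproduces the track's positions
#' and confidences exactly.
#'
#' @param track A [keypoint_track].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "keypoint_track"))
  out <- tibble::as_tibble(track)
  out$x[is.na(out$x)] <- 0
  out$y[is.na(out$y)] <- 0
  readr::write_csv(out, path)
  invisible(path)
}
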