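#' Configuration for the synthetic dyad generator
#'
#' The generator emulates the movement signal the analysis pipeline
#' consumes: two seated interlocutors whose head marker (nose) drifts with
#' mean-reverting posture sway and executes nodding bursts, with the
#' partners coupled through a probabilistic respond-to-a-nod mechanism
#' subject to transmission latency and jitter.
#'
#' The sway is band-limited Gaussian drift (white noise through a
#' second-order low-pass at `sway_cutoff_hz`, rescaled to `sway_sd`):
#' stationary and mean-reverting like postural sway of a seated speaker,
#' but with a tunable coherence time. Its default cutoff (1.5 Hz) makes
#' the idiosyncratic movement direction decorrelate in a few frames, below
#' the half-second minimum-line duration of the recurrence statistics,
#' while coupled nod episodes (half-cycle 1/(2 `nod_freq`) = 0.625 s at
#' the default 0.8 Hz) are long enough to register as diagonal lines.
#'
#' @param duration_s Recording length in seconds.
#' @param fps Frame rate (default 20).
#' @param sway_sd Stationary SD of the posture sway per axis, pixels.
#' @param sway_cutoff_hz Low-pass cutoff of the sway spectrum, Hz.
#' @param nod_rate Spontaneous nod events per second (Poisson).
#' @param nod_amplitude Peak vertical nod displacement, pixels.
#' @param nod_freq Nod oscillation frequency, Hz.
#' @param coupling Probability in \[0, 1\] that a partner's nod triggers a
#'   response nod.
#' @param response_delay_frames Mean response latency, frames.
#' @param jitter_frames SD of the response latency, frames.
#' @param exaggeration Multiplier on nod amplitude (models amplified
#'   nodding in front of a camera).
#' @param missing_rate Per-frame probability that pose detection fails.
#' @param seed Integer RNG seed; fixed seed gives byte-identical tracks.
#' @param base_p0,base_p1 Resting image positions (pixels) of the nose and
#'   mid-shoulder markers; their distance sets the body scale.
#' @param p1_noise_sd Frame-to-frame noise of the torso marker, pixels.
#' @return A `dyad_sim_config` list.
#' @export
dyad_sim_config <- function(duration_s = 60, fps = 20,
                            sway_sd = 5, sway_cutoff_hz = 1.5,
                            nod_rate = 0.3, nod_amplitude = 15, nod_freq = 0.8,
                            coupling = 0.5, response_delay_frames = 2,
                            jitter_frames = 0, exaggeration = 1,
                            missing_rate = 0, seed = 1L,
                            base_p0 = c(265, 120), base_p1 = c(265, 200),
                            p1_noise_sd = 0.5) {
  cfg <- list(duration_s = duration_s, fps = fps, sway_sd = sway_sd,
              sway_cutoff_hz = sway_cutoff_hz, nod_rate = nod_rate,
              nod_amplitude = nod_amplitude, nod_freq = nod_freq,
              coupling = coupling,
              response_delay_frames = response_delay_frames,
              jitter_frames = jitter_frames, exaggeration = exaggeration,
              missing_rate = missing_rate, seed = as.integer(seed),
              base_p0 = base_p0, base_p1 = base_p1,
              p1_noise_sd = p1_noise_sd)
  with(cfg, stopifnot(
    fps > 0, duration_s > 0, sway_sd >= 0, sway_cutoff_hz > 0,
    sway_cutoff_hz < fps / 2, nod_rate >= 0,
    nod_amplitude >= 0, nod_freq > 0, coupling >= 0, coupling <= 1,
    response_delay_frames >= 0, jitter_frames >= 0, exaggeration >= 0,
    missing_rate >= 0, missing_rate <= 1))
  structure(cfg, class = "dyad_sim_config")
}

#' Scenario presets for the generator
#'
#' `"face_to_face"` — near-immediate visibility of the partner: response
#' delay 2 frames, no jitter, natural nod amplitude. `"remote"` — video
#' mediation: response delay 8 frames, jitter SD 2 frames, nods exaggerated
#' by a factor 1.3.
#'
#' @param name `"face_to_face"` or `"remote"`.
#' @param ... Overrides passed on to [dyad_sim_config()].
#' @return A `dyad_sim_config`.
#' @export
scenario_preset <- function(name = c("face_to_face", "remote"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    face_to_face = list(response_delay_frames = 2, jitter_frames = 0,
                        exaggeration = 1.0),
    remote = list(response_delay_frames = 8, jitter_frames = 2,
                  exaggeration = 1.3))
  args <- utils::modifyList(defaults, list(...))
  do.call(dyad_sim_config, args)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# band-limited Gaussian sway path, sample SD exactly `sd`
sway_path <- function(n, sd, cutoff_hz, fps) {
  if (sd == 0) return(rep(0, n))
  pad <- 100L
  bf <- signal::butter(2, cutoff_hz / (fps / 2), type = "low")
  z <- as.numeric(signal::filtfilt(bf, stats::rnorm(n + 2 * pad)))
  z <- z[(pad + 1):(pad + n)]
  sd * (z - mean(z)) / stats::sd(z)
}

# damped-sinusoid nod waveform (~3 visible cycles), vertical displacement in px
nod_waveform <- function(amplitude, freq, fps) {
  len <- max(2L, round(3 / freq * fps))
  t <- (seq_len(len) - 1) / fps
  amplitude * sin(2 * pi * freq * t) * exp(-freq * t)
}

#' Simulate one dyadic recording
#'
#' Generates two coupled keypoint tracks. Each participant's torso marker
#' (neck) sits at a fixed base position plus small noise; the nose marker
#' adds band-limited posture sway per axis and vertical nod bursts
#' (damped sinusoids) arriving as a Poisson process. With probability
#' `coupling`, each spontaneous nod of one participant spawns a response
#' nod in the other after `response_delay_frames` plus Gaussian jitter;
#' responses do not chain. Overlapping nods superpose additively. With
#' `missing_rate > 0` frames are knocked out at random via
#' [inject_missing()].
#'
#' @param config A [dyad_sim_config()].
#' @param dyad_id,condition Metadata stamped on both tracks.
#' @return List with elements `a` and `b` ([keypoint_track]s for the two
#'   participants) and attribute `events` (the spontaneous and response nod
#'   onset frames actually used).
#' @export
simulate_dyad <- function(config, dyad_id = "dyad1", condition = NA_character_) {
  stopifnot(inherits(config, "dyad_sim_config"))
  n <- round(config$duration_s * config$fps)
  if (n < 2) rlang::abort("duration too short: need at least 2 frames")

  with_seed(config$seed, {
    wav <- nod_waveform(config$nod_amplitude * config$exaggeration,
                        config$nod_freq, config$fps)
    spont <- lapply(1:2, function(i) {
      k <- stats::rpois(1, config$nod_rate * config$duration_s)
      sort(ceiling(stats::runif(k, 0, n)))
    })
    # responses: partner answers a spontaneous nod after a jittered latency
    resp <- lapply(1:2, function(i) {
      other <- spont[[3 - i]]
      if (length(other) == 0) return(integer(0))
      answered <- other[stats::runif(length(other)) < config$coupling]
      if (length(answered) == 0) return(integer(0))
      lat <- config$response_delay_frames +
        stats::rnorm(length(answered), 0, config$jitter_frames)
      sort(answered + round(lat))
    })

    make_participant <- function(i, pid) {
      sway_x <- sway_path(n, config$sway_sd, config$sway_cutoff_hz, config$fps)
      sway_y <- sway_path(n, config$sway_sd, config$sway_cutoff_hz, config$fps)
      nod <- rep(0, n)
      for (onset in c(spont[[i]], resp[[i]])) {
        if (onset > n || onset + length(wav) - 1 < 1) next
        idx <- onset:min(n, onset + length(wav) - 1)
        idx <- idx[idx >= 1]
        nod[idx] <- nod[idx] + wav[idx - onset + 1]
      }
      frames <- 0:(n - 1)
      df <- dplyr::bind_rows(
        tibble::tibble(frame = frames, keypoint = "nose",
                       x = config$base_p0[1] + sway_x,
                       y = config$base_p0[2] + sway_y + nod,
                       confidence = 1),
        tibble::tibble(frame = frames, keypoint = "neck",
                       x = config$base_p1[1] + stats::rnorm(n, 0, config$p1_noise_sd),
                       y = config$base_p1[2] + stats::rnorm(n, 0, config$p1_noise_sd),
                       confidence = 1))
      keypoint_track(df, fps = config$fps, dyad_id = dyad_id,
                     participant_id = pid, condition = condition)
    }

    a <- make_participant(1, "A")
    b <- make_participant(2, "B")
    if (config$missing_rate > 0) {
      a <- inject_missing(a, config$missing_rate)
      b <- inject_missing(b, config$missing_rate)
    }
    structure(list(a = a, b = b),
              events = list(spont = spont, resp = resp))
  })
}

#' Knock out frames at random
#'
#' Emulates pose-detection failures: each frame is independently missing
#' (confidence 0, position `NA`, for all keypoints) with probability
#' `rate`.
#'
#' @param track A [keypoint_track].
#' @param rate Per-frame missing probability in \[0, 1\].
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The degraded [keypoint_track].
#' @export
inject_missing <- function(track, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(track)
  run <- function() {
    frames <- sort(unique(track$frame))
    drop <- frames[stats::runif(length(frames)) < rate]
    hit <- track$frame %in% drop
    out <- track
    out$confidence[hit] <- 0
    out$x[hit] <- NA_real_
    out$y[hit] <- NA_real_
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
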