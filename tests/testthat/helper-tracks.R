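# build a two-keypoint track from coordinate vectors
make_track <- function(p0x, p0y, p1x = NULL, p1y = NULL,
                       conf0 = NULL, conf1 = NULL, fps = 20, ...) {
  n <- length(p0x)
  p1x <- p1x %||% rep(0, n)
  p1y <- p1y %||% rep(2, n)
  conf0 <- conf0 %||% rep(1, n)
  conf1 <- conf1 %||% rep(1, n)
  df <- rbind(
    data.frame(frame = 0:(n - 1), keypoint = "nose", x = p0x, y = p0y,
               confidence = conf0),
    data.frame(frame = 0:(n - 1), keypoint = "neck", x = p1x, y = p1y,
               confidence = conf1))
  keypoint_track(df, fps = fps, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direction series straight from components (bypasses track plumbing)
make_direction_series <- function(vx, vy, fps = 20) {
  dyadcoord:::new_direction_series(
    tibble::tibble(step = seq_along(vx), vx = vx, vy = vy,
                   degenerate = vx == 0 & vy == 0),
    fps = fps, smoothed = FALSE, meta = list())
}

# simulate -> preprocess -> smooth -> embed -> recurrence, one dyad
crqa_from_config <- function(config, target_rr = 0.10) {
  pair <- simulate_dyad(config)
  emb <- lapply(pair, function(tr) {
    embed_direction(lowpass(direction_field(preprocess_track(tr))))
  })
  recurrence_matrix(emb[[1]], emb[[2]], target_rr = target_rr)
}

random_recurrence_matrix <- function(nr, nc, p) {
  as_recurrence_matrix(matrix(runif(nr * nc) < p, nr, nc))
}
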