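#' Time-delay embedding of a scalar series
#'
#' Row `t` of the result is `(s_t, s_{t+delay}, ..., s_{t+(dim-1)*delay})`,
#' so the output has `M = N - (dim - 1) * delay` rows.
#'
#' @param x Numeric series of length N.
#' @param delay Lag between embedding coordinates, in frames (>= 1).
#' @param dim Embedding dimension (>= 1).
#' @return M x dim numeric matrix.
#' @export
delay_embed <- function(x, delay, dim) {
  n <- length(x)
  stopifnot(delay >= 1, dim >= 1)
  m <- n - (dim - 1) * delay
  if (m < 1) rlang::abort("series too short for this delay/dimension")
  cols <- lapply(seq_len(dim) - 1L, function(k) x[(1 + k * delay):(m + k * delay)])
  do.call(cbind, cols)
}

# average mutual information between x_t and x_{t+lag}, equal-width bins
ami_lag <- function(x, lag, bins) {
  n <- length(x)
  a <- x[1:(n - lag)]
  b <- x[(1 + lag):n]
  rng <- range(x)
  if (rng[1] == rng[2]) rlang::abort("zero-entropy series")
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  ia <- pmin(pmax(findInterval(a, brk, all.inside = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(b, brk, all.inside = TRUE), 1L), bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / length(a)
  px <- rowSums(matrix(joint, bins, bins))
  py <- colSums(matrix(joint, bins, bins))
  pij <- matrix(joint, bins, bins)
  nz <- pij > 0
  sum(pij[nz] * log(pij[nz] / (px[row(pij)[nz]] * py[col(pij)[nz]])))
}

#' Embedding delay by the first minimum of average mutual information
#'
#' Estimates the average mutual information (AMI) between the series and
#' its lagged copy for lags 0..`max_lag` with an equal-width histogram
#' estimator and returns the lag of the first local minimum of the AMI
#' curve. If no local minimum occurs within `max_lag`, returns `max_lag`
#' with a warning.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag to scan; must be < length(x)/2.
#' @param bins Number of equal-width histogram bins (default 16).
#' @return Delay in frames.
#' @export
ami_delay <- function(x, max_lag, bins = 16) {
  stopifnot(max_lag >= 1, max_lag < length(x) / 2, bins >= 2)
  ami <- vapply(0:max_lag, function(l) ami_lag(x, l, bins), 0)
  for (k in seq_len(max_lag - 1)) {
    if (ami[k + 1] < ami[k] && ami[k + 1] <= ami[k + 2]) return(k)
  }
  rlang::warn("no local AMI minimum within max_lag; returning max_lag")
  max_lag
}

#' Embedding dimension by false nearest neighbours
#'
#' Kennel-style criterion: for each trial dimension m, each embedded
#' point's nearest neighbour (Euclidean, brute force) is checked in
#' dimension m + 1; the neighbour is *false* when the extra coordinate
#' stretches the pair by more than `rtol` relative to its distance, or
#' moves it beyond `atol` attractor sizes (series SD). The smallest m whose
#' false-neighbour fraction drops below 1% is returned; if none does by
#' `max_dim`, `max_dim` is returned with a warning.
#'
#' @param x Numeric series.
#' @param delay Embedding delay in frames.
#' @param max_dim Largest dimension to try (>= 2).
#' @param rtol,atol Kennel thresholds (defaults 10 and 2).
#' @param threshold Acceptable false-neighbour fraction (default 0.01).
#' @return Embedding dimension.
#' @export
fnn_dimension <- function(x, delay, max_dim = 10, rtol = 10, atol = 2,
                          threshold = 0.01) {
  stopifnot(delay >= 1, max_dim >= 2)
  n <- length(x)
  if (n < max_dim * delay + 1) rlang::abort("series too short to embed at max_dim")
  sd_x <- stats::sd(x)
  if (sd_x == 0) rlang::abort("zero-entropy series")
  for (m in seq_len(max_dim)) {
    emb <- delay_embed(x, delay, m)
    # keep points whose (m+1)-th coordinate exists
    keep <- nrow(emb) - delay
    if (keep < 2) break
    emb <- emb[seq_len(keep), , drop = FALSE]
    extra_coord <- x[seq_len(keep) + m * delay]
    d <- as.matrix(stats::dist(emb))
    diag(d) <- Inf
    nn <- max.col(-d, ties.method = "first")
    rd <- d[cbind(seq_len(keep), nn)]
    extra <- abs(extra_coord - extra_coord[nn])
    # numerically coincident states (exact revisits up to float error) are
    # true neighbours; without the floor their ~0/~0 distance ratio is noise
    floor_d <- 1e-8 * sd_x
    false_nn <- ifelse(rd > floor_d, extra / rd > rtol, extra > floor_d) |
      sqrt(rd^2 + extra^2) / sd_x > atol
    if (mean(false_nn) < threshold) return(m)
  }
  rlang::warn("false-neighbour fraction never fell below threshold; returning max_dim")
  max_dim
}

#' Concatenated x/y embedding of a direction series
#'
#' Embeds the horizontal and vertical direction components separately with
#' the same delay and dimension and concatenates the two embeddings
#' column-wise, giving `2 * dim` columns (8 at the defaults delay 7,
#' dimension 4). The embedded states are what cross-recurrence compares
#' between the two partners.
#'
#' @param series A `direction_series`.
#' @param delay Embedding delay in frames (default 7).
#' @param dim Per-coordinate embedding dimension (default 4).
#' @return An `embedded_series`: list with `vectors` (M x 2*dim matrix),
#'   `delay`, `dim`, `fps`, `meta`.
#' @export
embed_direction <- function(series, delay = 7, dim = 4) {
  stopifnot(inherits(series, "direction_series"))
  ex <- delay_embed(series$vx, delay, dim)
  ey <- delay_embed(series$vy, delay, dim)
  structure(
    list(vectors = cbind(ex, ey), delay = delay, dim = dim,
         fps = track_fps(series), meta = attr(series, "meta")),
    class = "embedded_series")
}

#' @export
print.embedded_series <- function(x, ...) {
  cat(sprintf("<embedded_series> %d states x %d dims (delay %d, dim %d per coordinate)\n",
              nrow(x$vectors), ncol(x$vectors), x$delay, x$dim))
  invisible(x)
}
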