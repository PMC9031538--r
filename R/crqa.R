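#' Cross-distance matrix between two embedded series
#'
#' Entry (i, j) is the Euclidean distance between state i of participant A
#' and state j of participant B in the shared embedding space.
#'
#' @param a,b `embedded_series` objects (or plain numeric matrices) with the
#'   same number of columns.
#' @return M_A x M_B numeric matrix.
#' @export
cross_distances <- function(a, b) {
  ma <- if (inherits(a, "embedded_series")) a$vectors else as.matrix(a)
  mb <- if (inherits(b, "embedded_series")) b$vectors else as.matrix(b)
  if (ncol(ma) != ncol(mb)) rlang::abort("embedding dimensions differ")
  sa <- rowSums(ma^2)
  sb <- rowSums(mb^2)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(ma, mb)
  sqrt(pmax(d2, 0))
}

#' Distance threshold for a fixed recurrence rate
#'
#' Returns the empirical `target_rr`-quantile of the flattened distance
#' matrix, so that marking entries with distance <= epsilon recurrent
#' yields a recurrence rate of `target_rr` exactly for continuous
#' (tie-free) distances; under ties the achieved rate exceeds the target by
#' at most the probability mass of the tied value. Fixing the rate per
#' matrix normalises the recurrence statistics across dyads and conditions
#' whose raw distance scales differ.
#'
#' @param distances Numeric distance matrix.
#' @param target_rr Requested recurrence rate, strictly in (0, 1).
#'   Default 0.10.
#' @return The threshold epsilon.
#' @export
fixed_rr_threshold <- function(distances, target_rr = 0.10) {
  if (!(target_rr > 0 && target_rr < 1)) {
    rlang::abort("target_rr must lie strictly in (0, 1)")
  }
  v <- as.vector(distances)
  if (max(v) == min(v)) {
    rlang::abort("degenerate distance distribution: all distances identical")
  }
  stats::quantile(v, probs = target_rr, type = 1, names = FALSE)
}

#' Cross-recurrence matrix at a fixed recurrence rate
#'
#' Builds the binary cross-recurrence matrix between two participants'
#' embedded direction series: states closer than the adaptive threshold of
#' [fixed_rr_threshold()] are recurrent. A recurrent point (i, j) means
#' participant A at time i moved in (embedding-)the same way as participant
#' B at time j; points on the main diagonal indicate synchronised movement,
#' points off it more complex, lagged coordination. No Theiler exclusion is
#' applied: the two series come from different people, so the main
#' diagonal is informative rather than artifactual.
#'
#' @inheritParams cross_distances
#' @inheritParams fixed_rr_threshold
#' @return A `recurrence_matrix`: list with `matrix` (logical M_A x M_B),
#'   `epsilon`, `rr` (achieved rate), `target_rr`, `metric`, `meta`.
#' @export
recurrence_matrix <- function(a, b, target_rr = 0.10) {
  d <- cross_distances(a, b)
  eps <- fixed_rr_threshold(d, target_rr)
  m <- d <= eps
  meta_a <- if (inherits(a, "embedded_series")) a$meta else NULL
  new_recurrence_matrix(m, epsilon = eps, target_rr = target_rr,
                        meta = meta_a)
}

#' Wrap a binary matrix as a recurrence matrix
#'
#' Mostly useful for toy examples and tests; `epsilon` is unknown (`NA`)
#' and the achieved recurrence rate is computed from the matrix.
#'
#' @param m Logical (or 0/1) matrix.
#' @param epsilon,target_rr,meta Optional provenance.
#' @return A `recurrence_matrix`.
#' @export
as_recurrence_matrix <- function(m, epsilon = NA_real_, target_rr = NA_real_,
                                 meta = NULL) {
  new_recurrence_matrix(matrix(as.logical(m), nrow(m), ncol(m)),
                        epsilon = epsilon, target_rr = target_rr, meta = meta)
}

new_recurrence_matrix <- function(m, epsilon, target_rr, meta) {
  structure(
    list(matrix = m, epsilon = epsilon, rr = mean(m),
         target_rr = target_rr, metric = "euclidean", meta = meta),
    class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("<recurrence_matrix> %d x %d, rr = %.4f (target %s), epsilon = %s\n",
              nrow(x$matrix), ncol(x$matrix), x$rr,
              format(x$target_rr), format(x$epsilon)))
  invisible(x)
}

#' Maximal line-length distribution of a recurrence matrix
#'
#' Counts maximal runs of consecutive recurrent points along every diagonal
#' (all offsets, main diagonal included) or down every column. Runs
#' touching the matrix border are counted at their observed length.
#'
#' @param rm A `recurrence_matrix` (or logical matrix).
#' @param orientation `"diagonal"` or `"vertical"`.
#' @return A tibble with columns `length` and `count` (number of maximal
#'   lines of that length), attributes `orientation` and
#'   `total_recurrent_points`.
#' @export
line_lengths <- function(rm, orientation = c("diagonal", "vertical")) {
  orientation <- match.arg(orientation)
  m <- if (inherits(rm, "recurrence_matrix")) rm$matrix else rm
  lens <- if (orientation == "diagonal") {
    if (length(m) == 0) integer(0) else {
      off <- col(m) - row(m)   # column-major order within an offset walks the diagonal
      unlist(lapply(split(m, off), run_lengths), use.names = FALSE)
    }
  } else {
    unlist(lapply(seq_len(ncol(m)), function(j) run_lengths(m[, j])),
           use.names = FALSE)
  }
  tab <- table(lens)
  structure(
    tibble::tibble(length = as.integer(names(tab)), count = as.integer(tab)),
    orientation = orientation,
    total_recurrent_points = sum(m),
    class = c("line_distribution", class(tibble::tibble())))
}

run_lengths <- function(v) {
  r <- rle(as.logical(v))
  r$lengths[r$values]
}

#' Line-based cross-recurrence statistics
#'
#' Computes the six coordination statistics from the diagonal and vertical
#' line-length distributions, counting only lines of at least `lmin`
#' (diagonal) or `vmin` (vertical) points. With raw diagonal counts c(l):
#' \itemize{
#' \item DET (determinism) = sum over l >= lmin of l c(l), divided by the total
#'   recurrent point count — the fraction of recurrent points forming long
#'   diagonal lines; stable, predictable coordination.
#' \item L = mean counted diagonal length; average duration of a
#'   coordination episode.
#' \item Lmax = longest counted diagonal; the longest maintained episode.
#' \item ENTR = Shannon entropy (nats) of the counted diagonal-length
#'   distribution; complexity of the coordination patterns.
#' \item LAM (laminarity) and TT (trapping time): the analogous fraction
#'   and mean over vertical lines, which form when one participant stays in
#'   the same movement state.
#' }
#' Statistics with no counted line are 0 (DET, LAM, Lmax, ENTR) or `NA`
#' (L, TT).
#'
#' @param rm A `recurrence_matrix`.
#' @param lmin,vmin Minimum diagonal / vertical line lengths, in frames
#'   (defaults 10; 0.5 s at 20 frames per second).
#' @return One-row tibble: `dyad_id`, `condition`, `rr`, `epsilon`, `DET`,
#'   `ENTR`, `L`, `Lmax`, `LAM`, `TT`, `lmin`, `vmin`.
#' @export
rqa_stats <- function(rm, lmin = 10, vmin = 10) {
  stopifnot(lmin >= 1, vmin >= 1)
  diag_d <- line_lengths(rm, "diagonal")
  vert_d <- line_lengths(rm, "vertical")
  ds <- line_summary(diag_d, lmin)
  vs <- line_summary(vert_d, vmin)
  meta <- if (inherits(rm, "recurrence_matrix")) rm$meta else NULL
  tibble::tibble(
    dyad_id = meta$dyad_id %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    rr = if (inherits(rm, "recurrence_matrix")) rm$rr else mean(rm),
    epsilon = if (inherits(rm, "recurrence_matrix")) rm$epsilon else NA_real_,
    DET = ds$fraction, ENTR = ds$entropy, L = ds$mean_len, Lmax = ds$max_len,
    LAM = vs$fraction, TT = vs$mean_len,
    lmin = lmin, vmin = vmin
  )
}

line_summary <- function(dist_tbl, min_len) {
  l <- dist_tbl$length
  c_l <- dist_tbl$count
  total <- sum(l * c_l)   # every recurrent point lies on exactly one maximal run
  sel <- l >= min_len
  pts <- sum(l[sel] * c_l[sel])
  n_lines <- sum(c_l[sel])
  p <- if (n_lines > 0) c_l[sel] / n_lines else numeric(0)
  list(
    fraction = if (total > 0) pts / total else 0,
    mean_len = if (n_lines > 0) pts / n_lines else NA_real_,
    max_len = if (n_lines > 0) max(l[sel]) else 0,
    entropy = if (n_lines > 0) -sum(p * log(p)) else 0
  )
}

#' Recurrence rate by diagonal offset
#'
#' Diagnostic profile: for each offset k in `[-max_offset, max_offset]`, the
#' fraction of recurrent points on diagonal k (A's time leads B's by k
#' frames for positive k), normalised by the diagonal's length. A peak away
#' from zero reveals a systematic lag between the partners, e.g. a
#' transmission latency.
#'
#' @param rm A `recurrence_matrix`.
#' @param max_offset Largest |offset| scanned; must be < min(M_A, M_B).
#' @return A tibble of class `rr_profile` with columns `offset`, `rr`.
#' @export
diagonal_rr_profile <- function(rm, max_offset) {
  m <- if (inherits(rm, "recurrence_matrix")) rm$matrix else rm
  stopifnot(max_offset < min(nrow(m), ncol(m)))
  offs <- (-max_offset):max_offset
  rrs <- vapply(offs, function(k) {
    i <- seq_len(min(nrow(m), ncol(m) - k, nrow(m) + k, ncol(m)))
    if (k >= 0) mean(m[cbind(i, i + k)]) else mean(m[cbind(i - k, i)])
  }, 0)
  structure(tibble::tibble(offset = offs, rr = rrs),
            class = c("rr_profile", class(tibble::tibble())))
}
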