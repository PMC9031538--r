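test_that("missing_fraction counts the confidence-zero frames", {
  tr <- make_track(p0x = 1:8, p0y = 1:8,
                   conf0 = c(1, 0, 1, 1, 0, 1, 1, 1))
  expect_equal(missing_fraction(tr, "nose"), 2 / 8)
  expect_equal(missing_fraction(tr, "neck"), 0)
  expect_error(missing_fraction(tr, "elbow"), "unknown keypoint")

  all_missing <- make_track(p0x = 1:4, p0y = 1:4, conf0 = rep(0, 4))
  expect_equal(missing_fraction(all_missing, "nose"), 1)
})

test_that("exclusion keeps small missing fractions and drops large ones, boundary kept", {
  n <- 100
  mk <- function(nmiss) {
    make_track(p0x = seq_len(n), p0y = seq_len(n),
               conf0 = c(rep(0, nmiss), rep(1, n - nmiss)))
  }
  expect_true(check_exclusion(mk(2), threshold = 0.10))    # ~2% kept
  expect_false(check_exclusion(mk(16), threshold = 0.10))  # 16% dropped
  expect_true(check_exclusion(mk(10), threshold = 0.10))   # exactly at threshold: kept
})

test_that("linear interpolation fills interior gaps and extends edges", {
  expect_equal(interpolate_missing(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(interpolate_missing(c(NA, 5, 5)), c(5, 5, 5))
  expect_equal(interpolate_missing(c(0, NA, NA, 3)), c(0, 1, 2, 3))
  x <- c(NA, 2, NA, 4, NA)
  expect_equal(interpolate_missing(x), c(2, 2, 3, 4, 4))
  expect_error(interpolate_missing(c(NA, NA)), "all values missing")
})

test_that("running median suppresses outliers and truncates at edges", {
  expect_equal(running_median(c(0, 0, 100, 0, 0), 5)[3], 0)
  expect_equal(running_median(rep(7, 10), 5), rep(7, 10))
  expect_equal(running_median(c(1, 2, 3, 4, 5), 3), c(1.5, 2, 3, 4, 4.5))
  expect_error(running_median(1:10, 4), "odd")
})

test_that("preprocessing yields gap-free tracks with the mean P0-P1 distance as scale", {
  # constant distance 2
  tr <- make_track(p0x = rep(0, 6), p0y = rep(0, 6))
  pt <- preprocess_track(tr)
  expect_equal(track_scale(pt), 2)

  # distances 3,4,5 -> mean 4 (window 1 leaves coordinates untouched)
  tr2 <- make_track(p0x = rep(0, 3), p0y = rep(0, 3),
                    p1x = c(3, 4, 5), p1y = rep(0, 3))
  expect_equal(track_scale(preprocess_track(tr2, median_window = 1)), 4)

  # one interior missing frame: length preserved, no NA anywhere
  tr3 <- make_track(p0x = c(1, 2, 99, 4, 5), p0y = rep(0, 5),
                    conf0 = c(1, 1, 0, 1, 1))
  pt3 <- preprocess_track(tr3, median_window = 3)
  expect_equal(nrow(pt3), 5)
  expect_false(anyNA(pt3))

  # coincident markers cannot define a scale
  degen <- make_track(p0x = rep(1, 8), p0y = rep(1, 8),
                      p1x = rep(1, 8), p1y = rep(1, 8))
  expect_error(preprocess_track(degen), "degenerate geometry")
})

test_that("cleaning is idempotent on clean series and scale is translation/scaling equivariant", {
  set.seed(11)
  tr <- make_track(p0x = cumsum(rnorm(40)), p0y = cumsum(rnorm(40)),
                   p1x = rnorm(40), p1y = 30 + rnorm(40))
  pt <- preprocess_track(tr)
  # the chain is the identity on an already-clean constant track
  const <- make_track(p0x = rep(3, 12), p0y = rep(4, 12))
  pc <- preprocess_track(const)
  expect_equal(pc$p0_x, rep(3, 12))
  expect_equal(preprocess_track(make_track(p0x = pc$p0_x, p0y = pc$p0_y))$p0_y,
               pc$p0_y)

  shift <- make_track(p0x = tr$x[tr$keypoint == "nose"] + 50,
                      p0y = tr$y[tr$keypoint == "nose"] - 20,
                      p1x = tr$x[tr$keypoint == "neck"] + 50,
                      p1y = tr$y[tr$keypoint == "neck"] - 20)
  expect_equal(track_scale(preprocess_track(shift)), track_scale(pt))

  doubled <- make_track(p0x = 2 * tr$x[tr$keypoint == "nose"],
                        p0y = 2 * tr$y[tr$keypoint == "nose"],
                        p1x = 2 * tr$x[tr$keypoint == "neck"],
                        p1y = 2 * tr$y[tr$keypoint == "neck"])
  expect_equal(track_scale(preprocess_track(doubled)), 2 * track_scale(pt))
})
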