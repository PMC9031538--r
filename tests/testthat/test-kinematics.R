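test_that("mobility statistics match hand-computed SD/scale values", {
  # constant head: no mobility, undefined ratio (flagged as NA, not Inf)
  const <- preprocess_track(make_track(p0x = rep(0, 10), p0y = rep(0, 10)))
  m0 <- mobility(const)
  expect_equal(m0$horizontal, 0)
  expect_equal(m0$vertical, 0)
  expect_true(is.na(m0$hv_ratio))

  # alternating x in {0,2}: population SD 1; P1 tracks P0 horizontally so
  # the P0-P1 distance is constantly 2 -> horizontal 0.5
  alt <- preprocess_track(make_track(p0x = rep(c(0, 2), 10), p0y = rep(0, 20),
                                     p1x = rep(c(0, 2), 10), p1y = rep(2, 20)),
                          median_window = 1)
  mp <- mobility(alt, sd_mode = "population")
  expect_equal(mp$horizontal, 0.5)
  expect_equal(mp$vertical, 0)
  # sample SD is inflated by sqrt(n/(n-1))
  ms <- mobility(alt, sd_mode = "sample")
  expect_equal(ms$horizontal, 0.5 * sqrt(20 / 19))
})

test_that("mobility is invariant under translation and joint rescaling", {
  set.seed(21)
  x <- cumsum(rnorm(50)); y <- cumsum(rnorm(50))
  cols <- c("horizontal", "vertical", "hv_ratio")
  tr_base <- make_track(p0x = x, p0y = y,
                        p1x = rep(0, 50), p1y = rep(47, 50))
  tr_shift <- make_track(p0x = x + 17, p0y = y - 5,
                         p1x = rep(17, 50), p1y = rep(42, 50))
  tr_scaled <- make_track(p0x = 3 * x, p0y = 3 * y,
                          p1x = rep(0, 50), p1y = rep(3 * 47, 50))
  mb <- mobility(preprocess_track(tr_base))
  expect_equal(mobility(preprocess_track(tr_shift))[cols], mb[cols])
  expect_equal(mobility(preprocess_track(tr_scaled))[cols], mb[cols])
})

test_that("direction field gives unit steps, flags stillness, respects image axes", {
  tr <- preprocess_track(make_track(p0x = c(0, 3, 3, 3), p0y = c(0, 4, 4, 9)),
                         median_window = 1)
  ds <- direction_field(tr)
  expect_equal(nrow(ds), 3)
  expect_equal(c(ds$vx[1], ds$vy[1]), c(0.6, 0.8))       # 3-4-5 step
  expect_equal(c(ds$vx[2], ds$vy[2]), c(0, 0))           # still frame
  expect_true(ds$degenerate[2])
  expect_equal(c(ds$vx[3], ds$vy[3]), c(0, 1))           # downward in image coords
  nondeg <- !ds$degenerate
  expect_equal(ds$vx[nondeg]^2 + ds$vy[nondeg]^2, rep(1, sum(nondeg)))
})

test_that("direction field is translation invariant and rotation equivariant", {
  set.seed(31)
  x <- cumsum(rnorm(30)); y <- cumsum(rnorm(30))
  mk <- function(px, py) direction_field(
    preprocess_track(make_track(p0x = px, p0y = py, p1y = rep(50, 30)),
                     median_window = 1))
  base <- mk(x, y)
  shifted <- mk(x + 100, y - 40)
  expect_equal(shifted$vx, base$vx)
  expect_equal(shifted$vy, base$vy)
  th <- pi / 5
  rot <- mk(cos(th) * x - sin(th) * y, sin(th) * x + cos(th) * y)
  expect_equal(rot$vx, cos(th) * base$vx - sin(th) * base$vy, tolerance = 1e-10)
  expect_equal(rot$vy, sin(th) * base$vx + cos(th) * base$vy, tolerance = 1e-10)
})

test_that("low-pass smoothing passes DC, kills Nyquist, and is linear", {
  const <- make_direction_series(vx = rep(0.6, 100), vy = rep(0.8, 100))
  sm <- lowpass(const)
  expect_equal(sm$vx, rep(0.6, 100), tolerance = 1e-4)
  expect_true(attr(sm, "smoothed"))

  nyq <- make_direction_series(vx = rep(0, 100), vy = rep(c(1, -1), 50))
  att <- lowpass(nyq, cutoff = 2)
  expect_lt(max(abs(att$vy)), 0.1)   # >= 90% attenuation well above cutoff

  set.seed(41)
  s <- make_direction_series(vx = rnorm(80), vy = rnorm(80))
  s3 <- make_direction_series(vx = 3 * s$vx, vy = 3 * s$vy)
  expect_equal(lowpass(s3)$vx, 3 * lowpass(s)$vx, tolerance = 1e-10)

  expect_error(lowpass(const, cutoff = 10), "Nyquist")
})

test_that("refiltering a slowly varying signal barely changes it", {
  t <- seq_len(400)
  slow <- make_direction_series(vx = sin(2 * pi * 0.1 * t / 20),
                                vy = cos(2 * pi * 0.1 * t / 20))
  once <- lowpass(slow)
  twice <- lowpass(once)
  # 0.1 Hz is deep inside the 2 Hz passband: double filtering moves points
  # by well under 1% of the unit amplitude
  expect_lt(max(abs(twice$vx - once$vx)), 0.01)
})
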