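test_that("cross distances are plain pairwise Euclidean distances", {
  a <- rbind(c(0, 0), c(1, 0))
  b <- rbind(c(0, 0), c(0, 1))
  expect_equal(cross_distances(a, b),
               rbind(c(0, 1), c(1, sqrt(2))))
  expect_equal(cross_distances(cbind(0), cbind(3)), cbind(3))
  set.seed(12)
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(diag(cross_distances(m, m)), rep(0, 10), tolerance = 1e-12)
  expect_error(cross_distances(matrix(0, 2, 2), matrix(0, 2, 3)), "dimensions differ")
})

test_that("fixed-RR thresholding picks the order statistic that hits the target", {
  d <- matrix(sample(1:100), 10, 10)
  eps <- fixed_rr_threshold(d, 0.10)
  expect_equal(eps, 10)
  expect_equal(sum(d <= eps), 10)
  expect_error(fixed_rr_threshold(d, 1.0), "strictly")
  expect_error(fixed_rr_threshold(matrix(0, 5, 5)), "degenerate")
})

test_that("recurrence count is monotone in the target rate", {
  set.seed(13)
  d <- matrix(runif(400), 20, 20)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.5),
                   function(r) sum(d <= fixed_rr_threshold(d, r)), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("line distributions match hand-enumerated toy matrices", {
  ident <- as_recurrence_matrix(diag(5) == 1)
  dl <- line_lengths(ident, "diagonal")
  expect_equal(dl$length, 5L)
  expect_equal(dl$count, 1L)
  vl <- line_lengths(ident, "vertical")
  expect_equal(vl$length, 1L)
  expect_equal(vl$count, 5L)

  ones <- as_recurrence_matrix(matrix(TRUE, 3, 3))
  dl3 <- line_lengths(ones, "diagonal")
  expect_equal(dl3$length, c(1L, 2L, 3L))
  expect_equal(dl3$count, c(2L, 2L, 1L))
  vl3 <- line_lengths(ones, "vertical")
  expect_equal(vl3$length, 3L)
  expect_equal(vl3$count, 3L)

  none <- as_recurrence_matrix(matrix(FALSE, 4, 4))
  expect_equal(nrow(line_lengths(none, "diagonal")), 0)
})

test_that("recurrence statistics match hand-computed values on a 5-point toy matrix", {
  m <- matrix(FALSE, 5, 5)
  m[cbind(1:3, 1:3)] <- TRUE      # one diagonal run of 3
  m[5, 1] <- TRUE; m[1, 5] <- TRUE  # two isolated points
  st <- rqa_stats(as_recurrence_matrix(m), lmin = 2, vmin = 2)
  expect_equal(st$DET, 3 / 5)
  expect_equal(st$L, 3)
  expect_equal(st$Lmax, 3)
  expect_equal(st$ENTR, 0)        # single counted length
  expect_equal(st$LAM, 0)         # no vertical run of 2+
  expect_true(is.na(st$TT))

  # nothing reaches lmin -> DET 0
  st10 <- rqa_stats(as_recurrence_matrix(m), lmin = 10, vmin = 10)
  expect_equal(st10$DET, 0)
  expect_equal(st10$Lmax, 0)
})

test_that("self-comparison saturates the main diagonal", {
  set.seed(14)
  e <- delay_embed(rnorm(30), 1, 2)
  rm <- recurrence_matrix(e, e, target_rr = 0.1)
  st <- rqa_stats(rm)
  expect_equal(st$Lmax, nrow(e))
})

test_that("optimised line counting agrees exactly with the naive oracle", {
  set.seed(15)
  for (i in 1:15) {
    nr <- sample(5:60, 1); nc <- sample(5:60, 1)
    rm <- random_recurrence_matrix(nr, nc, runif(1, 0.05, 0.4))
    for (orient in c("diagonal", "vertical")) {
      got <- line_lengths(rm, orient)
      want <- oracle_line_lengths(rm$matrix, orient)
      expect_equal(rep(got$length, got$count), sort(want))
    }
    o <- oracle_rqa(rm$matrix, lmin = 3, vmin = 3)
    st <- rqa_stats(rm, lmin = 3, vmin = 3)
    expect_equal(st$DET, o$DET)
    expect_equal(st$ENTR, o$ENTR)
    expect_equal(st$L, o$L)
    expect_equal(st$Lmax, o$Lmax)
    expect_equal(st$LAM, o$LAM)
    expect_equal(st$TT, o$TT)
  }
})

test_that("swapping participants transposes the matrix and preserves diagonal statistics", {
  set.seed(16)
  a <- delay_embed(rnorm(80), 2, 3)
  b <- delay_embed(rnorm(80), 2, 3)
  ab <- recurrence_matrix(a, b, 0.15)
  ba <- recurrence_matrix(b, a, 0.15)
  expect_equal(ba$matrix, t(ab$matrix))
  s_ab <- rqa_stats(ab, lmin = 2, vmin = 2)
  s_ba <- rqa_stats(ba, lmin = 2, vmin = 2)
  for (col in c("DET", "ENTR", "L", "Lmax")) {
    expect_equal(s_ba[[col]], s_ab[[col]])
  }
  # vertical lines of the swap are the horizontal lines of the original
  expect_equal(line_lengths(ba, "vertical"),
               line_lengths(as_recurrence_matrix(t(ab$matrix)), "vertical"),
               ignore_attr = TRUE)
})

test_that("diagonal RR profile locates imposed offsets", {
  ident <- as_recurrence_matrix(diag(10) == 1)
  prof <- diagonal_rr_profile(ident, 4)
  expect_equal(prof$rr[prof$offset == 0], 1)
  expect_equal(prof$offset[which.max(prof$rr)], 0)

  m <- matrix(FALSE, 20, 20)
  m[cbind(1:15, 6:20)] <- TRUE        # band at offset +5
  prof5 <- diagonal_rr_profile(as_recurrence_matrix(m), 8)
  expect_equal(prof5$offset[which.max(prof5$rr)], 5)
})
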