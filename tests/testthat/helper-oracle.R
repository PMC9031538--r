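# Independent reference implementations used to freeze expected values.
# Deliberately naive (explicit loops) so they share no code with the package.

# every maximal run of TRUEs along all diagonals or down all columns
oracle_line_lengths <- function(m, orientation) {
  lens <- integer(0)
  flush <- function(run) if (run > 0) lens <<- c(lens, run)
  if (orientation == "diagonal") {
    for (k in (-(nrow(m) - 1)):(ncol(m) - 1)) {
      run <- 0
      for (i in seq_len(nrow(m))) {
        j <- i + k
        if (j < 1 || j > ncol(m)) next
        if (m[i, j]) run <- run + 1 else { flush(run); run <- 0 }
      }
      flush(run)
    }
  } else {
    for (j in seq_len(ncol(m))) {
      run <- 0
      for (i in seq_len(nrow(m))) {
        if (m[i, j]) run <- run + 1 else { flush(run); run <- 0 }
      }
      flush(run)
    }
  }
  lens
}

oracle_rqa <- function(m, lmin = 10, vmin = 10) {
  dl <- oracle_line_lengths(m, "diagonal")
  vl <- oracle_line_lengths(m, "vertical")
  stat <- function(lens, minlen) {
    total <- sum(lens)
    sel <- lens[lens >= minlen]
    p <- if (length(sel) > 0) as.numeric(table(sel)) / length(sel) else numeric(0)
    list(frac = if (total > 0) sum(sel) / total else 0,
         mean = if (length(sel) > 0) mean(sel) else NA_real_,
         max = if (length(sel) > 0) max(sel) else 0,
         entr = if (length(sel) > 0) -sum(p * log(p)) else 0)
  }
  d <- stat(dl, lmin); v <- stat(vl, vmin)
  list(DET = d$frac, ENTR = d$entr, L = d$mean, Lmax = d$max,
       LAM = v$frac, TT = v$mean)
}

# histogram mutual information via marginal/joint entropies (different code
# path from the package's ratio form)
oracle_ami <- function(x, lag, bins = 16) {
  n <- length(x)
  a <- x[1:(n - lag)]
  b <- x[(1 + lag):n]
  brk <- seq(min(x), max(x), length.out = bins + 1)
  brk[1] <- brk[1] - 1e-9
  fa <- cut(a, brk); fb <- cut(b, brk)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ent(table(fa) / length(a)) + ent(table(fb) / length(b)) -
    ent(table(fa, fb) / length(a))
}
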