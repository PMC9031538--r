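# full 6-dyad x 2-participant x 4-condition design grid
full_design <- function(level = c("participant", "dyad"), n_dyads = 6) {
  level <- match.arg(level)
  g <- expand.grid(dyad_id = paste0("dyad", seq_len(n_dyads)),
                   condition = c("remote_mirror", "remote_no_mirror",
                                 "live_mirror", "live_no_mirror"),
                   stringsAsFactors = FALSE)
  if (level == "participant") {
    g <- merge(g, data.frame(participant_id = c("A", "B")))
  }
  g$value <- seq_len(nrow(g))
  tibble::as_tibble(g)
}

# table drawn from the random-intercept model the contrast assumes
sim_mixed_table <- function(seed, n_dyads = 6, beta_remote = 0.5,
                            sigma_u = 0.3, sigma_e = 0.2) {
  set.seed(seed)
  d <- full_design("participant", n_dyads)
  d$unit <- paste(d$dyad_id, d$participant_id)
  u <- stats::rnorm(length(unique(d$unit)), 0, sigma_u)
  names(u) <- unique(d$unit)
  d$value <- 1 + beta_remote * startsWith(d$condition, "remote") +
    u[d$unit] + stats::rnorm(nrow(d), 0, sigma_e)
  build_table(d[setdiff(names(d), "unit")], "value")
}
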