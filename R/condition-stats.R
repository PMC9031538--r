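#' Observation table for condition contrasts
#'
#' Assembles per-recording statistics (mobility rows or dyad-level
#' recurrence rows) into the design table for the condition contrasts,
#' deriving the two dummy-coded factors from the condition label:
#' `remote` is 1 for the video-mediated conditions, `no_mirror` is 1 when
#' the self-view was absent (`remote_mirror` -> (1,0),
#' `remote_no_mirror` -> (1,1), `live_mirror` -> (0,0),
#' `live_no_mirror` -> (0,1)). Excluded recordings are simply absent rows.
#'
#' @param stats A tibble with columns `dyad_id`, `condition`, optionally
#'   `participant_id`, and the response column.
#' @param response Name of the response column.
#' @return Tibble with the identifier columns, `condition`, `remote`,
#'   `no_mirror` and the response; attribute `response` records the
#'   response name.
#' @export
build_table <- function(stats, response) {
  stopifnot(is.data.frame(stats), response %in% names(stats))
  if (!all(stats$condition %in% dyad_conditions())) {
    rlang::abort("unknown condition label")
  }
  unit_cols <- intersect(c("dyad_id", "participant_id"), names(stats))
  if (anyDuplicated(stats[c(unit_cols, "condition")]) > 0) {
    rlang::abort("duplicate unit-condition rows")
  }
  out <- stats |>
    dplyr::mutate(
      remote = as.integer(startsWith(.data$condition, "remote")),
      no_mirror = as.integer(endsWith(.data$condition, "no_mirror"))
    ) |>
    dplyr::select(dplyr::all_of(unit_cols), "condition", "remote",
                  "no_mirror", dplyr::all_of(response))
  attr(out, "response") <- response
  out
}

#' Mixed-effects condition contrast
#'
#' Fits `response ~ 1 + remote + no_mirror + (1 | unit)` by maximum
#' likelihood, the repeated-measures model for the 2 x 2 condition design:
#' the two fixed effects measure the shift attributable to the remote
#' medium and to the absence of self-view, and the random intercept
#' absorbs stable differences between units (participants or dyads).
#' Fixed effects are reported with Wald z statistics and normal p-values.
#' A singular fit (random-intercept variance estimated at zero) is legal
#' and flagged rather than treated as an error.
#'
#' Responses with no variance at all cannot be fit; they return a
#' degenerate result with zero slopes, flagged via `degenerate`.
#'
#' @param table Output of [build_table()].
#' @param grouping `"participant"` (random intercept per participant,
#'   appropriate for individual-level mobility) or `"dyad"` (per dyad, for
#'   dyad-level recurrence statistics).
#' @param response Response column; defaults to the one recorded by
#'   [build_table()].
#' @param reml Use REML instead of maximum likelihood (default FALSE).
#' @return A `dyad_mixed_fit` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
fit_mixed_model <- function(table, grouping = c("participant", "dyad"),
                            response = attr(table, "response"),
                            reml = FALSE) {
  grouping <- match.arg(grouping)
  stopifnot(!is.null(response), response %in% names(table))
  df <- as.data.frame(table)
  df$.y <- df[[response]]
  df$.unit <- if (grouping == "participant") {
    if (!"participant_id" %in% names(df)) {
      rlang::abort("participant grouping needs a participant_id column")
    }
    interaction(df$dyad_id, df$participant_id, drop = TRUE)
  } else {
    factor(df$dyad_id)
  }
  if (length(unique(df$.unit)) < 2) rlang::abort("need at least 2 grouping units")

  if (stats::var(df$.y) == 0) {
    est <- c(`(Intercept)` = df$.y[1], remote = 0, no_mirror = 0)
    fixed <- tibble::tibble(term = names(est), estimate = unname(est),
                            std_error = 0, z = NA_real_, p = NA_real_)
    return(new_dyad_mixed_fit(NULL, fixed, sigma_group = 0, sigma_resid = 0,
                              singular = TRUE, degenerate = TRUE,
                              grouping = grouping, response = response,
                              nobs = nrow(df)))
  }

  fit <- lme4::lmer(.y ~ 1 + remote + no_mirror + (1 | .unit), data = df,
                    REML = reml,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  co <- as.data.frame(summary(fit)$coefficients)
  z <- co[["t value"]]
  fixed <- tibble::tibble(
    term = rownames(co),
    estimate = co[["Estimate"]],
    std_error = co[["Std. Error"]],
    z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_group <- vc$sdcor[vc$grp == ".unit"]
  new_dyad_mixed_fit(fit, fixed, sigma_group = sigma_group,
                     sigma_resid = stats::sigma(fit),
                     singular = lme4::isSingular(fit), degenerate = FALSE,
                     grouping = grouping, response = response,
                     nobs = nrow(df))
}

new_dyad_mixed_fit <- function(model, fixed, sigma_group, sigma_resid,
                               singular, degenerate, grouping, response, nobs) {
  structure(
    list(model = model, fixed = fixed, sigma_group = sigma_group,
         sigma_resid = sigma_resid, singular = singular,
         degenerate = degenerate, grouping = grouping, response = response,
         nobs = nobs),
    class = "dyad_mixed_fit")
}

#' @export
print.dyad_mixed_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects condition contrast for '%s' (random intercept per %s)\n",
              x$response, x$grouping))
  print(as.data.frame(x$fixed), digits = 4)
  cat(sprintf("sigma (%s) = %.4f%s, residual = %.4f, n = %d\n",
              x$grouping, x$sigma_group,
              if (x$singular) " [singular]" else "", x$sigma_resid, x$nobs))
  invisible(x)
}

#' Tidy a mixed-effects condition contrast
#'
#' @param x A `dyad_mixed_fit`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of fixed effects (`term`, `estimate`,
#'   `std_error`, `z`, `p`); `glance()`: a one-row model summary with the
#'   random-intercept and residual SDs and the singular-fit flag.
#' @export
tidy.dyad_mixed_fit <- function(x, ...) x$fixed

#' @rdname tidy.dyad_mixed_fit
#' @export
glance.dyad_mixed_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response, grouping = x$grouping,
    sigma_group = x$sigma_group, sigma_resid = x$sigma_resid,
    singular = x$singular, degenerate = x$degenerate,
    logLik = if (is.null(x$model)) NA_real_ else as.numeric(stats::logLik(x$model)),
    nobs = x$nobs)
}

#' Paired t-test
#'
#' Classical paired Student's t on the within-unit differences, df = n - 1,
#' two-sided. Identical inputs (all differences zero) return t = 0; a
#' nonzero constant difference has no estimable variance and is an error.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(t = 0, df = length(d) - 1, p = 1, mean_diff = 0))
    }
    rlang::abort("zero-variance differences")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = unname(ht$estimate))
}
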