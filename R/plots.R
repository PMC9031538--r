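#' Plot a cross-recurrence matrix
#'
#' Raster of the recurrence plot; time of participant A on the x axis,
#' participant B on the y axis. Structure along the main diagonal means
#' synchronised movement; off-diagonal bands mean lagged coordination.
#'
#' @param object A `recurrence_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recurrence_matrix <- function(object, ...) {
  m <- object$matrix
  df <- tibble::tibble(
    i = as.vector(row(m)), j = as.vector(col(m)),
    recurrent = as.vector(m))
  ggplot2::ggplot(df[df$recurrent, ], ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(fill = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "time A (frames)", y = "time B (frames)",
                  title = sprintf("rr = %.3f, epsilon = %.3g",
                                  object$rr, object$epsilon)) +
    ggplot2::theme_minimal()
}

#' Plot a diagonal recurrence-rate profile
#'
#' @param object An `rr_profile` from [diagonal_rr_profile()].
#' @param ... Unused.
#' @return A ggplot; the dashed line marks the peak offset.
#' @export
autoplot.rr_profile <- function(object, ...) {
  peak <- object$offset[which.max(object$rr)]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$rr)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = peak, linetype = "dashed") +
    ggplot2::labs(x = "diagonal offset (frames, A leads B)",
                  y = "recurrence rate",
                  title = sprintf("peak at offset %d", peak)) +
    ggplot2::theme_minimal()
}

#' Per-dyad condition profiles
#'
#' One line per unit (participant or dyad) across the four conditions, the
#' standard way to eyeball a repeated-measures condition effect before the
#' mixed model quantifies it.
#'
#' @param data A mobility or recurrence-statistics tibble with `dyad_id`,
#'   `condition` and the response column.
#' @param response Response column name (string).
#' @return A ggplot.
#' @export
plot_condition_profiles <- function(data, response) {
  stopifnot(response %in% names(data))
  unit_cols <- intersect(c("dyad_id", "participant_id"), names(data))
  df <- data
  df$unit <- do.call(paste, c(df[unit_cols], sep = "/"))
  df$condition <- factor(df$condition, levels = dyad_conditions())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data[[response]],
                                   group = .data$unit,
                                   colour = .data$dyad_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = response, colour = "dyad") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
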