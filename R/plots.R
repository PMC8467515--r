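# ggplot2 visualisations for the main result types.

#' Plot a read-length profile
#'
#' Bar chart of abundance per insert length over the 8-30 nt window, with
#' the 12 and 13 nt doRNA lengths highlighted.
#'
#' @param object A [length_histogram()] result.
#' @param y `"rpm"` (default) or `"reads"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dorna_length_profile
#' @export
autoplot.dorna_length_profile <- function(object, y = c("rpm", "reads"), ...) {
  y <- match.arg(y)
  df <- as_tibble(object)
  df$highlight <- df$length %in% c(12L, 13L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data[[y]],
                                   fill = .data$highlight)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "#C0392B")) +
    ggplot2::labs(x = "insert length (nt)",
                  y = if (y == "rpm") "reads per million" else "reads",
                  title = "Read-length distribution (8-30 nt window)") +
    ggplot2::theme_minimal()
}

#' Plot the doRNA 5'-extension ladder
#'
#' Column chart of family read counts by 5' offset (0 = 12-nt core,
#' -1 = the 13-nt +1 variant, deeper offsets reach into ITS1).
#'
#' @param object A [tabulate_ladder()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dorna_ladder
#' @export
autoplot.dorna_ladder <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$offset), ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$offset,
                                              levels = sort(unique(.data$offset))),
                                   y = .data$count, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "5' offset relative to the doRNA core",
                  y = "reads",
                  title = "doRNA 5'-extension ladder (3' end fixed at 5.8S G13)") +
    ggplot2::theme_minimal()
}

#' Plot a qPCR standard curve
#'
#' Dilution points and the fitted Cq on log10(copies) line, annotated
#' with slope and efficiency.
#'
#' @param object A [fit_standard_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dorna_stdcurve
#' @export
autoplot.dorna_stdcurve <- function(object, ...) {
  df <- object$fit$model
  names(df) <- c("cq", "log10_copies")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_copies, y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2C3E50") +
    ggplot2::labs(
      x = "log10 copies", y = "Cq",
      title = sprintf("Standard curve: slope %.3f, efficiency %.0f%%",
                      object$slope, 100 * object$efficiency)
    ) +
    ggplot2::theme_minimal()
}
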