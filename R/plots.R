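#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the annotation-cost curve of a run
#'
#' Test accuracy against the percentage of the original training set
#' manually annotated, the standard cost-effectiveness view of an
#' active-learning run.
#'
#' @param object an `al_run`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.al_run <- function(object, ...) {
  curve <- annotation_curve(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = manual_pct, y = accuracy)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "manually annotated (% of original training set)",
      y = "test accuracy",
      title = sprintf("%s / %s", object$config$algorithm,
                      object$config$criterion)
    ) +
    ggplot2::theme_minimal()
}

#' Compare annotation-cost curves across runs
#'
#' @param runs named list of `al_run` objects (names label the curves).
#' @param baseline optional baseline accuracy drawn as a horizontal
#'   reference line.
#' @return A ggplot object.
#' @export
plot_annotation_curves <- function(runs, baseline = NULL) {
  curves <- bind_rows(
    lapply(runs, annotation_curve),
    .id = "arm"
  )
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = manual_pct, y = accuracy,
                                    colour = arm)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "manually annotated (% of original training set)",
      y = "test accuracy", colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline, linetype = "dashed")
  }
  p
}

#' Plot a certainty ranking
#'
#' Certainty scores in ranked order; the top of the curve is pseudo-labeled,
#' the bottom manually annotated.
#'
#' @param object a `certainty_ranking`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.certainty_ranking <- function(object, ...) {
  df <- tibble::tibble(rank = seq_len(nrow(object)),
                       certainty = object$certainty)
  ggplot2::ggplot(df, ggplot2::aes(x = rank, y = certainty)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank (most certain first)",
                  y = sprintf("certainty (%s)", attr(object, "criterion"))) +
    ggplot2::theme_minimal()
}
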