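# ggplot2 displays for the main result types.

.PHASE_COLOURS <- c(ablation = "#3366cc", targeting = "#33a02c",
                    other = "#999999")

#' Plot a phase timeline
#'
#' Horizontal bars of the maximal constant-phase runs, optionally with the
#' ground-truth timeline underneath for comparison.
#'
#' @param timeline A [segment_timeline()] tibble, or a named list of such
#'   tibbles (e.g. `list(predicted = ..., truth = ...)`).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_timeline <- function(timeline, title = "Workflow timeline") {
  if (is.data.frame(timeline)) timeline <- list(predicted = timeline)
  df <- dplyr::bind_rows(
    lapply(names(timeline), function(nm) {
      dplyr::mutate(timeline[[nm]], track = nm)
    })
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = 0, ymax = 1, fill = .data$phase
    )) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track)) +
    ggplot2::scale_fill_manual(values = .PHASE_COLOURS) +
    ggplot2::labs(x = "frame index", y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot precision-recall curves
#'
#' @param pr A tibble with columns `recall`, `precision` and optionally
#'   `method` (as in `report$pr`).
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(pr) {
  p <- ggplot2::ggplot(pr, ggplot2::aes(x = .data$recall,
                                        y = .data$precision))
  p <- if ("method" %in% names(pr)) {
    p + ggplot2::geom_path(ggplot2::aes(colour = .data$method))
  } else {
    p + ggplot2::geom_path()
  }
  p +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  title = "Ablation detection precision-recall") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.feto_report <- function(object, ...) {
  plot_pr_curve(object$pr)
}

#' @export
autoplot.feto_model <- function(object, ...) {
  lt <- tidy.feto_model(object)
  ggplot2::ggplot(lt, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x,
                         span = 0.3) +
    ggplot2::labs(x = "iteration", y = "cross-entropy loss",
                  title = paste0("Training loss (", object$variant, ")")) +
    ggplot2::theme_minimal()
}

#' Display a frame
#'
#' @param x A `feto_frame`.
#' @param ... Unused.
#' @return (Invisibly) the frame.
#' @export
plot.feto_frame <- function(x, ...) {
  op <- graphics::par(mar = c(0, 0, 1, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(x$pixels, 0, 0, 1, 1)
  ttl <- paste0(x$procedure_id, "[", x$index, "] ",
                ifelse(is.na(x$phase), "", x$phase))
  graphics::title(ttl)
  invisible(x)
}
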