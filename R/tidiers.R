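#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a confusion table
#'
#' @param x A `feto_confusion`.
#' @param ... Unused.
#' @return A one-row tibble with the four cells and the total.
#' @export
tidy.feto_confusion <- function(x, ...) {
  tibble::tibble(tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
                 total = confusion_total(x))
}

#' Tidy / glance a study report
#'
#' `tidy()` returns the per-sequence metric rows (one per method x fold);
#' `glance()` the cumulative confusion cells and metrics per method.
#'
#' @param x A `feto_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.feto_report <- function(x, ...) x$per_sequence

#' @rdname tidy.feto_report
#' @export
glance.feto_report <- function(x, ...) x$cumulative

#' Tidy / glance a trained detector
#'
#' `tidy()` returns the training loss trace; `glance()` a one-row model
#' summary.
#'
#' @param x A `feto_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.feto_model <- function(x, ...) {
  x$loss_trace %||% tibble::tibble(iteration = integer(), loss = numeric())
}

#' @rdname tidy.feto_model
#' @export
glance.feto_model <- function(x, ...) {
  n_par <- sum(vapply(x$params$W, length, numeric(1))) +
    sum(vapply(x$params$b, length, numeric(1))) +
    length(x$params$Wfc) + length(x$params$bfc)
  tibble::tibble(
    variant = x$variant,
    input_size = x$input_size,
    pooling = x$pool_type,
    n_parameters = n_par,
    trained = isTRUE(x$trained),
    final_loss = if (is.null(x$loss_trace)) NA_real_ else
      utils::tail(x$loss_trace$loss, 1)
  )
}
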