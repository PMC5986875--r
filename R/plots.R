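#' @method autoplot cgr_fit
#' @export
autoplot.cgr_fit <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$individual_id, y = .data$proportion,
                                     fill = .data$population)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "estimated genome proportion", fill = "founder") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Distribution of absolute estimation errors
#'
#' Histogram of `|true - estimated|` over all individual-by-population cells,
#' optionally overlaying several fits (e.g. the two constraint modes).
#'
#' @param truth wide truth tibble.
#' @param ... named fits or proportion tibbles to compare.
#' @param populations optional restriction of the scored populations.
#' @return A ggplot object.
#' @export
plot_error_distribution <- function(truth, ..., populations = NULL) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("fit", seq_along(fits))
  }
  long <- purrr::imap(fits, function(f, nm) {
    al <- .align_prop_tables(truth, f, populations)
    tibble(fit = nm, abs_error = abs(as.numeric(al$truth) - as.numeric(al$est)))
  })
  long <- dplyr::bind_rows(long)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$abs_error, fill = .data$fit)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "|true - estimated| genome proportion", y = "cells") +
    ggplot2::theme_minimal()
}

#' Heatmap of panel frequency-column correlations
#'
#' Visualises [panel_correlations()]: close relatives among the founder
#' populations show up as strongly correlated allele-frequency vectors.
#'
#' @param panel a [founder_panel()].
#' @return A ggplot object.
#' @export
plot_panel_correlations <- function(panel) {
  cm <- panel_correlations(panel)
  df <- as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("pop_a", "pop_b", "correlation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pop_a, y = .data$pop_b,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
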