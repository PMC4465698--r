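# ggplot2 views of the main result types.

#' Plot phenotype status counts
#'
#' Bar chart of subjects per assigned status.
#'
#' @param object A `poag_assignments` tibble from [run_phenotyping()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poag_assignments <- function(object, ...) {
  counts <- dplyr::count(as_tibble(object), .data$status, .drop = FALSE)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "subjects",
                  title = "Phenotype algorithm assignments") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the distribution of extracted cup-to-disc ratios per eye
#'
#' Faceted histogram of CDR values by eye.
#'
#' @param object A `cdr_measurements` tibble from [extract_cdr()].
#' @param binwidth Histogram bin width on the CDR scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdr_measurements <- function(object, binwidth = 0.1, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30", colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$eye)) +
    ggplot2::labs(x = "cup-to-disc ratio", y = "measurements",
                  title = "Extracted cup-to-disc ratios") +
    ggplot2::theme_minimal()
}

#' Plot chart-review performance metrics
#'
#' Bar chart of the defined metrics of a confusion tally.
#'
#' @param object A `confusion_counts` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_counts <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$estimate), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion",
                  title = "Algorithm performance") +
    ggplot2::theme_minimal()
}
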