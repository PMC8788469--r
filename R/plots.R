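#' Plot a relative abundance matrix
#'
#' Per-sample distribution of log10 relative abundances.
#'
#' @param object A `rel_abundance` tibble from [quantify()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rel_abundance <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$abundance), .data$abundance > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id,
                                    y = log10(.data$abundance))) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = "sample", y = "log10 relative abundance",
      title = sprintf("%s relative abundance", attr(object, "method"))
    )
}

#' Plot a bootstrap error distribution
#'
#' Histogram of the bootstrap medians of the absolute error, with the
#' point median marked.
#'
#' @param object A `boot_error` object from [bootstrap_absolute_error()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.boot_error <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(median_pct = object$boot_medians),
                  ggplot2::aes(x = .data$median_pct)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$median_error_pct,
                        linetype = "dashed") +
    ggplot2::labs(x = "bootstrap median absolute error (%)", y = "count")
}

#' Scatter of estimated versus expected amounts
#'
#' Log-log scatter of estimated fmol against expected fmol for the spiked
#' standards, with the identity line.
#'
#' @param estimates Long tibble `accession`, `sample_id`, `fmol`.
#' @param expected Tibble `accession`, `expected_fmol`.
#' @return A ggplot object.
#' @export
plot_recovery <- function(estimates, expected) {
  dat <- absolute_errors(estimates, expected)
  ggplot2::ggplot(dat, ggplot2::aes(x = log10(.data$expected_fmol),
                                    y = log10(.data$fmol))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "log10 expected (fmol)", y = "log10 estimated (fmol)")
}
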