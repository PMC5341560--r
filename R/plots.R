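# ggplot2 views of the main result types.

#' Plot the per-read identity histogram of a mapping report
#'
#' @param report an [mapping_report()] result.
#' @return a ggplot.
#' @export
plot_identity_histogram <- function(report) {
  ggplot2::ggplot(report$read_identity,
                  ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "best identity to any contig", y = "reads",
                  title = "Long-read mapping identity") +
    ggplot2::theme_minimal()
}

#' Plot the genes-by-isoform-count histogram of a catalogue summary
#'
#' @param summary an [summarize_catalog()] result.
#' @return a ggplot.
#' @export
plot_isoform_histogram <- function(summary) {
  ggplot2::ggplot(summary$histogram,
                  ggplot2::aes(x = factor(.data$n_isoforms),
                               y = .data$n_genes)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = "isoform classes per gene", y = "genes",
                  title = "Alternative splicing per gene") +
    ggplot2::theme_minimal()
}

#' @method autoplot iso_catalog_summary
#' @export
autoplot.iso_catalog_summary <- function(object, ...) {
  plot_isoform_histogram(object)
}

#' @method autoplot iso_mapping_report
#' @export
autoplot.iso_mapping_report <- function(object, ...) {
  plot_identity_histogram(object)
}

#' Volcano plot of a differential screen
#'
#' @param object an `iso_de` tibble from [de_screen()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot iso_de
#' @export
autoplot.iso_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$pass)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "passes cutoffs") +
    ggplot2::theme_minimal()
}

#' EM convergence trace
#'
#' @param object an `iso_em_fit` from [em_abundance()].
#' @param ... unused.
#' @return a ggplot of the log-likelihood per iteration.
#' @method autoplot iso_em_fit
#' @export
autoplot.iso_em_fit <- function(object, ...) {
  ll <- attr(object, "loglik")
  ggplot2::ggplot(tibble::tibble(iteration = seq_along(ll), loglik = ll),
                  ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(y = "log-likelihood", title = "EM convergence") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
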