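# ggplot2 visualizations and broom-style summaries for the result objects.

#' Plot an insertion spectrum as a genome-wide needle plot
#'
#' @param object a [build_spectrum()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tn_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$fraction,
                                   colour = .data$strand)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::labs(x = "genome position (nt)",
                  y = "fraction of mapped molecules",
                  title = attr(object, "sample")) +
    ggplot2::theme_minimal()
}

#' Plot called peaks along the genome
#'
#' @param object a [call_peaks()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tn_peaks <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$summit,
                                   y = .data$fold_enrichment)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$summit, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "genome position (nt)", y = "fold enrichment") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential enrichment results
#'
#' @param object a [diff_enrichment()] result.
#' @param q_cut significance threshold to color by (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tn_diff <- function(object, q_cut = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$q < q_cut
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = -log10(pmax(.data$q, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log2 fold change (end vs start)",
                  y = "-log10 q") +
    ggplot2::theme_minimal()
}

#' Plot lineage insertion traces across time points
#'
#' Long-format per-lineage spectra, faceted by time point and colored by
#' lineage barcode.
#'
#' @param lineages a [demultiplex_lineages()] result.
#' @return a ggplot object.
#' @export
plot_lineage_traces <- function(lineages) {
  df <- tibble::as_tibble(lineages)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$fraction,
                                   colour = .data$barcode)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$time_point)) +
    ggplot2::labs(x = "genome position (nt)",
                  y = "fraction of lineage molecules") +
    ggplot2::theme_minimal()
}

#' @export
tidy.tn_diff <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.tn_diff <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$q < 0.05),
    dispersion = attr(x, "dispersion"),
    libsize_start = attr(x, "library_sizes")[["start"]],
    libsize_end = attr(x, "library_sizes")[["end"]]
  )
}

#' @export
tidy.tn_spectrum <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.tn_spectrum <- function(x, ...) {
  tibble::tibble(
    sample = attr(x, "sample"),
    n_sites = nrow(x),
    total_mapped = attr(x, "total_mapped"),
    n_off_ta_positions = nrow(attr(x, "off_ta"))
  )
}
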