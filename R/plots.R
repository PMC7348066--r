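#' Plot methods for pipeline results
#'
#' `autoplot()` gives the standard diagnostic for each stage: a QQ plot of
#' gene-level p-values for a gene scan, a two-trait significance scatter for
#' the meta-analysis, and a gene x study evidence tile map for the
#' expression stage.
#'
#' @param object A `pleio_gene_scan`, `pleio_meta` or `pleio_de` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pleio_plots
NULL

#' @rdname pleio_plots
#' @importFrom ggplot2 autoplot
#' @method autoplot pleio_gene_scan
#' @export
autoplot.pleio_gene_scan <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$empirical_p)) |>
    dplyr::arrange(.data$empirical_p) |>
    dplyr::mutate(expected = -log10(stats::ppoints(dplyr::n())),
                  observed = -log10(.data$empirical_p))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  title = "Gene-based test QQ plot") +
    ggplot2::theme_minimal()
}

#' @rdname pleio_plots
#' @method autoplot pleio_meta
#' @export
autoplot.pleio_meta <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p_a), -log10(.data$p_b),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 name = "Combined\nsignificant") +
    ggplot2::labs(x = expression(-log[10](p[trait ~ A])),
                  y = expression(-log[10](p[trait ~ B])),
                  title = "Cross-trait gene evidence") +
    ggplot2::theme_minimal()
}

#' @rdname pleio_plots
#' @method autoplot pleio_de
#' @export
autoplot.pleio_de <- function(object, ...) {
  df <- object$de |>
    dplyr::mutate(neglog = -log10(.data$pvalue),
                  sig = !is.na(.data$pvalue) &
                    .data$pvalue < object$threshold)
  ggplot2::ggplot(df, ggplot2::aes(.data$study_id, .data$gene,
                                   fill = .data$neglog)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_point(data = dplyr::filter(df, .data$sig), size = 1) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p)),
                                  na.value = "grey85") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$disease),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Differential expression across studies",
                  subtitle = "dots mark study-level Bonferroni significance") +
    ggplot2::theme_minimal()
}

#' QQ plot of gene-level p-values
#' @param scan A `pleio_gene_scan`.
#' @return A ggplot object.
#' @export
plot_gene_qq <- function(scan) autoplot.pleio_gene_scan(scan)

#' Two-trait significance scatter
#' @param meta A `pleio_meta`.
#' @return A ggplot object.
#' @export
plot_meta_scatter <- function(meta) autoplot.pleio_meta(meta)

#' Gene-by-study differential-expression tile map
#' @param de A `pleio_de`.
#' @return A ggplot object.
#' @export
plot_de_tiles <- function(de) autoplot.pleio_de(de)
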