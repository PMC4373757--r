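#' Volcano plot of a paired DE result
#'
#' log2 fold change against log2 of the adjusted p-value, with significant
#' genes beyond the fold-change highlight thresholds labelled by colour and
#' dotted threshold lines, the conventional rendering of a timepoint's DE
#' landscape.
#'
#' @param de A `paired_de` object or gene-level tibble.
#' @param up_fc,down_fc Highlight thresholds (see [volcano_classify()]).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, up_fc = 2.8, down_fc = 0.35) {
  df <- volcano_classify(de, up_fc = up_fc, down_fc = down_fc)
  df <- df[!is.na(df$p_adj), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = log2(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = log2(c(down_fc, up_fc)), linetype = "dotted") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(`highlighted-up` = "firebrick",
                                            `highlighted-down` = "forestgreen",
                                            other = "grey60")) +
    ggplot2::labs(x = "log2 fold change (operated / control)",
                  y = "log2 adjusted P", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object A `paired_de` object.
#' @param ... Passed to [plot_volcano()].
#' @method autoplot paired_de
#' @export
autoplot.paired_de <- function(object, ...) plot_volcano(object, ...)

#' Observed versus expected multi-study occurrence
#'
#' Frequency histogram of genes by the number of studies they occur in
#' (squares) against the Monte-Carlo null expectation (circles), on a log
#' count scale — the standard rendering of cross-study concordance against
#' chance overlap.
#'
#' @param observed An `occurrence_profile` from [occurrence_histogram()].
#' @param null An `occurrence_null` from [occurrence_null()] (optional).
#' @return A ggplot object.
#' @export
plot_occurrence <- function(observed, null = NULL) {
  obs <- dplyr::mutate(as_tibble(observed)[, c("j", "observed")],
                       series = "observed")
  obs <- dplyr::rename(obs, count = "observed")
  df <- obs
  if (!is.null(null)) {
    exp <- dplyr::mutate(as_tibble(null)[, c("j", "expected")],
                         series = "expected (null)")
    exp <- dplyr::rename(exp, count = "expected")
    df <- dplyr::bind_rows(obs, exp)
  }
  df <- df[df$j >= 1, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = pmax(.data$count, 0.01),
                                   shape = .data$series)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line(ggplot2::aes(group = .data$series), linewidth = 0.3) +
    ggplot2::scale_shape_manual(values = c(observed = 15, `expected (null)` = 1)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of studies a gene occurs in",
                  y = "genes (log scale)", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of top enriched pathways
#'
#' @param object An `enrichment_result`.
#' @param n Number of top pathways to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, n = 15, ...) {
  df <- head(as_tibble(object), n)
  df$pathway_id <- factor(df$pathway_id, levels = rev(df$pathway_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$p_upper, 1e-300)),
                                   y = .data$pathway_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dotted") +
    ggplot2::labs(x = "-log10 P (hypergeometric upper tail)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname hypergeom_overlap
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(k = x$k, n1 = x$n1, n2 = x$n2, U = x$U,
         pmf = x$pmf, p_upper = x$p_upper)
}
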