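#' Box plots of per-proband counts by evidence strength
#'
#' One box per tool x category (first/second/third quartile, whiskers at
#' 1.5 x IQR, outliers as points), the standard presentation of per-proband
#' evidence yield.
#'
#' @param yt A `yield_table` from [tabulate_yield()].
#' @param categories Categories to display (default: the PP3 strengths).
#' @return A ggplot object.
#' @export
plot_evidence_yield <- function(yt, categories = c(
                                  "PP3_Strong", "PP3_Moderate", "PP3_Supporting"
                                )) {
  d <- yt$per_proband[yt$per_proband$category %in% categories, , drop = FALSE]
  d$category <- factor(as.character(d$category), levels = categories)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, coef = 1.5) +
    ggplot2::facet_wrap(~tool, nrow = 1) +
    ggplot2::labs(
      x = NULL, y = "rare missense variants per proband"
    ) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
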