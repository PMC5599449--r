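#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_col
#'   geom_point labs theme_minimal coord_flip facet_wrap
#' @export
ggplot2::autoplot

#' Plot a rarefaction curve
#'
#' @param object a `cs_rarefaction` tibble from [rarefaction_curve()].
#' @param ... ignored.
#' @return A ggplot: mean observed OTUs vs depth with a +/- 1 s.d. ribbon.
#' @export
autoplot.cs_rarefaction <- function(object, ...) {
  ggplot(object, aes(x = .data$depth, y = .data$mean_otus)) +
    geom_ribbon(aes(ymin = .data$mean_otus - .data$sd_otus,
                    ymax = .data$mean_otus + .data$sd_otus),
                alpha = 0.2) +
    geom_line() +
    geom_point() +
    labs(x = "Subsampling depth (reads)", y = "Observed OTUs") +
    theme_minimal()
}

#' Plot top SIMPER contributors
#'
#' @param object a `cs_simper` result.
#' @param n_top number of OTUs to show.
#' @param ... ignored.
#' @return A ggplot bar chart of percent contributions.
#' @export
autoplot.cs_simper <- function(object, n_top = 10L, ...) {
  top <- head(tidy(object), n_top)
  top$otu_id <- factor(top$otu_id, levels = rev(top$otu_id))
  ggplot(top, aes(x = .data$otu_id, y = .data$contribution_pct)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "Contribution to between-group dissimilarity (%)") +
    theme_minimal()
}

#' Plot growth calls against the criterion thresholds
#'
#' Scraped vs inoculum relative abundance on log scales, coloured by the
#' final call; the dashed lines mark the minimum-abundance criterion and the
#' increase diagonal.
#'
#' @param growth_calls output of [call_growth()] / [call_growth_all()].
#' @param params the [growth_params()] used (for the threshold line).
#' @return A ggplot.
#' @export
plot_growth_calls <- function(growth_calls, params = growth_params()) {
  eps <- 1e-5
  df <- growth_calls |>
    mutate(x = .data$rel_inoculum + eps, y = .data$rel_scraped + eps)
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$grew)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = params$min_rel_abundance + eps,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    labs(x = "Relative abundance in inoculum",
         y = "Relative abundance in scraped community",
         colour = "grew") +
    theme_minimal()
}
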