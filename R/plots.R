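#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_abline
#'   geom_smooth geom_line scale_fill_gradient2 labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Heat map of a divergence matrix
#'
#' Diverging palette: blue for non-random similarity (positive scores), red
#' for random similarity (negative scores).
#'
#' @param object A `divergence_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.divergence_matrix <- function(object, ...) {
  taxa <- rownames(object)
  df <- tidyr::expand_grid(taxon1 = taxa, taxon2 = taxa)
  df$score <- as.numeric(object[cbind(df$taxon1, df$taxon2)])
  ggplot(df, aes(x = factor(.data$taxon1, taxa),
                 y = factor(.data$taxon2, rev(taxa)), fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                         midpoint = 0, limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "similarity") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 7),
                   axis.text.y = ggplot2::element_text(size = 7))
}

#' Saturation scatter plots
#'
#' Compared distances against the reference patristic distances, one facet
#' per comparison, with the fitted OLS line and the 1:1 diagonal.
#'
#' @param object A `saturation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturation_report <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot(pairs, aes(x = .data$reference, y = .data$compared)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.6,
                colour = "#b2182b") +
    facet_wrap(~comparison, scales = "free_y") +
    labs(x = "reference patristic distance", y = "compared distance") +
    theme_minimal()
}

#' Ka against branch length
#'
#' @param object A `rate_correlation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_correlation <- function(object, ...) {
  ggplot(object$data, aes(x = .data$branch_length, y = .data$Ka)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.6) +
    labs(x = "branch length to ancestor (subs/site)",
         y = "Ka (nonsynonymous subs/site)",
         subtitle = sprintf("R² = %.2f", object$r_squared)) +
    theme_minimal()
}

#' Slow-fast support trajectories
#'
#' Bootstrap support per focal clade as the fastest sites are stripped.
#'
#' @param object A `slowfast_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.slowfast_report <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$fraction, y = .data$support, colour = .data$clade)) +
    geom_line() + geom_point(aes(shape = .data$recovered)) +
    ggplot2::scale_x_reverse() +
    labs(x = "fraction of sites retained", y = "bootstrap support") +
    theme_minimal()
}
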