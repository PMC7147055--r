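# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_histogram
#'   geom_vline geom_abline labs theme_minimal facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot PCA coordinates coloured by population
#'
#' @param object A `cnv_pca` object.
#' @param x,y Components to plot (defaults PC1, PC2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cnv_pca <- function(object, x = "PC1", y = "PC2", ...) {
  df <- object$scores
  p <- ggplot(df, aes(.data[[x]], .data[[y]]))
  if ("population" %in% names(df)) {
    p <- p + aes(colour = .data$population)
  }
  if ("group" %in% names(df)) {
    p <- p + aes(shape = .data$group)
  }
  ve <- round(100 * object$variance_explained, 1)
  i <- as.integer(sub("PC", "", c(x, y)))
  p + geom_point(size = 2) + theme_minimal() +
    labs(x = paste0(x, " (", ve[i[1]], "%)"),
         y = paste0(y, " (", ve[i[2]], "%)"),
         title = "CNV copy-number PCA")
}

#' Plot the random-placement overlap null
#'
#' Histogram of simulated by-chance overlap with the observed value marked.
#'
#' @param object An `overlap_null` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_null <- function(object, ...) {
  ggplot(tidy(object), aes(.data$overlap_bp / 1e6)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$observed_bp / 1e6, colour = "red",
               linewidth = 1) +
    theme_minimal() +
    labs(x = "overlap (Mb)", y = "replicates",
         title = "Observed vs random-placement overlap")
}

#' Bar plot of population-group sharing Venn counts
#'
#' @param sharing A `sharing_matrix` from [population_sharing()].
#' @return A ggplot.
#' @export
plot_sharing <- function(sharing) {
  ggplot(sharing$venn,
         aes(stats::reorder(.data$combination, -.data$n_bins),
             .data$n_bins)) +
    geom_col(fill = "steelblue") + theme_minimal() +
    labs(x = "group combination", y = paste0("occupied ", sharing$bin,
                                             " bp bins"),
         title = "CNVR sharing between groups")
}

#' Per-chromosome CNVR density plot
#'
#' @param density Output of [density_by_chromosome()].
#' @return A ggplot.
#' @export
plot_density_by_chromosome <- function(density) {
  ggplot(density, aes(.data$chrom, .data$cnvr_per_mb)) +
    geom_col(fill = "darkorange") + theme_minimal() +
    labs(x = NULL, y = "CNVRs per Mb", title = "CNVR density")
}

#' Copy number against haplotype dosage
#'
#' The tagging scatter: one point per sample, fractional copy number
#' against haplotype dosage, with the fitted regression line.
#'
#' @param dosage Dosage vector (0/1/2).
#' @param fractional_copy Fractional copy numbers.
#' @return A ggplot.
#' @export
plot_copy_regression <- function(dosage, fractional_copy) {
  fit <- copy_regression(dosage, fractional_copy)
  ggplot(tibble(dosage = dosage, copy = fractional_copy),
         aes(.data$dosage, .data$copy)) +
    geom_point(alpha = 0.6,
               position = ggplot2::position_jitter(width = 0.05, height = 0)) +
    geom_abline(intercept = fit$intercept, slope = fit$slope,
                colour = "red") +
    theme_minimal() +
    labs(x = "haplotype dosage", y = "fractional copy number",
         subtitle = sprintf("slope %.2f, r2 %.2f, p %.2g", fit$slope,
                            fit$r_squared, fit$p_slope))
}

#' Carrier-frequency spectrum by CNVR class
#'
#' @param regions CNVR region tibble (needs `frequency` and `class`).
#' @param bins Histogram bins (default 20).
#' @return A ggplot.
#' @export
plot_frequency_spectrum <- function(regions, bins = 20) {
  ggplot(regions, aes(100 * .data$frequency)) +
    geom_histogram(bins = bins, fill = "grey40") +
    facet_wrap(~class) + theme_minimal() +
    labs(x = "carrier frequency (%)", y = "CNVRs",
         title = "CNVR frequency spectrum")
}
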