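# ggplot2 figures for the main result types.

#' Scatter of binned means (vigintile plots)
#'
#' Draws the classic vigintile scatter: average distinct-miRNA count on the
#' x axis against the average of a gene-level feature (CV, GC content,
#' dinucleotide ratio, conservation) on the y axis, one point per bin.
#'
#' @param binned Tibble from [binned_means()].
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_binned_means <- function(binned, xlab = "mean distinct-miRNA count",
                              ylab = "mean feature value") {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$mean_y, y = .data$mean_x)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_classic()
}

#' Distribution of a per-gene value in the Q1 and Q4 groups
#'
#' @param values Tibble with `gene_id` and the value column.
#' @param strata A `gene_strata` object.
#' @param col Name of the value column (default `"cv"`).
#' @return A ggplot object (overlaid densities).
#' @export
plot_group_distributions <- function(values, strata, col = "cv") {
  d <- tidy(strata) |>
    filter(.data$group != "mid") |>
    inner_join(values, by = "gene_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[col]],
                                  fill = .data$group,
                                  colour = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = col, y = "density") +
    ggplot2::theme_classic()
}

#' @describeIn assign_quartile_groups Histogram of distinct-miRNA counts
#'   with the quartile thresholds marked.
#' @param object,x A `gene_strata` object.
#' @param ... Unused.
#' @method autoplot gene_strata
#' @export
autoplot.gene_strata <- function(object, ...) {
  ggplot2::ggplot(object$assignments, ggplot2::aes(x = .data$n_mirnas)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(object$q25_threshold,
                                       object$q75_threshold),
                        colour = "blue", linetype = 2) +
    ggplot2::labs(x = "distinct miRNAs per gene", y = "genes") +
    ggplot2::theme_classic()
}

#' @describeIn group_trajectory Mean normalized site count against species
#'   distance rank.
#' @param object A `gene_trajectory` object.
#' @param ... Unused.
#' @method autoplot gene_trajectory
#' @export
autoplot.gene_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$distance_rank,
                               y = .data$mean_norm_count)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "distance rank from reference",
                  y = "mean normalized site count",
                  title = object$group_name) +
    ggplot2::theme_classic()
}
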