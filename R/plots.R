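# ggplot2 graphics for the main result types.

#' Plot seed calls in the peak-index plane
#'
#' Scatters each called seed by embryo ploidy and peak index, coloured by
#' pathway, with the classification boundary drawn in. The canonical FCSS
#' picture: sexually derived seeds cluster at index 1.5, apomictic seeds at
#' 2 and above.
#'
#' @param calls Seed-call tibble from [call_seeds()].
#' @param pi_boundary Boundary drawn as a dashed line (default 2).
#' @return A ggplot object.
#' @export
plot_seed_calls <- function(calls, pi_boundary = 2) {
  d <- dplyr::filter(calls, is.finite(.data$peak_index),
                     is.finite(.data$embryo_x))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$embryo_x, y = .data$peak_index,
                                  colour = .data$pathway)) +
    ggplot2::geom_hline(yintercept = pi_boundary, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "embryo ploidy (x)", y = "peak index (endosperm/embryo)",
                  colour = "pathway") +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence histogram with extracted peaks
#'
#' @param hist Histogram tibble (`channel`, `count`).
#' @param peaks Optional peak tibble from [extract_peaks()]; means drawn as
#'   vertical lines.
#' @return A ggplot object.
#' @export
plot_histogram <- function(hist, peaks = NULL) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$channel, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::labs(x = "fluorescence channel", y = "events") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0)
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$mean),
                                 colour = "red", linetype = "dotted")
  p
}

#' @describeIn monte_carlo_association Null distribution of the association
#'   statistic with the observed value marked, one panel per side.
#' @param object An `fcss_assoc` object.
#' @param ... Unused.
#' @export
autoplot.fcss_assoc <- function(object, ...) {
  d <- tibble::tibble(
    side = rep(c("sex_given", "apo_given"),
               each = ncol(object$null_stats)),
    stat = c(object$null_stats[1, ], object$null_stats[2, ]))
  obs <- tibble::tibble(side = c("sex_given", "apo_given"),
                        observed = unname(object$observed))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "red") +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "% mixed plants under the null", y = "replicates") +
    ggplot2::theme_minimal()
}

#' @describeIn tetraploid_geneflow_screen Population means of the male
#'   genomic contribution against cytotype diversity, with the fitted line.
#' @param object An `fcss_geneflow` object.
#' @param ... Unused.
#' @export
autoplot.fcss_geneflow <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$shannon_H,
                               y = .data$mean_m_embryo_x)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_seeds), alpha = 0.8) +
    ggplot2::geom_abline(intercept = object$fit$intercept,
                         slope = object$fit$slope, colour = "red") +
    ggplot2::labs(x = "Shannon cytotype diversity (H)",
                  y = "mean male genomic contribution to embryo (x)",
                  size = "seeds") +
    ggplot2::theme_minimal()
}

#' @describeIn pollen_viability_glm Pooled pollen-viability proportions by
#'   cytotype (one point per population), sized by individuals pooled.
#' @param object An `fcss_pollen` object.
#' @param ... Unused.
#' @export
autoplot.fcss_pollen <- function(object, ...) {
  ggplot2::ggplot(object$pooled,
                  ggplot2::aes(x = factor(.data$ploidy_x),
                               y = .data$prop_viable)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(ggplot2::aes(size = .data$n_individuals),
                         width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "cytotype (x)", y = "proportion viable pollen",
                  size = "individuals") +
    ggplot2::theme_minimal()
}
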