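# ggplot2 displays for the package's result types. Each returns a ggplot
# object so callers can restyle freely.

#' @describeIn cmeans_fuzzy trajectory plot: one panel per cluster, member
#'   genes coloured by membership, centroid drawn in black.
#' @param object an `artr_cmeans` object.
#' @export
autoplot.artr_cmeans <- function(object, ...) {
  x <- object$data
  times <- colnames(x) %||% paste0("t", seq_len(ncol(x)))
  long <- tibble(
    gene_id = rep(rownames(x) %||% as.character(seq_len(nrow(x))),
                  times = ncol(x)),
    time = rep(seq_len(ncol(x)), each = nrow(x)),
    value = as.vector(x),
    cluster = rep(object$cluster, times = ncol(x)),
    membership = rep(object$membership[cbind(seq_len(nrow(x)),
                                             object$cluster)],
                     times = ncol(x)))
  cent <- tibble(
    time = rep(seq_len(ncol(x)), each = nrow(object$centroids)),
    value = as.vector(object$centroids),
    cluster = rep(seq_len(nrow(object$centroids)), times = ncol(x)))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene_id,
                                    colour = .data$membership),
                       alpha = 0.6) +
    ggplot2::geom_line(data = cent, linewidth = 1, colour = "black") +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(x)), labels = times) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time point", y = "z-scored binding strength",
                  colour = "membership") +
    ggplot2::theme_minimal()
}

#' @describeIn profile_matrix mean read-density profile around the anchors.
#' @param object an `artr_profile` object.
#' @param ... unused.
#' @export
autoplot.artr_profile <- function(object, ...) {
  df <- tibble(position = object$positions, density = object$mean)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from anchor (nt)",
                  y = "mean normalised read density") +
    ggplot2::theme_minimal()
}

#' Plot the minimum-centroid-distance curve
#'
#' @param dmin a [dmin_curve()] tibble.
#' @return A ggplot object (elbow diagnostic for choosing the cluster
#'   number).
#' @export
plot_dmin <- function(dmin) {
  df <- dmin %>% filter(!is.na(.data$dmin))
  ggplot2::ggplot(df, ggplot2::aes(.data$c, .data$dmin)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cluster number c", y = "minimum centroid distance") +
    ggplot2::theme_minimal()
}

#' Plot a metagene peak distribution
#'
#' @param meta a [metagene_peaks()] tibble.
#' @return A ggplot object: density along the normalised
#'   5'UTR/CDS/3'UTR axis with segment boundaries marked.
#' @export
plot_metagene <- function(meta) {
  bounds <- cumsum(tapply(meta$density, meta$segment, length))
  bounds <- meta$position[bounds[-length(bounds)]]
  ggplot2::ggplot(meta, ggplot2::aes(.data$position, .data$density,
                                     colour = .data$segment)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::geom_vline(xintercept = bounds, linetype = "dashed") +
    ggplot2::labs(x = "normalised transcript position", y = "peak density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-feature read fractions
#'
#' @param fractions an [assign_reads()] tibble.
#' @return A ggplot bar chart of the six canonical feature fractions.
#' @export
plot_feature_fractions <- function(fractions) {
  ggplot2::ggplot(fractions, ggplot2::aes(.data$feature, .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of usable reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
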