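#' Plot cluster centroid traces
#'
#' Shows each cluster's mean z-scored trace with its semantic label, the
#' standard visualization of the four fidget response types.
#'
#' @param clusters A `fidget_clusters` fit.
#' @param fps Sampling rate used for the time axis.
#' @param pre Number of pre-onset samples in the centroid traces.
#' @return A ggplot object.
#' @export
plot_response_types <- function(clusters, fps = 30, pre = 0L) {
  types <- label_clusters(clusters$centroids, pre = pre)
  k <- nrow(clusters$centroids)
  ns <- ncol(clusters$centroids)
  df <- tibble(
    cluster = rep(seq_len(k), each = ns),
    type = rep(types, each = ns),
    time_s = rep((seq_len(ns) - pre - 1) / fps, times = k),
    z = as.vector(t(clusters$centroids)))
  ggplot(df, aes(.data$time_s, .data$z, colour = .data$type,
                 group = .data$cluster)) +
    geom_line() +
    labs(x = "time from fidget onset (s)", y = "mean z-scored dF/F",
         colour = "response type") +
    theme_minimal()
}

#' Plot response-type distributions by stratum
#'
#' Bar chart of the percentage of each response type within each stratum
#' (area, layer or Cre line), as produced by [type_distribution()].
#'
#' @param dist A [type_distribution()] tibble.
#' @return A ggplot object.
#' @export
plot_type_distribution <- function(dist) {
  ggplot(dist, aes(.data$stratum, .data$percent, fill = .data$type_label)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "% of neurons", fill = "response type") +
    theme_minimal()
}

#' Plot the fidget-vs-running modulation scatter
#'
#' Per-cell fidget Cohen's d against running Cohen's d, with jointly
#' significant cells highlighted.
#'
#' @param interaction A [modulation_interaction()] result.
#' @return A ggplot object.
#' @export
plot_modulation_scatter <- function(interaction) {
  df <- interaction$scatter |>
    mutate(joint = .data$sig_fidget & .data$sig_running)
  ggplot(df, aes(.data$d_running, .data$d_fidget, colour = .data$joint)) +
    geom_point(alpha = 0.6) +
    labs(x = "running Cohen's d", y = "fidget Cohen's d",
         colour = "jointly significant") +
    theme_minimal()
}
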