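#' Heatmap of the temporal topic structure
#'
#' Renders the K x T prevalence matrix (topics as rows, quarters as
#' columns) as a heatmap, with topic rows ordered by the Ward dendrogram of
#' their time series. Colors are scaled globally over the whole matrix, on
#' the raw prevalence scale.
#'
#' @param series A `temporal_topic_series`.
#' @param file Optional output path (png/pdf inferred from extension); if
#'   `NULL` the heatmap is drawn on the current device.
#' @param ... Passed on to [pheatmap::pheatmap()].
#' @return The `pheatmap` object, invisibly.
#' @export
plot_topic_heatmap <- function(series, file = NULL, ...) {
  stopifnot(inherits(series, "temporal_topic_series"))
  mat <- t(series$values)
  ph <- pheatmap::pheatmap(
    mat,
    cluster_rows = nrow(mat) >= 2,
    cluster_cols = FALSE,
    clustering_distance_rows = "euclidean",
    clustering_method = "ward.D2",
    filename = file %||% NA,
    silent = !is.null(file),
    main = sprintf("Topical prevalence over quarters (%s)",
                   toupper(series$model_tag %||% "")),
    ...)
  invisible(ph)
}

#' Dendrogram of the topic-series clustering
#'
#' @param clustering A `topic_clustering` from [cluster_topic_series()].
#' @param file Optional png output path.
#' @return `NULL`, invisibly.
#' @export
plot_topic_dendrogram <- function(clustering, file = NULL) {
  stopifnot(inherits(clustering, "topic_clustering"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  plot(stats::as.dendrogram(clustering$hclust),
       main = "Ward clustering of topic time series",
       ylab = "merge height")
  invisible(NULL)
}

#' Line plots of per-topic prevalence series
#'
#' One panel per topic showing the quarterly mean prevalence trajectory,
#' optionally with bootstrap bands.
#'
#' @param series A `temporal_topic_series`.
#' @param ci Optional `prevalence_ci` from [bootstrap_prevalence_ci()].
#' @param topics Optional integer vector selecting topics (default all).
#' @param file Optional output path for [ggplot2::ggsave()].
#' @return The ggplot object, invisibly.
#' @export
plot_topic_series <- function(series, ci = NULL, topics = NULL,
                              file = NULL) {
  stopifnot(inherits(series, "temporal_topic_series"))
  K <- ncol(series$values)
  topics <- topics %||% seq_len(K)
  df <- do.call(rbind, lapply(topics, function(k) {
    d <- data.frame(
      quarter = seq_len(nrow(series$values)),
      prevalence = series$values[, k],
      topic = series$topic_labels[k],
      stringsAsFactors = FALSE)
    if (!is.null(ci)) {
      d$lower <- ci$lower[, k]
      d$upper <- ci$upper[, k]
    }
    d
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = quarter,
                                        y = prevalence))
  if (!is.null(ci)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = lower, ymax = upper),
      fill = "grey80")
  }
  p <- p +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~topic, scales = "free_y") +
    ggplot2::labs(x = "quarter", y = "mean topical prevalence") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 6, dpi = 120)
  }
  invisible(p)
}
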