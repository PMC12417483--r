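#' Plot the parameter-search trace of an adaptive DBSCAN fit
#'
#' Cluster count against the scanned neighbor rank k, with the selected k
#' marked; a second panel-free way to see where the count stabilized.
#'
#' @param object A `"kann_dbscan"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kann_dbscan <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$k, y = .data$n_clusters)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "neighbor rank k",
      y = "clusters found",
      title = "Adaptive DBSCAN parameter search",
      subtitle = sprintf(
        "selected k = %s, eps = %.3g, pmin = %.3g, N = %d",
        object$k, object$eps, object$pmin, object$n_clusters
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of a polarity distribution
#'
#' @param results Input accepted by [polarity_distribution()], or its output.
#' @return A ggplot.
#' @export
plot_polarity <- function(results) {
  dist <- if (is.data.frame(results) && all(c("polarity", "proportion") %in% names(results)) &&
    !"score" %in% names(results)) {
    results
  } else {
    polarity_distribution(results)
  }
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$polarity, y = .data$proportion, fill = .data$polarity)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of documents", title = "Sentiment polarity distribution") +
    ggplot2::theme_minimal()
}

#' K-average nearest-neighbor distance curve (epsilon candidates)
#'
#' @param d A distance matrix, or the tibble from [eps_candidates()].
#' @return A ggplot of the candidate epsilon against k.
#' @export
plot_eps_candidates <- function(d) {
  cand <- if (is.data.frame(d)) d else eps_candidates(d)
  ggplot2::ggplot(cand, ggplot2::aes(x = .data$k, y = .data$eps)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "neighbor rank k", y = expression(bar(D)[k]),
      title = "Epsilon candidate list (K-average NN distance)"
    ) +
    ggplot2::theme_minimal()
}
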