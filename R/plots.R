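#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an n-gram selection
#'
#' Bar chart of the chi-square values of the top n-grams, colored by
#' direction (overrepresented in successful vs failed sequences), key
#' segments opaque.
#'
#' @param object An `ngram_selection`.
#' @param top_n How many n-grams to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ngram_selection <- function(object, top_n = 20, ...) {
  df <- utils::head(tidy(object), top_n)
  df$ngram <- factor(df$ngram, levels = rev(df$ngram))
  df$group <- ifelse(df$direction >= 0, "successful", "failed")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chi2, y = .data$ngram,
                                   fill = .data$group,
                                   alpha = .data$key)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                guide = "none") +
    ggplot2::labs(x = "chi-square", y = NULL, fill = "overrepresented in",
                  title = sprintf("%d-gram chi-square selection (%s)",
                                  attr(object, "n"),
                                  attr(object, "representation") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-number scan
#'
#' Mean silhouette and Calinski-Harabasz index against the number of
#' clusters, each on its own panel (free y scales), maximizers highlighted.
#'
#' @param object A `kscan` tibble from [scan_k()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kscan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[c("k", "silhouette", "ch")],
    c("silhouette", "ch"), names_to = "index", values_to = "value")
  best <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(object, .data$best_silhouette),
                  index = "silhouette", value = .data$silhouette),
    dplyr::mutate(dplyr::filter(object, .data$best_ch),
                  index = "ch", value = .data$ch))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = best, color = "red", size = 3) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "number of clusters", y = NULL,
                  title = "Cluster validity indices across k") +
    ggplot2::theme_minimal()
}

#' Plot a clustering
#'
#' Per-sequence silhouette widths grouped by cluster.
#'
#' @param object A `seq_clustering` with the distance matrix attached (as
#'   from [cluster_sequences()]) or `D` supplied.
#' @param D The distance matrix, if not attached to `object`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seq_clustering <- function(object, D = attr(object, "D"), ...) {
  if (is.null(D)) stop("supply the distance matrix D", call. = FALSE)
  sil <- cluster::silhouette(object$assignment, dmatrix = as.matrix(D))
  df <- tibble::tibble(cluster = factor(sil[, "cluster"]),
                       width = sil[, "sil_width"])
  df <- dplyr::arrange(df, .data$cluster, dplyr::desc(.data$width))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$width,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = object$silhouette, linetype = 2) +
    ggplot2::labs(x = "sequences (sorted within cluster)",
                  y = "silhouette width",
                  title = sprintf("k = %d, mean silhouette %.3f",
                                  object$k, object$silhouette)) +
    ggplot2::theme_minimal()
}

#' Plot the effectiveness profile of encoded sequences
#'
#' Step-by-step post-move state effectiveness trajectories for a sample of
#' groups, highlighting approach to the target (d = 0).
#'
#' @param encoded Output of [encode_sequences()].
#' @param groups Optional group ids to show (default: first 12).
#' @return A ggplot.
#' @export
plot_effectiveness_profile <- function(encoded, groups = NULL) {
  ids <- unique(encoded$group_id)
  if (is.null(groups)) groups <- utils::head(ids, 12)
  df <- dplyr::filter(encoded, .data$group_id %in% groups)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$d_post)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~group_id) +
    ggplot2::labs(x = "action", y = "state effectiveness d after the action",
                  title = "Distance-to-target trajectories") +
    ggplot2::theme_minimal()
}
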