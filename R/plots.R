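#' SAM quantile plot
#'
#' The classic SAM diagnostic: observed scores against the permutation
#' expected order statistics, with the identity line and the selected
#' delta band; called genes are highlighted by direction.
#'
#' @param object a `sam_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sam_fit <- function(object, ...) {
  df <- tidy(object) |> dplyr::arrange(.data$rank)
  df$status <- ifelse(!df$called, "not called",
                      ifelse(df$direction == "up", "up", "down"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected_d, y = .data$d,
                                   colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = c(-1, 1) * object$delta,
                         linetype = 3, colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`not called` = "grey60",
                                            up = "firebrick", down = "steelblue")) +
    ggplot2::labs(x = "expected score (permutation order statistic)",
                  y = "observed SAM score d",
                  colour = NULL,
                  title = sprintf("SAM: %s vs %s (delta = %.3g, est. FDR = %.3g)",
                                  object$contrast[1], object$contrast[2],
                                  object$delta, object$fdr_estimate)) +
    ggplot2::theme_minimal()
}

#' Dendrogram plot with group annotation
#'
#' Segment-based rendering of a UPGMA tree; leaves can be coloured by a
#' per-sample label (e.g. MMR status) to mirror the two-major-cluster
#' readout.
#'
#' @param object an `upgma` tree.
#' @param labels optional named character vector (or tibble with `sample_id`
#'   plus one label column) colouring the leaf marks.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.upgma <- function(object, labels = NULL, ...) {
  n <- length(object$labels)
  pos <- numeric(n)
  pos[object$order] <- seq_len(n)
  node_x <- function(k) {
    if (k < 0) return(pos[-k])
    mean(c(node_x(object$merge[k, 1]), node_x(object$merge[k, 2])))
  }
  node_h <- function(k) if (k < 0) 0 else object$height[k]
  segs <- purrr::map_dfr(seq_len(n - 1), function(k) {
    kids <- object$merge[k, ]
    xs <- vapply(kids, node_x, numeric(1))
    hs <- vapply(kids, node_h, numeric(1))
    dplyr::bind_rows(
      tibble::tibble(x = xs, xend = xs, y = hs, yend = object$height[k]),
      tibble::tibble(x = xs[1], xend = xs[2],
                     y = object$height[k], yend = object$height[k])
    )
  })
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::labs(x = NULL, y = "merge height (1 - Pearson r)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      val_col <- setdiff(names(labels), "sample_id")[1]
      v <- labels[[val_col]]
      names(v) <- labels$sample_id
      labels <- v
    }
    leaf_df <- tibble::tibble(x = pos, y = -0.02 * max(object$height),
                              group = unname(labels[object$labels]))
    p <- p +
      ggplot2::geom_point(data = leaf_df,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$group),
                          shape = 15, size = 1.5) +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Classification-report plot
#'
#' Per-sample correlations to the two class centroids, coloured by MMR
#' status, with the decision diagonal.
#'
#' @param object a `classification_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- object$per_sample
  rcols <- grep("^r_", names(df), value = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[rcols[1]]],
                                   y = .data[[rcols[2]]],
                                   colour = .data$mmr_status,
                                   shape = .data$correct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = "Nearest-centroid classification",
                  x = paste("Pearson r to", sub("^r_", "", rcols[1]), "centroid"),
                  y = paste("Pearson r to", sub("^r_", "", rcols[2]), "centroid"),
                  colour = "MMR status", shape = "correct") +
    ggplot2::theme_minimal()
}
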