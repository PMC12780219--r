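#' Embedding scatter plot of a pipeline run
#'
#' Cells on the first two embedding coordinates (UMAP when computed,
#' otherwise PC1/PC2), colored by cluster, with the identified marker
#' cluster emphasized.
#'
#' @param run A `scgain_run`.
#' @param color One of `"cluster"`, `"truth"`, `"cnv"`.
#' @return A ggplot object.
#' @export
plot_embedding <- function(run, color = c("cluster", "truth", "cnv")) {
  color <- match.arg(color)
  df <- tidy(run)
  if (!is.null(run$umap)) {
    df$dim1 <- run$umap[, 1]; df$dim2 <- run$umap[, 2]
    axes <- c("UMAP1", "UMAP2")
  } else axes <- c("PC1", "PC2")
  aes_col <- switch(color,
                    cluster = ggplot2::aes(color = factor(.data$cluster)),
                    truth = ggplot2::aes(color = .data$truth_label),
                    cnv = ggplot2::aes(color = .data$cnv_score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::geom_point(aes_col, size = 0.4, alpha = 0.6) +
    ggplot2::geom_point(data = df[df$in_marker_cluster, , drop = FALSE],
                        color = "red", size = 1.2) +
    ggplot2::labs(x = axes[1], y = axes[2],
                  color = color,
                  title = "Input-gain clustering",
                  subtitle = "marker cluster in red") +
    ggplot2::theme_minimal()
}

#' Histogram of per-cell CNV scores with the positivity threshold
#'
#' @param scores Named vector from [cnv_score()].
#' @param threshold Gate drawn as a vertical line.
#' @param labels Optional per-cell grouping (e.g. truth labels).
#' @return A ggplot object.
#' @export
plot_cnv_scores <- function(scores, threshold = 1.009, labels = NULL) {
  df <- tibble(score = as.numeric(scores),
               group = if (is.null(labels)) "all"
               else as.character(labels[names(scores)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "CNV score", y = "cells",
                  title = "Expression-based CNV score") +
    ggplot2::theme_minimal()
}

#' Running-sum enrichment plot for one gene set
#'
#' @param ranked_stats Named statistic vector (as in [preranked_gsea()]).
#' @param gene_set Character gene set.
#' @param weight_p Hit-weight exponent.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(ranked_stats, gene_set, weight_p = 1) {
  ord <- order(-ranked_stats, names(ranked_stats))
  s <- ranked_stats[ord]
  nm <- names(s)
  hit <- nm %in% gene_set
  w <- abs(s)^weight_p
  nr <- sum(w[hit])
  inc <- numeric(length(s))
  inc[hit] <- if (nr > 0) w[hit] / nr else 1 / sum(hit)
  inc[!hit] <- -1 / (length(s) - sum(hit))
  run <- cumsum(inc)
  df <- tibble(rank = seq_along(run), running = run, hit = hit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line(color = "darkgreen") +
    ggplot2::geom_rug(data = df[df$hit, , drop = FALSE], sides = "b",
                      alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "rank", y = "running enrichment score") +
    ggplot2::theme_minimal()
}

#' @rdname plot_embedding
#' @param object A `scgain_run`.
#' @param ... Passed to [plot_embedding()].
#' @export
autoplot.scgain_run <- function(object, ...) plot_embedding(object, ...)
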