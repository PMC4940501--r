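#' Heatmap of a bipartite web
#'
#' Interaction counts as a tile map, rows and columns optionally ordered and
#' outlined by a module partition (the usual way module structure is shown
#' for these webs).
#'
#' @param object A [bipartite_web()].
#' @param partition Optional `module_partition` from [find_modules()]; rows
#'   and columns are sorted by module and module blocks are outlined.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bipartite_web <- function(object, partition = NULL, ...) {
  long <- tidy(object, keep_zero = TRUE)
  if (!is.null(partition)) {
    mod <- stats::setNames(partition$module, partition$node)
    long$plant <- factor(long$plant,
                         levels = rownames(object)[order(mod[rownames(object)])])
    long$taxon <- factor(long$taxon,
                         levels = colnames(object)[order(mod[colnames(object)])])
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon, y = .data$plant,
                                          fill = .data$count)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "navy") +
    ggplot2::labs(x = "bacterial taxon", y = "legume species",
                  fill = "nodules") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
  if (!is.null(partition)) {
    mod <- stats::setNames(partition$module, partition$node)
    rlev <- levels(long$plant); clev <- levels(long$taxon)
    boxes <- dplyr::bind_rows(lapply(unique(partition$module), function(m) {
      ri <- which(mod[rlev] == m); ci <- which(mod[clev] == m)
      if (!length(ri) || !length(ci)) return(NULL)
      tibble::tibble(xmin = min(ci) - 0.5, xmax = max(ci) + 0.5,
                     ymin = min(ri) - 0.5, ymax = max(ri) + 0.5)
    }))
    if (nrow(boxes)) {
      p <- p + ggplot2::geom_rect(
        data = boxes,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = .data$ymin, ymax = .data$ymax),
        inherit.aes = FALSE, fill = NA, color = "red", linewidth = 0.6)
    }
  }
  p
}

#' Null-distribution plot for a web statistic
#'
#' Histogram of the null values with the observed statistic marked — the
#' standard visual for a fixed-marginal randomization test.
#'
#' @param object A `null_ensemble` from [null_distribution()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_ensemble <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red",
                        linewidth = 0.8) +
    ggplot2::labs(x = object$statistic, y = "null webs",
                  title = sprintf("%s: observed vs %d fixed-marginal nulls",
                                  object$statistic, length(object$null))) +
    ggplot2::theme_minimal()
}

#' Network metrics across sites and delineation levels
#'
#' Dot plot of each network-level metric per web, faceted by metric — a
#' quick reading of how topology shifts along the invasion gradient and
#' with taxon resolution.
#'
#' @param object An `analysis_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.analysis_report <- function(object, ...) {
  long <- object$networks |>
    dplyr::select(dplyr::all_of(c("level", "web", "connectance",
                                  "interaction_evenness", "wnodf", "Q",
                                  "h2prime", "generality_plants",
                                  "generality_bacteria"))) |>
    tidyr::pivot_longer(-c("level", "web"), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$web, y = .data$value,
                                     color = .data$level,
                                     group = .data$level)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, color = "level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
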