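# ggplot2 views of spectra matches and annotated networks.

#' Plot an observed spectrum with matched predicted fragments
#'
#' Peaks as vertical segments; fragments matched by [match_peaks()] are
#' colored by kind and labeled.
#'
#' @param spectrum A one-row spectra tibble or list with `peaks`.
#' @param match A `match_result` from [match_peaks()].
#' @return A ggplot object.
#' @export
plot_spectrum_match <- function(spectrum, match) {
  peaks <- if (is.data.frame(spectrum)) {
    if ("peaks" %in% names(spectrum)) spectrum$peaks[[1]] else spectrum
  } else spectrum$peaks[[1]]
  matched <- match$matched
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0, yend = .data$intensity),
                          color = "grey60", linewidth = 0.3) +
    ggplot2::geom_segment(
      data = matched,
      ggplot2::aes(x = .data$obs_mz, xend = .data$obs_mz, y = 0,
                   yend = .data$intensity, color = .data$kind),
      linewidth = 0.7
    ) +
    ggplot2::geom_text(
      data = matched,
      ggplot2::aes(x = .data$obs_mz, y = .data$intensity, label = .data$label,
                   color = .data$kind),
      angle = 90, hjust = -0.1, size = 2.8, show.legend = FALSE
    ) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, 0.25))) +
    ggplot2::labs(x = "m/z", y = "intensity", color = "ion kind") +
    ggplot2::theme_minimal()
}

#' Plot an annotated molecular network
#'
#' Nodes laid out with a force-directed algorithm, colored by annotation
#' level; unannotated nodes in grey.
#'
#' @param object A `cdp_pipeline` object.
#' @param label Label annotated nodes with their compound name.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdp_pipeline <- function(object, label = TRUE, ...) {
  net <- object$network
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes$id))
  set.seed(42) # layout only
  xy <- igraph::layout_with_fr(g)
  pos <- tibble::tibble(id = net$nodes$id, x = xy[, 1], y = xy[, 2])
  ann <- object$annotations |>
    dplyr::distinct(.data$node_id, .keep_all = TRUE) |>
    dplyr::select("node_id", "name", "level")
  pos <- dplyr::left_join(pos, ann, by = c(id = "node_id"))
  pos$level[is.na(pos$level)] <- "unannotated"
  seg <- dplyr::left_join(net$edges, pos[, c("id", "x", "y")], by = c(from = "id")) |>
    dplyr::left_join(pos[, c("id", "x", "y")], by = c(to = "id"),
                     suffix = c("", "end"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y, color = .data$level),
                        size = 3) +
    ggplot2::scale_color_manual(values = c(
      database = "#4477AA", denovo = "#66CCEE", deep_mined = "#EE6677",
      propagated = "#CCBB44", revised = "#AA3377", unannotated = "grey70"
    ), na.value = "grey70") +
    ggplot2::theme_void() +
    ggplot2::labs(color = "annotation level")
  if (label) {
    p <- p + ggplot2::geom_text(
      data = pos[!is.na(pos$name), ],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      size = 2.6, vjust = -1.2
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
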