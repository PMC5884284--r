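# ggplot2 views of the result types. Cluster labels use the run-wide
# colormap from label_color(): dark blue ("01") through bright yellow
# (all channels), gray for unassigned cells.

#' Plot a TFT/iTFT map
#'
#' One tile per (window, channel), faceted by band, filled with the
#' label's run-consistent color.
#'
#' @param object A `pc_tft`.
#' @param universe Optional character vector of labels fixing the
#'   colormap across several maps of the same run.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pc_tft <- function(object, universe = NULL, ...) {
  df <- tidy(object)
  uni <- universe %||% unique(df$label)
  cols <- label_color(unique(df$label), universe = uni)
  pal <- stats::setNames(cols$hex, cols$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$channel,
                                   fill = .data$label)) +
    ggplot2::geom_tile(color = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = pal, name = "cluster") +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = "time window", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a TFL contrast map
#'
#' Band-by-window heatmap of Levenshtein distances for one channel,
#' scaled from 0 (conditions agree) to the channel count.
#'
#' @param object A `pc_tfl` from [tfl_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pc_tfl <- function(object, ...) {
  n_ch <- attr(object, "n_ch")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window, y = .data$band,
                                       fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#00008B", high = "#FFFF00",
                                 limits = c(0, n_ch), name = "LD") +
    ggplot2::labs(x = "time window", y = "band (Hz)",
                  title = paste0("TFL map, channel ", attr(object, "channel"))) +
    ggplot2::theme_minimal()
}

#' Scalp map of cluster labels at one map cell
#'
#' Projects the montage to 2-D (orthographic from above, nose up) and
#' colors each electrode by its cluster label.
#'
#' @param labels Character vector of hex labels, one per channel in
#'   montage order.
#' @param montage A `pc_montage`.
#' @param universe Labels fixing the colormap (defaults to those shown).
#' @return A ggplot.
#' @export
plot_scalp <- function(labels, montage, universe = labels) {
  stopifnot(length(labels) == nrow(montage))
  cols <- label_color(labels, universe = universe)
  df <- tibble::tibble(channel = montage$channel, x = montage$x, y = montage$y,
                       label = labels, hex = cols$hex)
  circ <- tibble::tibble(t = seq(0, 2 * pi, length.out = 181))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = cos(.data$t), y = sin(.data$t)),
                       inherit.aes = FALSE, color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$label), size = 6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 2.5,
                       vjust = -1.6) +
    ggplot2::scale_color_manual(values = stats::setNames(cols$hex, cols$label),
                                name = "cluster") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a windowed TF power map for one channel
#'
#' @param power_map channels x windows x bands array (as returned in
#'   `run_pipeline()$power_maps`).
#' @param channel Channel name or index.
#' @return A ggplot.
#' @export
plot_power_map <- function(power_map, channel) {
  ch_names <- dimnames(power_map)[[1]]
  j <- if (is.character(channel)) match(channel, ch_names) else as.integer(channel)
  if (is.na(j)) stop("unknown channel: ", channel, call. = FALSE)
  d <- dim(power_map)
  bands <- dimnames(power_map)[[3]] %||% as.character(seq_len(d[3]))
  df <- tibble::tibble(
    band = rep(bands, each = d[2]),
    window = rep(seq_len(d[2]), times = d[3]),
    power = as.numeric(power_map[j, , ])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$band,
                                   fill = .data$power)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "power") +
    ggplot2::labs(x = "time window", y = "band (Hz)") +
    ggplot2::theme_minimal()
}
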