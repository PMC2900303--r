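# Fig-2-style colors for composite maps: purple = few events, yellow/red = many.
composite_palette <- c("#2D004B", "#542788", "#8073AC", "#E08214", "#FDB863", "#D7191C")

#' Plot a composite activity map
#'
#' @param object A `composite_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot composite_map
#' @export
autoplot.composite_map <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$counts)) - 1L,
                    col = seq_len(ncol(object$counts)) - 1L)
  df$count <- as.vector(object$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = composite_palette) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Composite map (%d transients)", object$n_events),
                  x = "column (px)", y = "row (px)", fill = "events") +
    ggplot2::theme_minimal()
}

#' Plot one pseudocolored frame of a ratio stack
#'
#' @param object A `ratio_stack`.
#' @param frame 0-based frame index. Default 0.
#' @param range Display range `c(lo, hi)`; default [display_range()] of the
#'   session.
#' @param ... Unused.
#' @return A ggplot (raster of the 8-bit pseudocolor render).
#' @method autoplot ratio_stack
#' @export
autoplot.ratio_stack <- function(object, frame = 0, range = NULL, ...) {
  tt <- dim(object$ratio)[3]
  if (frame < 0 || frame >= tt) stop_validation("frame out of bounds")
  if (is.null(range)) range <- display_range(object)
  rgbarr <- encode_pseudocolor(object$ratio[, , frame + 1L], range[1], range[2],
                               valid = object$valid[, , frame + 1L])
  df <- expand.grid(row = seq_len(dim(rgbarr)[1]) - 1L,
                    col = seq_len(dim(rgbarr)[2]) - 1L)
  df$colour <- grDevices::rgb(as.vector(rgbarr[, , 1]), as.vector(rgbarr[, , 2]),
                              as.vector(rgbarr[, , 3]), maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$colour) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Ratio frame %d (t = %gs)", frame,
                                  object$t0_s + frame * object$dt_s),
                  x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Plot per-group transient rates
#'
#' Bar of group mean rates with per-embryo points overlaid, in the shape of
#' a per-treatment frequency table.
#'
#' @param rates Tibble with `group`, `rate` columns (see
#'   [summarize_groups()]).
#' @return A ggplot.
#' @export
plot_rate_summary <- function(rates) {
  stopifnot(all(c("group", "rate") %in% names(rates)))
  means <- rates |>
    group_by(.data$group) |>
    summarise(mean_rate = mean(.data$rate), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$group, y = .data$mean_rate)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_jitter(data = rates, ggplot2::aes(y = .data$rate),
                         width = 0.08, height = 0, size = 2) +
    ggplot2::labs(x = NULL, y = "Ca2+ transients per hour") +
    ggplot2::theme_minimal()
}
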