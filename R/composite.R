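#' Accumulate the per-session composite activity map
#'
#' The topographic composite of a session: for each pixel, the number of
#' transient events whose (union) footprint covered it. Each event
#' increments each of its footprint pixels exactly once; sustained events
#' are excluded by default.
#'
#' @param table An event table from [detect_events()] (must carry
#'   footprints).
#' @param shape Image dimensions `c(height, width)`; defaults to the
#'   table's recorded shape.
#' @param include_sustained Count sustained events too? Default `FALSE`.
#' @return A `composite_map`: list with `counts` (integer matrix) and
#'   `n_events` (number of events counted).
#' @export
accumulate_composite <- function(table, shape = NULL, include_sustained = FALSE) {
  if (is.null(shape)) shape <- c(attr(table, "height"), attr(table, "width"))
  shape <- as.integer(shape)
  if (length(shape) != 2 || anyNA(shape) || any(shape < 1)) {
    stop_validation("shape must be c(height, width)")
  }
  keep <- if (include_sustained) rep(TRUE, nrow(table)) else table$label == "transient"
  counts <- matrix(0L, shape[1], shape[2])
  feet <- table$footprint[keep]
  for (fp in feet) {
    if (is.null(fp)) stop_validation("event table has no footprints (read from CSV?)")
    if (length(fp) && (min(fp) < 1 || max(fp) > prod(shape))) {
      stop_validation("event footprint out of image bounds")
    }
    counts[fp] <- counts[fp] + 1L
  }
  structure(list(counts = counts, n_events = sum(keep)), class = "composite_map")
}

#' @export
print.composite_map <- function(x, ...) {
  cat(sprintf("<composite_map> %d x %d px, %d events, max count %d\n",
              nrow(x$counts), ncol(x$counts), x$n_events, max(x$counts)))
  invisible(x)
}

#' Contrast Ca2+ activity inside versus outside a region of interest
#'
#' The localized-suppression assay: transient events are assigned to the
#' ROI or its complement by the nearest pixel to their centroid, giving
#' event rates per hour for each region, alongside the session-mean valid
#' ratio per region. `suppression` is `rate_in / rate_out` (NA when no
#' events occurred outside).
#'
#' @param table An event table.
#' @param ratios The session `ratio_stack`.
#' @param roi Logical ROI mask (see [roi_from_reference()]).
#' @param session_hours Session duration in hours (> 0).
#' @return A one-row tibble: `rate_in`, `rate_out` (events/hour),
#'   `mean_ratio_in`, `mean_ratio_out`, `suppression`, `n_in`, `n_out`.
#' @export
roi_contrast <- function(table, ratios, roi, session_hours) {
  stopifnot(inherits(ratios, "ratio_stack"))
  if (!is.numeric(session_hours) || length(session_hours) != 1 || session_hours <= 0) {
    stop_validation("session_hours must be a single positive number")
  }
  roi <- as.matrix(roi)
  hw <- dim(ratios$ratio)[1:2]
  if (!identical(dim(roi), hw)) stop_shape("roi does not match ratio stack dims")
  if (!any(roi)) stop_degenerate("ROI is empty")

  tr <- table[table$label == "transient", , drop = FALSE]
  inside <- logical(nrow(tr))
  if (nrow(tr)) {
    r <- pmin(pmax(round(tr$centroid_row) + 1, 1), hw[1])
    c <- pmin(pmax(round(tr$centroid_col) + 1, 1), hw[2])
    inside <- roi[cbind(r, c)]
  }
  n_in <- sum(inside); n_out <- sum(!inside)

  tt <- dim(ratios$ratio)[3]
  roi_rep <- array(roi, dim = c(hw, tt))
  vin <- ratios$valid & roi_rep
  vout <- ratios$valid & !roi_rep
  mean_in <- if (any(vin)) mean(ratios$ratio[vin]) else NA_real_
  mean_out <- if (any(vout)) mean(ratios$ratio[vout]) else NA_real_

  tibble(
    rate_in = n_in / session_hours, rate_out = n_out / session_hours,
    mean_ratio_in = mean_in, mean_ratio_out = mean_out,
    suppression = if (n_out > 0) n_in / n_out else NA_real_,
    n_in = n_in, n_out = n_out
  )
}
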