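#' Detection parameters for the subtractive transient analysis
#'
#' @param k_sigma Threshold multiplier in robust standard deviations of the
#'   pooled frame-difference noise. Default 4.
#' @param min_area_px Minimum detection footprint in pixels. Default 4.
#' @param max_gap_frames Dropout frames tolerated inside one event before it
#'   is closed. Default 0 (a single sub-threshold frame splits an event).
#' @param d_max_s Maximum persistence, in seconds, for an event to count as
#'   a transient rather than sustained release. Default 30 s, the
#'   "persists no longer than thirty seconds" rule; the bound is inclusive.
#' @param link_min_overlap Minimum footprint overlap (fraction of the
#'   smaller footprint) to link detections across consecutive frames into
#'   one event. Default 0.25.
#' @param max_area_px Optional footprint ceiling for sensitivity analyses;
#'   events larger than this are dropped. Default `Inf`: size never
#'   disqualifies an event (morphant transients are deliberately large).
#' @return A `detection_params` list.
#' @export
detection_params <- function(k_sigma = 4, min_area_px = 4, max_gap_frames = 0,
                             d_max_s = 30, link_min_overlap = 0.25,
                             max_area_px = Inf) {
  p <- list(k_sigma = k_sigma, min_area_px = as.integer(min_area_px),
            max_gap_frames = as.integer(max_gap_frames), d_max_s = d_max_s,
            link_min_overlap = link_min_overlap, max_area_px = max_area_px)
  if (!is.numeric(p$k_sigma) || p$k_sigma <= 0) stop_validation("k_sigma must be > 0")
  if (p$min_area_px < 1) stop_validation("min_area_px must be >= 1")
  if (p$max_gap_frames < 0) stop_validation("max_gap_frames must be >= 0")
  if (!is.numeric(p$d_max_s) || p$d_max_s <= 0) stop_validation("d_max_s must be > 0")
  if (p$link_min_overlap <= 0 || p$link_min_overlap > 1) {
    stop_validation("link_min_overlap must be in (0, 1]")
  }
  structure(p, class = "detection_params")
}

#' Classify an event by the persistence rule
#'
#' An elevation is a transient when it persists no longer than `d_max_s`
#' (boundary inclusive); longer elevations are sustained release.
#'
#' @param duration_s Event duration in seconds (> 0).
#' @param d_max_s Persistence bound in seconds (> 0), default 30.
#' @return `"transient"` or `"sustained"` (vectorized over `duration_s`).
#' @export
classify_duration <- function(duration_s, d_max_s = 30) {
  if (!is.numeric(duration_s) || any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    stop_validation("duration_s must be positive")
  }
  if (!is.numeric(d_max_s) || length(d_max_s) != 1 || d_max_s <= 0) {
    stop_validation("d_max_s must be a single positive number")
  }
  ifelse(duration_s <= d_max_s, "transient", "sustained")
}

#' Detect localized Ca2+ release events in a ratio stack
#'
#' The subtractive analysis. Consecutive ratio frames are differenced;
#' a pooled robust noise scale `sigma = 1.4826 * mad` of the differences
#' sets the detection threshold `k_sigma * sigma`. Per frame, 8-connected
#' suprathreshold components of at least `min_area_px` pixels become
#' detections; detections in consecutive frames whose footprints overlap by
#' at least `link_min_overlap` of the smaller footprint are linked into one
#' event. A pixel stays part of an ongoing event while its ratio remains
#' above its pre-onset baseline plus the threshold, so event duration
#' measures elevation, not only the rising phase. Each event is measured
#' (onset, offset, duration, peak-frame centroid, maximum footprint, peak
#' amplitude above baseline) and labeled transient or sustained by the
#' `d_max_s` persistence rule. Only increases are detected; negative-going
#' deflections are ignored.
#'
#' @param ratios A `ratio_stack` with at least 2 frames.
#' @param params A [detection_params()] list.
#' @return An event table: a tibble with columns `id`, `onset_frame`,
#'   `offset_frame` (0-based, inclusive), `duration_s`, `centroid_row`,
#'   `centroid_col` (0-based pixels), `area_px`, `peak_delta_ratio`,
#'   `label`, and a `footprint` list-column of linear pixel indices of the
#'   union footprint; sorted by onset. Attributes carry `dt_s` and the
#'   frame shape.
#' @export
detect_events <- function(ratios, params = detection_params()) {
  stopifnot(inherits(ratios, "ratio_stack"), inherits(params, "detection_params"))
  d <- dim(ratios$ratio)
  h <- d[1]; w <- d[2]; tt <- d[3]; hw <- h * w
  if (tt < 2) stop_validation("detection needs at least 2 frames")
  R <- ratios$ratio; V <- ratios$valid
  if (!any(V)) {
    return(empty_event_table(ratios$dt_s, h, w, ratios$t0_s, tt))
  }

  # frame differences on pixels valid in both frames
  Dif <- R[, , 2:tt, drop = FALSE] - R[, , 1:(tt - 1), drop = FALSE]
  vp <- V[, , 2:tt, drop = FALSE] & V[, , 1:(tt - 1), drop = FALSE]
  dv <- Dif[vp]
  if (length(dv) == 0) {
    return(empty_event_table(ratios$dt_s, h, w, ratios$t0_s, tt))
  }
  sigma <- 1.4826 * median(abs(dv - median(dv)))
  thr <- params$k_sigma * sigma
  active <- vp & (Dif > thr)

  open <- list()      # open events
  done <- list()      # finalized events
  next_id <- 1L

  finalize <- function(ev) {
    foot <- sort(unique(ev$union))
    rows0 <- ((foot - 1L) %% h)          # 0-based
    cols0 <- (foot - 1L) %/% h
    peak_foot <- ev$peak_foot
    pr0 <- ((peak_foot - 1L) %% h)
    pc0 <- (peak_foot - 1L) %/% h
    list(id = ev$id,
         onset_frame = ev$onset_i - 1L, offset_frame = ev$last_i - 1L,
         duration_s = (ev$last_i - ev$onset_i + 1L) * ratios$dt_s,
         centroid_row = mean(pr0), centroid_col = mean(pc0),
         area_px = ev$area_max, peak_delta_ratio = ev$peak_delta,
         footprint = foot)
  }

  for (t in 2:tt) {
    off3 <- (t - 1L) * hw
    # elevated continuation of open events
    for (j in seq_along(open)) {
      ev <- open[[j]]
      p <- ev$pixels
      keep <- V[off3 + p] & (R[off3 + p] > ev$base + thr)
      open[[j]]$elev_now <- p[keep]
    }
    # difference-based detections this frame
    comps <- label_components_8(matrix(active[, , t - 1L], h, w))
    if (length(comps)) comps <- comps[lengths(comps) >= params$min_area_px]

    # Link detections to open events by overlap with the event's detection
    # footprint of the previous frame(s). Linking is between rises only:
    # elevation persistence keeps an event open and measures its duration,
    # but a fresh rise on top of an already-elevated plateau (e.g. a
    # transient over a sustained domain) is a new event.
    det_ev <- rep(0L, length(comps))
    if (length(comps) && length(open)) {
      for (k in seq_along(comps)) {
        best <- 0; best_j <- 0L
        for (j in seq_along(open)) {
          fp <- open[[j]]$det_prev
          if (length(fp) == 0) next
          ov <- length(intersect(comps[[k]], fp)) /
            min(length(comps[[k]]), length(fp))
          if (ov >= params$link_min_overlap && ov > best) {
            best <- ov; best_j <- j
          }
        }
        det_ev[k] <- best_j
      }
    }

    # update open events with their footprint at t
    for (j in seq_along(open)) {
      ev <- open[[j]]
      foot_t <- ev$elev_now
      linked <- which(det_ev == j)
      for (k in linked) {
        newpix <- setdiff(comps[[k]], ev$pixels)
        if (length(newpix)) {
          # baseline of a joining pixel = its ratio just before it activated
          ev$pixels <- c(ev$pixels, newpix)
          ev$base <- c(ev$base, R[(t - 2L) * hw + newpix])
        }
        foot_t <- union(foot_t, comps[[k]])
      }
      if (length(linked)) {
        ev$det_prev <- sort(unique(unlist(comps[linked])))
        ev$det_gap <- 0L
      } else {
        ev$det_gap <- ev$det_gap + 1L
        if (ev$det_gap > params$max_gap_frames) ev$det_prev <- integer(0)
      }
      if (length(foot_t)) {
        ev$union <- union(ev$union, foot_t)
        ev$area_max <- max(ev$area_max, length(foot_t))
        delta <- R[off3 + foot_t] - ev$base[match(foot_t, ev$pixels)]
        pk <- max(delta)
        if (pk > ev$peak_delta) {
          ev$peak_delta <- pk
          ev$peak_foot <- foot_t
        }
        ev$last_i <- t
        ev$gap <- 0L
      } else {
        ev$gap <- ev$gap + 1L
      }
      open[[j]] <- ev
    }

    # close events that exceeded the allowed gap
    if (length(open)) {
      closing <- vapply(open, function(ev) ev$gap > params$max_gap_frames, logical(1))
      for (ev in open[closing]) done[[length(done) + 1L]] <- finalize(ev)
      open <- open[!closing]
    }

    # unmatched detections start new events
    for (k in which(det_ev == 0L)) {
      pix <- comps[[k]]
      ev <- list(id = next_id, onset_i = t, last_i = t,
                 pixels = pix, base = R[(t - 2L) * hw + pix],
                 union = pix, det_prev = pix, det_gap = 0L,
                 elev_now = integer(0), area_max = length(pix),
                 peak_delta = max(R[off3 + pix] - R[(t - 2L) * hw + pix]),
                 peak_foot = pix, gap = 0L)
      next_id <- next_id + 1L
      open[[length(open) + 1L]] <- ev
    }
  }
  for (ev in open) done[[length(done) + 1L]] <- finalize(ev)

  if (length(done) == 0) {
    return(empty_event_table(ratios$dt_s, h, w, ratios$t0_s, tt))
  }
  tab <- tibble(
    id = map_int(done, "id"),
    onset_frame = map_int(done, "onset_frame"),
    offset_frame = map_int(done, "offset_frame"),
    duration_s = map_dbl(done, "duration_s"),
    centroid_row = map_dbl(done, "centroid_row"),
    centroid_col = map_dbl(done, "centroid_col"),
    area_px = map_int(done, "area_px"),
    peak_delta_ratio = map_dbl(done, "peak_delta_ratio"),
    label = classify_duration(map_dbl(done, "duration_s"), params$d_max_s),
    footprint = map(done, "footprint")
  )
  if (is.finite(params$max_area_px)) {
    tab <- tab[tab$area_px <= params$max_area_px, , drop = FALSE]
  }
  tab <- arrange(tab, .data$onset_frame, .data$id)
  tab$id <- seq_len(nrow(tab))
  new_event_table(tab, dt_s = ratios$dt_s, height = h, width = w,
                  t0_s = ratios$t0_s, n_frames = tt)
}
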