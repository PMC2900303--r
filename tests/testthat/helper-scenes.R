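# Builders for noise-free piecewise-constant ratio stacks and the
# independent brute-force oracle used to validate the subtractive detector.

# events: list of list(pixels = linear indices, onset, offset (1-based,
# internal), amp); contributions add on a constant baseline.
make_block_scene <- function(h, w, tt, events, baseline = 1, dt_s = 15) {
  r <- array(baseline, c(h, w, tt))
  hw <- h * w
  for (ev in events) {
    for (t in ev$onset:ev$offset) {
      idx <- ev$pixels + (t - 1L) * hw
      r[idx] <- r[idx] + ev$amp
    }
  }
  ratio_stack(r, array(TRUE, c(h, w, tt)), dt_s = dt_s)
}

rect_pixels <- function(h, r0, r1, c0, c1) {
  as.vector(outer(r0:r1, ((c0:c1) - 1L) * h, `+`))
}

disc_pixels <- function(h, w, cr, cc, radius) {
  dr <- rep(-radius:radius, times = 2 * radius + 1)
  dc <- rep(-radius:radius, each = 2 * radius + 1)
  keep <- dr^2 + dc^2 <= radius^2
  rr <- cr + dr[keep]; ccol <- cc + dc[keep]
  ok <- rr >= 1 & rr <= h & ccol >= 1 & ccol <= w
  as.integer((ccol[ok] - 1L) * h + rr[ok])
}

# 8-neighborhood dilation of a linear-index pixel set
dilate_pixels <- function(px, h, w) {
  r <- ((px - 1L) %% h) + 1L
  c <- (px - 1L) %/% h + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    out <- c(out, (cc[ok] - 1L) * h + rr[ok])
  }
  unique(out)
}

# Random piecewise-constant scene: events are rectangles or discs with
# constant footprints; any two events are either spatially separated
# (dilated footprints disjoint) or separated in time by >= 2 baseline
# frames, so that per-frame linking and 3D labeling agree by construction.
random_block_scene <- function(h = 16, w = 16, tt = 20, max_events = 4,
                               dt_s = 15) {
  n_target <- sample(0:max_events, 1)
  events <- list()
  tries <- 0
  while (length(events) < n_target && tries < 50) {
    tries <- tries + 1
    if (runif(1) < 0.5) {
      r0 <- sample(1:(h - 3), 1); c0 <- sample(1:(w - 3), 1)
      px <- rect_pixels(h, r0, r0 + sample(1:3, 1), c0, c0 + sample(1:3, 1))
    } else {
      radius <- sample(2:3, 1)
      px <- disc_pixels(h, w, sample((radius + 1):(h - radius), 1),
                        sample((radius + 1):(w - radius), 1), radius)
    }
    onset <- sample(2:(tt - 1), 1)
    offset <- min(tt, onset + sample(0:4, 1))
    cand <- list(pixels = sort(px), onset = onset, offset = offset,
                 amp = runif(1, 0.3, 1))
    ok <- TRUE
    for (ev in events) {
      spatial_sep <- length(intersect(dilate_pixels(cand$pixels, h, w),
                                      ev$pixels)) == 0
      time_sep <- cand$onset > ev$offset + 2 || ev$onset > cand$offset + 2
      if (!spatial_sep && !time_sep) { ok <- FALSE; break }
    }
    if (ok) events[[length(events) + 1L]] <- cand
  }
  list(stack = make_block_scene(h, w, tt, events, dt_s = dt_s),
       events = events)
}

# Brute-force oracle: per-pixel thresholding against the frame-1 baseline
# and 3D connected-component labeling (26-connectivity) of the elevated
# voxels. Independent of the detector's incremental linking machinery.
oracle_detect <- function(ratios, d_max_s = 30, min_area_px = 1) {
  r <- ratios$ratio
  d <- dim(r); h <- d[1]; w <- d[2]; tt <- d[3]; hw <- h * w
  base <- as.vector(r[, , 1])
  elev <- array(FALSE, d)
  for (t in 2:tt) elev[, , t] <- r[, , t] > base
  idx_all <- which(elev)
  labels <- integer(length(idx_all))
  names(labels) <- as.character(idx_all)
  elev_set <- elev
  comp_id <- 0L
  comps <- list()
  visited <- array(FALSE, d)
  for (start in idx_all) {
    if (visited[start]) next
    comp_id <- comp_id + 1L
    queue <- start; visited[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      v0 <- v - 1L
      t <- v0 %/% hw + 1L
      rest <- v0 %% hw
      c <- rest %/% h + 1L
      rr <- rest %% h + 1L
      for (dt in -1:1) for (dc in -1:1) for (dr in -1:1) {
        if (dt == 0 && dc == 0 && dr == 0) next
        t2 <- t + dt; c2 <- c + dc; r2 <- rr + dr
        if (t2 < 1 || t2 > tt || c2 < 1 || c2 > w || r2 < 1 || r2 > h) next
        u <- (t2 - 1L) * hw + (c2 - 1L) * h + r2
        if (elev_set[u] && !visited[u]) {
          visited[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    comps[[comp_id]] <- members
  }
  rows <- lapply(comps, function(members) {
    v0 <- members - 1L
    t <- v0 %/% hw + 1L
    px <- v0 %% hw + 1L
    areas <- table(t)
    foot <- sort(unique(px))
    data.frame(onset_frame = min(t) - 1L, offset_frame = max(t) - 1L,
               duration_s = (max(t) - min(t) + 1L) * ratios$dt_s,
               area_px = max(areas),
               footprint = I(list(foot)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(onset_frame = integer(), offset_frame = integer(),
                      duration_s = double(), area_px = integer(),
                      footprint = I(list()))
  }
  out <- out[out$area_px >= min_area_px, , drop = FALSE]
  out$label <- c("sustained", "transient")[1L + (out$duration_s <= d_max_s)]
  out[order(out$onset_frame, vapply(out$footprint, min, numeric(1))), ,
      drop = FALSE]
}

# Canonical comparable form of an event table (detector or oracle).
event_signature <- function(tab) {
  ord <- order(tab$onset_frame, vapply(tab$footprint, min, numeric(1)))
  lapply(ord, function(i) list(
    onset = tab$onset_frame[i], offset = tab$offset_frame[i],
    footprint = sort(tab$footprint[[i]])
  ))
}

# Independent Fisher oracle: point probabilities from binomial-coefficient
# arithmetic (lchoose), summing the small-probability tables.
fisher_oracle <- function(x, tie_tol = 1e-7) {
  r1 <- sum(x[1, ]); c1 <- sum(x[, 1]); n <- sum(x)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  pk <- exp(logp)
  p_obs <- pk[match(x[1, 1], support)]
  min(1, sum(pk[pk <= p_obs * (1 + tie_tol)]))
}

# Small noisy synthetic session used by several unit tests (fast: ~64x64).
small_session <- function(seed, rate = 12, frames = 160, ...) {
  scene_params(frames = frames, height = 64, width = 64,
               sustained_domains = list(),
               transient_rate_per_hour = rate, seed = seed, ...)
}
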