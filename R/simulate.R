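#' Optical parameters of the two-state indicator forward model
#'
#' The indicator is modeled as a linear mixture of its Ca2+-free and
#' Ca2+-bound forms. At 340-nm excitation the bound form is brighter
#' (`g340_bound > g340_free`); at 380 nm the free form is brighter
#' (`g380_bound < g380_free`), so the 340/380 ratio increases strictly
#' with the normalized Ca2+ level. Gains are in expected camera counts at
#' full occupancy; `offset` is the camera baseline added after the shot
#' noise.
#'
#' @param g340_free,g340_bound Gains at 340 nm for free/bound indicator.
#' @param g380_free,g380_bound Gains at 380 nm for free/bound indicator.
#' @param offset Camera baseline counts (>= 0).
#' @return An `optics_params` list.
#' @export
optics_params <- function(g340_free = 400, g340_bound = 2000,
                          g380_free = 2000, g380_bound = 400, offset = 10) {
  p <- list(g340_free = g340_free, g340_bound = g340_bound,
            g380_free = g380_free, g380_bound = g380_bound, offset = offset)
  if (any(!vapply(p, is.numeric, logical(1))) || any(unlist(p) < 0)) {
    stop_validation("optics parameters must be non-negative numbers")
  }
  if (!(g340_bound > g340_free)) stop_validation("need g340_bound > g340_free")
  if (!(g380_bound < g380_free)) stop_validation("need g380_bound < g380_free")
  structure(p, class = "optics_params")
}

#' Scene parameters for the synthetic dual-wavelength movie generator
#'
#' Describes a simulated embryo session: a spatially structured baseline
#' Ca2+ field over an elliptical embryo, sustained high-Ca2+ domains
#' (lateral presomitic stripes and sequentially appearing intersomitic
#' boundary bands), stochastic localized transients as a homogeneous
#' Poisson process with rectangular kinetics, photobleaching, and
#' per-channel shot noise. Defaults model a wild-type-like 2-hour somite
#' session at 15-s sampling.
#'
#' @param frames,height,width Stack dimensions. Default 480 frames of
#'   128 x 128 (2 h at 15 s).
#' @param dt_s Inter-frame interval in seconds. Default 15.
#' @param baseline_c Baseline normalized Ca2+ level in `[0, 1]`. Default
#'   0.15.
#' @param sustained_domains List of domains, each a list with `geometry`
#'   (`"stripe"` or `"disc"`), geometry parameters (`rows`/`cols` index
#'   ranges for stripes; `center`, `radius_px` for discs), `delta_c`
#'   elevation, and `on_frame`/`off_frame` (0-based, inclusive). Use
#'   [default_domains()] for the wild-type-like geometry; `list()` for
#'   none.
#' @param transient_rate_per_hour Poisson arrival rate of transients.
#' @param transient_duration_frames Integer support sampled uniformly for
#'   event durations. Default `c(1, 2)` (15-30 s at 15-s sampling).
#' @param transient_radius_px Integer support for footprint radii.
#' @param transient_amplitude_c Range `c(lo, hi)` of uniform transient
#'   amplitudes (normalized Ca2+).
#' @param morphant_mode Model the morphant phenotype of larger areas of
#'   increased release: radii are enlarged and amplitudes raised. Default
#'   `FALSE`.
#' @param roi_suppression Optional list `(center, radius_px,
#'   rate_multiplier)`: transients whose center falls inside the disc ROI
#'   are thinned to `rate_multiplier` of the ambient rate, and a 540-nm
#'   lineage-tracer reference image of the ROI is attached to the output.
#' @param optics An [optics_params()].
#' @param shot_scale Shot-noise scale: counts are drawn as
#'   `rpois(expected / s) * s`. 1 = pure Poisson counting noise; 0 disables
#'   noise.
#' @param tau_bleach_s Photobleaching time constant in seconds applied to
#'   both channels; `Inf` disables. Default 36000 (~18% signal loss over a
#'   2-h session, typical of gentle wide-field exposure at 15-s sampling).
#' @param seed Integer RNG seed; identical parameters give bit-identical
#'   output.
#' @return A validated `scene_params` list.
#' @export
scene_params <- function(frames = 480, height = 128, width = 128, dt_s = 15,
                         baseline_c = 0.15,
                         sustained_domains = default_domains(frames, height, width),
                         transient_rate_per_hour = 5.3,
                         transient_duration_frames = c(1, 2),
                         transient_radius_px = c(2, 3),
                         transient_amplitude_c = c(0.25, 0.4),
                         morphant_mode = FALSE,
                         roi_suppression = NULL,
                         optics = optics_params(),
                         shot_scale = 1, tau_bleach_s = 36000,
                         seed = 1) {
  p <- list(frames = as.integer(frames), height = as.integer(height),
            width = as.integer(width), dt_s = dt_s, baseline_c = baseline_c,
            sustained_domains = sustained_domains,
            transient_rate_per_hour = transient_rate_per_hour,
            transient_duration_frames = as.integer(transient_duration_frames),
            transient_radius_px = as.integer(transient_radius_px),
            transient_amplitude_c = transient_amplitude_c,
            morphant_mode = isTRUE(morphant_mode),
            roi_suppression = roi_suppression,
            optics = optics, shot_scale = shot_scale,
            tau_bleach_s = tau_bleach_s, seed = as.integer(seed))
  if (p$frames < 2 || p$height < 4 || p$width < 4) {
    stop_validation("scene needs >= 2 frames and >= 4 x 4 pixels")
  }
  if (p$dt_s <= 0) stop_validation("dt_s must be > 0")
  if (baseline_c < 0 || baseline_c > 1) stop_validation("baseline_c must be in [0, 1]")
  if (transient_rate_per_hour < 0) stop_validation("rate must be >= 0")
  if (any(p$transient_duration_frames < 1)) stop_validation("durations must be >= 1 frame")
  if (any(p$transient_radius_px < 1)) stop_validation("radii must be >= 1 px")
  if (length(transient_amplitude_c) != 2 || any(transient_amplitude_c <= 0) ||
      diff(transient_amplitude_c) < 0) {
    stop_validation("transient_amplitude_c must be c(lo, hi), positive")
  }
  if (p$shot_scale < 0) stop_validation("shot_scale must be >= 0")
  if (p$tau_bleach_s <= 0) stop_validation("tau_bleach_s must be > 0")
  max_domain <- if (length(sustained_domains)) {
    max(vapply(sustained_domains, function(d) d$delta_c, numeric(1)))
  } else 0
  amp_hi <- transient_amplitude_c[2] * if (p$morphant_mode) 1.5 else 1
  if (baseline_c + max_domain + amp_hi > 1 + 1e-9) {
    stop_validation("baseline_c plus maximum elevations must not exceed 1")
  }
  if (!is.null(roi_suppression)) {
    rs <- roi_suppression
    if (!is.list(rs) || is.null(rs$center) || is.null(rs$radius_px) ||
        is.null(rs$rate_multiplier) || rs$rate_multiplier < 0 ||
        rs$rate_multiplier > 1) {
      stop_validation("roi_suppression needs center, radius_px, rate_multiplier in [0, 1]")
    }
  }
  structure(p, class = "scene_params")
}

#' Wild-type-like sustained-domain geometry
#'
#' Two lateral presomitic stripes flanking the midline, on for the whole
#' session, plus four intersomitic boundary bands that appear sequentially
#' as somitogenesis proceeds and persist once formed.
#'
#' @param frames,height,width Scene dimensions.
#' @param delta_c Elevation of the domains. Default 0.15.
#' @return A list of domain specifications for [scene_params()].
#' @export
default_domains <- function(frames, height, width, delta_c = 0.15) {
  stripe_w <- max(2L, round(0.06 * width))
  lat1 <- round(0.22 * width); lat2 <- round(0.78 * width)
  doms <- list(
    list(geometry = "stripe", cols = seq(lat1 - stripe_w %/% 2, length.out = stripe_w),
         delta_c = delta_c, on_frame = 0L, off_frame = frames - 1L),
    list(geometry = "stripe", cols = seq(lat2 - stripe_w %/% 2, length.out = stripe_w),
         delta_c = delta_c, on_frame = 0L, off_frame = frames - 1L)
  )
  band_rows <- round(seq(0.25, 0.7, length.out = 4) * height)
  band_h <- max(1L, round(0.02 * height))
  on_at <- round(seq(0.15, 0.75, length.out = 4) * (frames - 1))
  for (k in seq_along(band_rows)) {
    doms[[length(doms) + 1L]] <- list(
      geometry = "stripe", rows = seq(band_rows[k], length.out = band_h),
      cols = seq(round(0.3 * width), round(0.7 * width)),
      delta_c = delta_c, on_frame = as.integer(on_at[k]),
      off_frame = frames - 1L)
  }
  doms
}

#' Named scene presets
#'
#' Four presets spanning the study conditions: `"wildtype"` (5.3
#' transients/h, 2-h somite session with sustained domains),
#' `"rgs3_morphant"` (21.7/h, morphant mode: larger, stronger transients),
#' `"wnt5b_morphant"` (1.3/h), and `"roi_suppression"` (blastula-like
#' 1-h session, no sustained domains, ambient 20/h thinned to 10% inside a
#' tracer-marked ROI, with the 540-nm reference attached).
#'
#' @param name Preset name.
#' @param seed RNG seed.
#' @param ... Overrides passed to [scene_params()].
#' @return A `scene_params` list.
#' @export
scene_preset <- function(name = c("wildtype", "rgs3_morphant", "wnt5b_morphant",
                                  "roi_suppression"), seed = 1, ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    wildtype = list(transient_rate_per_hour = 5.3),
    rgs3_morphant = list(transient_rate_per_hour = 21.7, morphant_mode = TRUE),
    wnt5b_morphant = list(transient_rate_per_hour = 1.3),
    roi_suppression = list(
      frames = 240, height = 96, width = 96,
      sustained_domains = list(),
      transient_rate_per_hour = 20,
      roi_suppression = list(center = c(48, 48), radius_px = 20,
                             rate_multiplier = 0.1))
  )
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  if (!"sustained_domains" %in% names(args)) {
    dims <- list(frames = 480, height = 128, width = 128)
    dims <- utils::modifyList(dims, args[names(args) %in% names(dims)])
    args$sustained_domains <- default_domains(dims$frames, dims$height, dims$width)
  }
  do.call(scene_params, args)
}

# Elliptical embryo footprint covering most of the field of view.
embryo_ellipse <- function(height, width, fill = 0.45) {
  r <- (seq_len(height) - (height + 1) / 2) / (fill * height)
  c <- (seq_len(width) - (width + 1) / 2) / (fill * width)
  outer(r^2, c^2, `+`) <= 1
}

#' Forward model: normalized Ca2+ field to expected channel intensities
#'
#' Linear two-state mixing: `F = g_free * (1 - c) + g_bound * c` per
#' channel, plus the camera offset. The resulting noise-free ratio is
#' strictly increasing in `c`.
#'
#' @param c_frame Matrix (or array) of normalized Ca2+ in `[0, 1]`.
#' @param optics An [optics_params()].
#' @return List with `f340` and `f380` expected intensities.
#' @export
fura2_forward <- function(c_frame, optics = optics_params()) {
  if (anyNA(c_frame) || min(c_frame) < 0 || max(c_frame) > 1) {
    stop_validation("c must lie in [0, 1]")
  }
  list(
    f340 = optics$g340_free * (1 - c_frame) + optics$g340_bound * c_frame + optics$offset,
    f380 = optics$g380_free * (1 - c_frame) + optics$g380_bound * c_frame + optics$offset
  )
}

disc_offsets <- function(radius, height) {
  dr <- rep(-radius:radius, times = 2 * radius + 1)
  dc <- rep(-radius:radius, each = 2 * radius + 1)
  keep <- dr^2 + dc^2 <= radius^2
  list(dr = dr[keep], dc = dc[keep])
}

#' Simulate a dual-wavelength embryo movie with ground truth
#'
#' Builds the normalized Ca2+ field (baseline over an elliptical embryo,
#' sustained domains, Poisson-arriving rectangular transients with
#' uniform marks; overlapping contributions add and clamp at 1), passes it
#' through the two-state indicator forward model with exponential
#' photobleaching, applies per-channel shot noise, and returns the image
#' pair stack together with the exact log of sampled transients.
#'
#' @param params A [scene_params()].
#' @return List with `stack` (an [image_pair_stack()]), `truth` (tibble:
#'   `onset_frame` 0-based, `duration_frames`, `center_row`, `center_col`
#'   0-based, `radius_px`, `amplitude_c`), `roi` (logical mask or NULL)
#'   and `params`.
#' @export
simulate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$height; w <- params$width; tt <- params$frames; hw <- h * w
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(params$seed)

  emb <- embryo_ellipse(h, w)
  cc <- array(0, dim = c(h, w, tt))
  base_frame <- ifelse(emb, params$baseline_c, 0)
  for (t in seq_len(tt)) cc[, , t] <- base_frame

  for (d in params$sustained_domains) {
    px <- domain_pixels(d, h, w)
    frames_on <- (d$on_frame:d$off_frame) + 1L
    frames_on <- frames_on[frames_on >= 1 & frames_on <= tt]
    idx <- rep(px, times = length(frames_on)) +
      rep((frames_on - 1L) * hw, each = length(px))
    cc[idx] <- cc[idx] + d$delta_c
  }

  # Poisson arrivals with i.i.d. marks; morphant mode enlarges and
  # strengthens events ("larger areas of increased Ca2+ release").
  hours <- tt * params$dt_s / 3600
  n_arrivals <- rpois(1, params$transient_rate_per_hour * hours)
  radius_support <- params$transient_radius_px
  amp_range <- params$transient_amplitude_c
  if (params$morphant_mode) {
    radius_support <- radius_support + 3L
    amp_range <- amp_range * 1.5
  }
  roi_mask <- NULL
  rs <- params$roi_suppression
  if (!is.null(rs)) {
    off <- disc_offsets(rs$radius_px, h)
    roi_mask <- matrix(FALSE, h, w)
    rr <- rs$center[1] + off$dr; ccol <- rs$center[2] + off$dc
    ok <- rr >= 1 & rr <= h & ccol >= 1 & ccol <= w
    roi_mask[cbind(rr[ok], ccol[ok])] <- TRUE
  }

  events <- list()
  if (n_arrivals > 0) {
    for (k in seq_len(n_arrivals)) {
      radius <- sample_one(radius_support)
      dur <- sample_one(params$transient_duration_frames)
      amp <- runif(1, amp_range[1], amp_range[2])
      center <- sample_center(emb, radius)
      onset <- sample_one(seq_len(tt - 1L))  # internal 2..tt -> 0-based >= 1
      if (!is.null(rs) && roi_mask[center[1], center[2]] &&
          runif(1) > rs$rate_multiplier) {
        next  # thinned inside the suppressed ROI
      }
      events[[length(events) + 1L]] <- list(
        onset = onset + 1L, dur = dur, center = center,
        radius = radius, amp = amp)
    }
  }
  for (ev in events) {
    off <- disc_offsets(ev$radius, h)
    rr <- ev$center[1] + off$dr; ccol <- ev$center[2] + off$dc
    ok <- rr >= 1 & rr <= h & ccol >= 1 & ccol <= w
    px <- (ccol[ok] - 1L) * h + rr[ok]
    frames_on <- ev$onset:min(tt, ev$onset + ev$dur - 1L)
    idx <- rep(px, times = length(frames_on)) +
      rep((frames_on - 1L) * hw, each = length(px))
    cc[idx] <- cc[idx] + ev$amp
  }
  cc[cc > 1] <- 1

  t_s <- (seq_len(tt) - 1L) * params$dt_s
  bleach <- if (is.finite(params$tau_bleach_s)) exp(-t_s / params$tau_bleach_s) else rep(1, tt)
  bleach_full <- rep(bleach, each = hw)
  emb_full <- rep(as.vector(emb), times = tt)
  op <- params$optics
  f340 <- (op$g340_free * (1 - cc) + op$g340_bound * cc) * bleach_full * emb_full
  f380 <- (op$g380_free * (1 - cc) + op$g380_bound * cc) * bleach_full * emb_full
  f340 <- apply_shot_noise(f340, params$shot_scale) + op$offset
  f380 <- apply_shot_noise(f380, params$shot_scale) + op$offset
  dim(f340) <- dim(f380) <- c(h, w, tt)

  ref <- NULL
  if (!is.null(roi_mask)) {
    ref <- matrix(0, h, w)
    ref[emb] <- 40
    ref[roi_mask & emb] <- 200
    ref <- apply_shot_noise(ref, params$shot_scale) + op$offset
    ref <- matrix(ref, h, w)
  }

  truth <- if (length(events)) {
    tibble(
      onset_frame = map_int(events, function(e) e$onset - 1L),
      duration_frames = map_int(events, function(e) as.integer(e$dur)),
      center_row = map_dbl(events, function(e) e$center[1] - 1),
      center_col = map_dbl(events, function(e) e$center[2] - 1),
      radius_px = map_int(events, function(e) as.integer(e$radius)),
      amplitude_c = map_dbl(events, function(e) e$amp)
    )
  } else {
    tibble(onset_frame = integer(), duration_frames = integer(),
           center_row = double(), center_col = double(),
           radius_px = integer(), amplitude_c = double())
  }
  truth <- arrange(truth, .data$onset_frame)

  stack <- image_pair_stack(
    f340, f380, dt_s = params$dt_s, reference_540 = ref,
    meta = list(generator = "caltrace-synthetic", seed = as.character(params$seed))
  )
  list(stack = stack, truth = truth,
       roi = if (is.null(roi_mask)) NULL else new_mask(roi_mask, "roi"),
       params = params)
}

domain_pixels <- function(d, h, w) {
  if (identical(d$geometry, "stripe")) {
    rows <- if (is.null(d$rows)) seq_len(h) else d$rows[d$rows >= 1 & d$rows <= h]
    cols <- if (is.null(d$cols)) seq_len(w) else d$cols[d$cols >= 1 & d$cols <= w]
    as.vector(outer(rows, (cols - 1L) * h, `+`))
  } else if (identical(d$geometry, "disc")) {
    off <- disc_offsets(d$radius_px, h)
    rr <- d$center[1] + off$dr; ccol <- d$center[2] + off$dc
    ok <- rr >= 1 & rr <= h & ccol >= 1 & ccol <= w
    (ccol[ok] - 1L) * h + rr[ok]
  } else {
    stop_validation(paste("unknown domain geometry:", d$geometry))
  }
}

sample_one <- function(support) {
  if (length(support) == 1) support else sample(support, 1)
}

# Uniform center inside the embryo, at least `radius + 1` px from the border.
sample_center <- function(emb, radius) {
  h <- nrow(emb); w <- ncol(emb)
  repeat {
    r <- sample.int(h - 2 * (radius + 1), 1) + radius + 1
    c <- sample.int(w - 2 * (radius + 1), 1) + radius + 1
    if (emb[r, c]) return(c(r, c))
  }
}

apply_shot_noise <- function(x, shot_scale) {
  if (shot_scale <= 0) return(as.vector(x))
  rpois(length(x), as.vector(x) / shot_scale) * shot_scale
}

#' Score detected events against simulation ground truth
#'
#' Greedy one-to-one matching: a detected event matches a truth event when
#' their onsets differ by at most `tol_frames` frames and the detected
#' centroid lies within `tol_px` pixels of the true center. Candidate
#' pairs are taken smallest onset difference first, ties broken by
#' smallest distance, then lowest truth index.
#'
#' @param detected An event table (transients and sustained alike are
#'   eligible; filter first if desired).
#' @param truth Ground-truth tibble from [simulate_scene()].
#' @param tol_frames Onset tolerance in frames. Default 1.
#' @param tol_px Centroid tolerance in pixels. Default 4.
#' @return One-row tibble: `precision`, `recall`, `f1`, `n_detected`,
#'   `n_truth`, `n_matched`. With no detections and non-empty truth,
#'   precision is reported as 0 with a warning.
#' @export
score_detection <- function(detected, truth, tol_frames = 1, tol_px = 4) {
  if (tol_frames < 0 || tol_px < 0) stop_validation("tolerances must be >= 0")
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 && nt > 0) {
    warn("no detections against non-empty truth; precision reported as 0")
    return(tibble(precision = 0, recall = 0, f1 = 0,
                  n_detected = 0L, n_truth = nt, n_matched = 0L))
  }
  if (nt == 0) {
    return(tibble(precision = if (nd == 0) 1 else 0,
                  recall = 1, f1 = if (nd == 0) 1 else 0,
                  n_detected = nd, n_truth = 0L, n_matched = 0L))
  }
  cand <- expand.grid(d = seq_len(nd), t = seq_len(nt))
  cand$donset <- abs(detected$onset_frame[cand$d] - truth$onset_frame[cand$t])
  cand$dist <- sqrt((detected$centroid_row[cand$d] - truth$center_row[cand$t])^2 +
                    (detected$centroid_col[cand$d] - truth$center_col[cand$t])^2)
  cand <- cand[cand$donset <= tol_frames & cand$dist <= tol_px, , drop = FALSE]
  cand <- cand[order(cand$donset, cand$dist, cand$t), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt); matched <- 0L
  for (i in seq_len(nrow(cand))) {
    d <- cand$d[i]; t <- cand$t[i]
    if (!used_d[d] && !used_t[t]) {
      used_d[d] <- TRUE; used_t[t] <- TRUE; matched <- matched + 1L
    }
  }
  precision <- matched / nd
  recall <- matched / nt
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(precision = precision, recall = recall, f1 = f1,
         n_detected = nd, n_truth = nt, n_matched = matched)
}

#' Write and read scene parameters as a human-editable YAML config
#'
#' @param params A [scene_params()].
#' @param path YAML file path.
#' @return `write_scene_config` returns `path` invisibly;
#'   `read_scene_config` returns a validated `scene_params`.
#' @export
write_scene_config <- function(params, path) {
  stopifnot(inherits(params, "scene_params"))
  x <- unclass(params)
  x$optics <- unclass(x$optics)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop_io(paste("file not found:", path))
  x <- yaml::read_yaml(path)
  x$optics <- do.call(optics_params, x$optics)
  x$tau_bleach_s <- x$tau_bleach_s %||% Inf
  if (is.character(x$tau_bleach_s)) x$tau_bleach_s <- as.numeric(x$tau_bleach_s)
  do.call(scene_params, x)
}
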