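#' Segment the embryo from the background
#'
#' The analysis is restricted to embryo tissue; background pixels carry no
#' indicator and would produce unstable ratios. A pixel belongs to the
#' embryo when its time-mean 380-nm intensity is positive and at least the
#' `quantile_q` quantile of the time-mean image; holes are then filled.
#'
#' @param stack An [image_pair_stack()].
#' @param quantile_q Quantile of the time-mean 380-nm image used as the
#'   threshold (0 < q < 1). Default 0.1.
#' @param min_fill Minimum fraction of the field of view the mask must
#'   cover; below this the input is considered degenerate (likely an empty
#'   field of view). Default 0.05.
#' @return A logical mask of kind `"embryo"`.
#' @export
compute_embryo_mask <- function(stack, quantile_q = 0.1, min_fill = 0.05) {
  stopifnot(inherits(stack, "image_pair_stack"))
  if (!is.numeric(quantile_q) || quantile_q <= 0 || quantile_q >= 1) {
    stop_validation("quantile_q must be in (0, 1)")
  }
  mean380 <- rowMeans(stack$f380, dims = 2)
  thr <- quantile(mean380, quantile_q, names = FALSE)
  mask <- mean380 >= thr & mean380 > 0
  if (any(mask)) {
    mask <- EBImage::fillHull(mask) > 0
  }
  if (mean(mask) < min_fill) {
    stop_degenerate(sprintf(
      "embryo mask covers %.1f%% of pixels (< %.1f%%): empty field of view?",
      100 * mean(mask), 100 * min_fill))
  }
  new_mask(mask, "embryo")
}

#' Compute the pixel-wise 340/380 ratio stack
#'
#' The ratio image is the quotient of the 340-nm image divided by the
#' 380-nm image pixel by pixel; it rises with intracellular free Ca2+.
#' A pixel/frame is valid when the mask includes the pixel and the 380-nm
#' denominator is at least `eps`; everywhere else the ratio is undefined
#' (stored as NA and flagged invalid).
#'
#' @param stack An [image_pair_stack()].
#' @param mask Optional logical embryo mask ([compute_embryo_mask()]); the
#'   default admits every pixel.
#' @param eps Denominator floor in intensity units (> 0). Default: 1% of the
#'   99th percentile of the 380-nm channel, a relative floor robust to bit
#'   depth.
#' @return A `ratio_stack` with elements `ratio`, `valid`, `dt_s`, `t0_s`.
#' @export
compute_ratio <- function(stack, mask = NULL, eps = NULL) {
  stopifnot(inherits(stack, "image_pair_stack"))
  hw <- frame_shape(stack)
  if (is.null(mask)) mask <- matrix(TRUE, hw[1], hw[2])
  if (!identical(dim(mask), hw)) stop_shape("mask does not match stack spatial dims")
  if (is.null(eps)) eps <- 0.01 * quantile(stack$f380, 0.99, names = FALSE)
  if (!is.numeric(eps) || length(eps) != 1 || is.na(eps) || eps <= 0) {
    stop_validation("eps must be a single positive intensity")
  }
  valid <- stack$f380 >= eps & rep(as.logical(mask), n_frames(stack))
  dim(valid) <- dim(stack$f380)
  ratio <- array(NA_real_, dim(stack$f340))
  ratio[valid] <- stack$f340[valid] / stack$f380[valid]
  new_ratio_stack(ratio, valid, dt_s = stack$dt_s, t0_s = stack$t0_s)
}

#' The blue-green-yellow-red pseudocolor lookup table
#'
#' A fixed 256-level lookup table (low ratio / low Ca2+ at the blue end,
#' high ratio / high Ca2+ at the yellow/red end), shipped as a CSV so
#' renders are bit-reproducible.
#'
#' @return A 256 x 3 integer matrix of RGB values 0-255.
#' @export
pseudocolor_lut <- function() {
  lut <- the$lut
  if (is.null(lut)) {
    path <- system.file("extdata", "pseudocolor_lut.csv", package = "caltrace",
                        mustWork = TRUE)
    lut <- as.matrix(read.csv(path))
    storage.mode(lut) <- "integer"
    stopifnot(identical(dim(lut), c(256L, 3L)))
    the$lut <- lut
  }
  lut
}

the <- new.env(parent = emptyenv())

#' Encode a ratio frame as an 8-bit pseudocolor image
#'
#' Ratios are linearly rescaled so `lo` maps to level 0 (blue end) and `hi`
#' to level 255 (red end): `s = clamp((r - lo)/(hi - lo), 0, 1)`, level
#' `floor(255 s)` with `s = 1` mapping to 255, then passed through the
#' fixed lookup table. Invalid pixels render black.
#'
#' @param frame Numeric matrix of ratios (one frame).
#' @param valid Logical matrix of the same shape; default all valid (NA
#'   ratios are treated as invalid regardless).
#' @param lo,hi Display range in ratio units, `lo < hi`. See
#'   [display_range()] for the session-percentile default used by the
#'   pipeline.
#' @return `height x width x 3` integer array of 8-bit RGB.
#' @export
encode_pseudocolor <- function(frame, lo, hi, valid = NULL) {
  frame <- as.matrix(frame)
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 || length(hi) != 1 ||
      !is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop_validation("display range requires lo < hi (finite)")
  }
  if (is.null(valid)) valid <- !is.na(frame) else valid <- valid & !is.na(frame)
  s <- (frame - lo) / (hi - lo)
  s[s < 0] <- 0; s[s > 1] <- 1
  level <- floor(255 * s)
  level[s >= 1] <- 255
  lut <- pseudocolor_lut()
  out <- array(0L, dim = c(dim(frame), 3L))
  lv <- level[valid] + 1L
  for (ch in 1:3) {
    plane <- matrix(0L, nrow(frame), ncol(frame))
    plane[valid] <- lut[lv, ch]
    out[, , ch] <- plane
  }
  out
}

#' Session display range for pseudocolor rendering
#'
#' @param ratios A `ratio_stack`.
#' @param probs Two percentiles of the valid ratios; default 1st and 99th.
#' @return Numeric `c(lo, hi)`.
#' @export
display_range <- function(ratios, probs = c(0.01, 0.99)) {
  stopifnot(inherits(ratios, "ratio_stack"))
  v <- ratios$ratio[ratios$valid]
  if (length(v) == 0) stop_degenerate("no valid ratio pixels")
  rng <- quantile(v, probs, names = FALSE)
  if (rng[1] >= rng[2]) rng[2] <- rng[1] + .Machine$double.eps * max(1, abs(rng[1]))
  rng
}

#' Derive the lineage-tracer region of interest from the reference channel
#'
#' Cells co-injected with the Texas Red tracer are located from the 540-nm
#' reference exposure: pixels at or above `frac_of_max` of the image
#' maximum, keeping only the largest 8-connected component.
#'
#' @param reference `height x width` reference image with a positive maximum.
#' @param frac_of_max Threshold as a fraction of the maximum (0 < f < 1).
#'   Default 0.5.
#' @return A logical mask of kind `"roi"`.
#' @export
roi_from_reference <- function(reference, frac_of_max = 0.5) {
  reference <- as.matrix(reference)
  if (!is.numeric(frac_of_max) || frac_of_max <= 0 || frac_of_max >= 1) {
    stop_validation("frac_of_max must be in (0, 1)")
  }
  mx <- max(reference)
  if (!is.finite(mx) || mx <= 0) {
    stop_degenerate("reference image has no positive signal")
  }
  new_mask(largest_component_8(reference >= frac_of_max * mx), "roi")
}
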