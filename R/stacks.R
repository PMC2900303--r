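#' Construct a dual-wavelength image pair stack
#'
#' Bundles the two aligned excitation channels of a ratiometric (Fura-2 style)
#' acquisition: the 340-nm channel, whose fluorescence rises with bound
#' indicator (high Ca2+), and the 380-nm channel, whose fluorescence falls.
#' Arrays are `height x width x frames`; both channels must match exactly.
#'
#' @param f340,f380 Numeric arrays, `height x width x frames`, non-negative
#'   finite intensities in arbitrary fluorescence units. At least 2 frames.
#' @param dt_s Inter-frame interval in seconds (> 0). The acquisitions this
#'   models used 15 s.
#' @param t0_s Acquisition start time in seconds (default 0). Frame `k`
#'   (0-based) is at time `t0_s + k * dt_s`.
#' @param reference_540 Optional single `height x width` image of the
#'   lineage-tracer (Texas Red, 540-nm excitation) reference channel.
#' @param meta Named list of free-form string metadata (stage annotations,
#'   embryo id, orientation).
#'
#' @return An object of class `image_pair_stack`.
#' @export
image_pair_stack <- function(f340, f380, dt_s, t0_s = 0, reference_540 = NULL,
                             meta = list()) {
  f340 <- as_stack_array(f340, "f340")
  f380 <- as_stack_array(f380, "f380")
  if (!identical(dim(f340), dim(f380))) {
    stop_shape(sprintf(
      "f340 and f380 must have identical dimensions; got %s vs %s",
      paste(dim(f340), collapse = "x"), paste(dim(f380), collapse = "x")
    ))
  }
  if (dim(f340)[3] < 2) stop_validation("an image pair stack needs >= 2 frames")
  if (!is.numeric(dt_s) || length(dt_s) != 1 || !is.finite(dt_s) || dt_s <= 0) {
    stop_validation("dt_s must be a single positive number of seconds")
  }
  if (!is.numeric(t0_s) || length(t0_s) != 1 || !is.finite(t0_s)) {
    stop_validation("t0_s must be a single finite number of seconds")
  }
  for (nm in c("f340", "f380")) {
    x <- get(nm)
    if (anyNA(x) || !all(is.finite(x))) stop_validation(paste(nm, "contains non-finite values"))
    if (min(x) < 0) stop_validation(paste(nm, "contains negative intensities"))
  }
  if (!is.null(reference_540)) {
    reference_540 <- as.matrix(reference_540)
    if (!identical(dim(reference_540), dim(f340)[1:2])) {
      stop_shape("reference_540 must match the spatial dimensions of the stacks")
    }
    if (anyNA(reference_540) || !all(is.finite(reference_540)) || min(reference_540) < 0) {
      stop_validation("reference_540 must be finite and non-negative")
    }
  }
  if (!is.list(meta)) stop_validation("meta must be a named list")
  structure(
    list(f340 = f340, f380 = f380, dt_s = dt_s, t0_s = t0_s,
         reference_540 = reference_540, meta = meta),
    class = "image_pair_stack"
  )
}

as_stack_array <- function(x, name) {
  if (is.list(x)) x <- simplify2array(x)
  if (!is.array(x) || length(dim(x)) != 3) {
    stop_shape(paste(name, "must be a height x width x frames array"))
  }
  storage.mode(x) <- if (is.integer(x)) "integer" else "double"
  x
}

#' @export
print.image_pair_stack <- function(x, ...) {
  d <- dim(x$f340)
  cat(sprintf(
    "<image_pair_stack> %d x %d px, %d frames, dt = %gs (%.1f min)%s\n",
    d[1], d[2], d[3], x$dt_s, d[3] * x$dt_s / 60,
    if (!is.null(x$reference_540)) ", with 540-nm reference" else ""
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.image_pair_stack <- function(x) dim(x$f340)

n_frames <- function(x) {
  if (inherits(x, "image_pair_stack")) dim(x$f340)[3]
  else if (inherits(x, "ratio_stack")) dim(x$ratio)[3]
  else stop_validation("not a stack")
}

frame_shape <- function(x) {
  if (inherits(x, "image_pair_stack")) dim(x$f340)[1:2]
  else if (inherits(x, "ratio_stack")) dim(x$ratio)[1:2]
  else stop_validation("not a stack")
}

#' Construct a ratio stack directly
#'
#' Usually produced by [compute_ratio()]; the constructor is exported for
#' building ratio stacks from other sources (or fixtures) directly.
#'
#' @param ratio Numeric `height x width x frames` array of 340/380 ratios.
#' @param valid Logical array of the same shape; where `FALSE`, the ratio
#'   is treated as undefined. Default: finite, positive entries of `ratio`.
#' @param dt_s Inter-frame interval in seconds (> 0).
#' @param t0_s Acquisition start time in seconds.
#' @return A `ratio_stack`.
#' @export
ratio_stack <- function(ratio, valid = NULL, dt_s, t0_s = 0) {
  if (!is.array(ratio) || length(dim(ratio)) != 3) {
    stop_shape("ratio must be a height x width x frames array")
  }
  if (is.null(valid)) valid <- is.finite(ratio) & ratio > 0
  storage.mode(valid) <- "logical"
  if (!identical(dim(ratio), dim(valid))) stop_shape("ratio/valid shape mismatch")
  if (!is.numeric(dt_s) || length(dt_s) != 1 || dt_s <= 0) {
    stop_validation("dt_s must be a single positive number of seconds")
  }
  if (any(!is.finite(ratio[valid]))) stop_validation("non-finite ratios marked valid")
  new_ratio_stack(ratio, valid, dt_s, t0_s)
}

new_ratio_stack <- function(ratio, valid, dt_s, t0_s = 0) {
  stopifnot(identical(dim(ratio), dim(valid)))
  structure(list(ratio = ratio, valid = valid, dt_s = dt_s, t0_s = t0_s),
            class = "ratio_stack")
}

#' @export
print.ratio_stack <- function(x, ...) {
  d <- dim(x$ratio)
  rng <- if (any(x$valid)) range(x$ratio[x$valid]) else c(NA, NA)
  cat(sprintf(
    "<ratio_stack> %d x %d px, %d frames, dt = %gs; valid %.1f%%; ratio range [%.3g, %.3g]\n",
    d[1], d[2], d[3], x$dt_s, 100 * mean(x$valid), rng[1], rng[2]
  ))
  invisible(x)
}

#' @export
dim.ratio_stack <- function(x) dim(x$ratio)

new_mask <- function(pixels, kind = c("embryo", "roi")) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "logical"
  structure(pixels, kind = kind, class = c("caltrace_mask", "matrix", "array"))
}

#' @export
print.caltrace_mask <- function(x, ...) {
  cat(sprintf("<mask kind=%s> %d x %d px, %d true (%.1f%%)\n",
              attr(x, "kind"), nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}
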