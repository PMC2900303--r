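#' Read a dual-wavelength acquisition from multi-page TIFF files
#'
#' Reads one multi-page grayscale TIFF per excitation channel into an
#' [image_pair_stack()]. Integer TIFFs (8/16-bit) are read bit-exactly.
#'
#' @param path_340,path_380 Paths to the 340-nm and 380-nm channel stacks.
#' @param dt_s Inter-frame interval in seconds (> 0).
#' @param reference_path Optional path to a single-page TIFF of the 540-nm
#'   lineage-tracer reference exposure.
#' @param t0_s Acquisition start time in seconds.
#' @param meta Named list of string metadata.
#'
#' @return An [image_pair_stack()].
#' @export
read_pair_stack <- function(path_340, path_380, dt_s, reference_path = NULL,
                            t0_s = 0, meta = list()) {
  f340 <- read_tiff_stack(path_340)
  f380 <- read_tiff_stack(path_380)
  if (!identical(dim(f340), dim(f380))) {
    stop_shape(sprintf(
      "channel stacks disagree: '%s' is %s but '%s' is %s",
      path_340, paste(dim(f340), collapse = "x"),
      path_380, paste(dim(f380), collapse = "x")
    ))
  }
  ref <- NULL
  if (!is.null(reference_path)) {
    ref <- read_tiff_stack(reference_path)
    if (dim(ref)[3] != 1) stop_format("reference image must be a single page")
    ref <- ref[, , 1]
  }
  image_pair_stack(f340, f380, dt_s = dt_s, t0_s = t0_s,
                   reference_540 = ref, meta = meta)
}

read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop_io(paste("file not found:", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop_format(
                      sprintf("cannot read '%s' as TIFF: %s", path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop_format(paste("empty TIFF:", path))
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1 || length(dims[[1]]) != 2) {
    stop_format(paste("pages of", path, "are not uniform grayscale images"))
  }
  arr <- array(0, dim = c(dims[[1]], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (all(arr == round(arr))) storage.mode(arr) <- "integer"
  arr
}

#' Write an image pair stack as TIFF channels plus a JSON sidecar
#'
#' Each channel is written as a 16-bit multi-page grayscale TIFF.
#' Integer-valued stacks within 0..65535 round-trip bit-exactly; other
#' values are quantized with a per-channel scale recorded in the sidecar, so
#' that `value = stored * scale` with absolute error at most `scale / 2`.
#' The sidecar (`stack.json`) records `dt_s`, `t0_s`, metadata, file names
#' and quantization scales; [read_pair_stack_dir()] reverses the operation.
#'
#' @param stack An [image_pair_stack()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of written file paths.
#' @export
write_pair_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "image_pair_stack"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(paste("cannot create directory:", dir))
  }
  if (file.access(dir, mode = 2) != 0) stop_io(paste("directory not writable:", dir))
  files <- list(f340 = file.path(dir, "f340.tif"),
                f380 = file.path(dir, "f380.tif"))
  scales <- list(
    f340 = write_tiff16(stack$f340, files$f340),
    f380 = write_tiff16(stack$f380, files$f380)
  )
  if (!is.null(stack$reference_540)) {
    files$reference_540 <- file.path(dir, "reference_540.tif")
    ref <- stack$reference_540
    dim(ref) <- c(dim(ref), 1L)
    scales$reference_540 <- write_tiff16(ref, files$reference_540)
  }
  sidecar <- list(
    format = "caltrace-pair-stack/1",
    dt_s = stack$dt_s, t0_s = stack$t0_s,
    files = lapply(files, basename),
    quantization_scale = scales,
    meta = stack$meta
  )
  sidecar_path <- file.path(dir, "stack.json")
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, list(sidecar = sidecar_path)))
}

# Writes height x width x frames as 16-bit TIFF; returns the quantization
# scale (1 means bit-exact integers).
write_tiff16 <- function(arr, path) {
  mx <- max(arr)
  integral <- all(arr == round(arr))
  scale <- if (integral && mx <= 65535) 1 else mx / 65535
  if (mx == 0) scale <- 1
  stored <- round(arr / scale)  # exact 16-bit levels; |x - stored*scale| <= scale/2
  pages <- lapply(seq_len(dim(arr)[3]), function(k) stored[, , k] / 65535)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16,
                                 compression = "none"),
                 error = function(e) stop_io(conditionMessage(e)))
  scale
}

#' Read back a stack written by [write_pair_stack()]
#'
#' @param dir Directory containing `stack.json` and the channel TIFFs.
#' @return An [image_pair_stack()].
#' @export
read_pair_stack_dir <- function(dir) {
  sidecar_path <- file.path(dir, "stack.json")
  if (!file.exists(sidecar_path)) stop_io(paste("no stack.json in", dir))
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  rescale <- function(name) {
    arr <- read_tiff_stack(file.path(dir, sc$files[[name]]))
    s <- sc$quantization_scale[[name]]
    if (!is.null(s) && s != 1) arr <- arr * s
    arr
  }
  f340 <- rescale("f340")
  f380 <- rescale("f380")
  ref <- NULL
  if (!is.null(sc$files$reference_540)) ref <- rescale("reference_540")[, , 1]
  meta <- as.list(sc$meta)
  image_pair_stack(f340, f380, dt_s = sc$dt_s, t0_s = sc$t0_s %||% 0,
                   reference_540 = ref, meta = meta)
}

# ---- Event tables -----------------------------------------------------------

event_table_columns <- c("id", "onset_frame", "offset_frame", "duration_s",
                         "centroid_row", "centroid_col", "area_px",
                         "peak_delta_ratio", "label")

new_event_table <- function(events, dt_s = NA_real_, height = NA_integer_,
                            width = NA_integer_, t0_s = 0,
                            n_frames = NA_integer_) {
  events <- as_tibble(events)
  stopifnot(all(event_table_columns %in% names(events)))
  events <- arrange(events, .data$onset_frame, .data$id)
  structure(events, dt_s = dt_s, height = height, width = width, t0_s = t0_s,
            n_frames = n_frames, class = c("event_table", class(tibble())))
}

empty_event_table <- function(dt_s = NA_real_, height = NA_integer_,
                              width = NA_integer_, t0_s = 0,
                              n_frames = NA_integer_) {
  new_event_table(
    tibble(id = integer(), onset_frame = integer(), offset_frame = integer(),
           duration_s = double(), centroid_row = double(),
           centroid_col = double(), area_px = integer(),
           peak_delta_ratio = double(), label = character(),
           footprint = list()),
    dt_s = dt_s, height = height, width = width, t0_s = t0_s,
    n_frames = n_frames
  )
}

#' Write an event table to CSV
#'
#' One row per event, fixed column order
#' `id, onset_frame, offset_frame, duration_s, centroid_row, centroid_col,
#' area_px, peak_delta_ratio, label`, header always present. Frame indices
#' are 0-based; centroids are 0-based pixel (row, col); float fields are
#' serialized with 6 significant digits. The in-memory footprint list-column
#' (pixel indices) is not serialized.
#'
#' @param table An event table as returned by [detect_events()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_event_table <- function(table, path) {
  stopifnot(inherits(table, "event_table") || is.data.frame(table))
  df <- as.data.frame(table)[, event_table_columns, drop = FALSE]
  for (col in c("duration_s", "centroid_row", "centroid_col", "peak_delta_ratio")) {
    df[[col]] <- signif(df[[col]], 6)
  }
  ok <- tryCatch(write.csv(df, path, row.names = FALSE, quote = FALSE),
                 error = function(e) stop_io(conditionMessage(e)))
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#'
#' @param path CSV path.
#' @param dt_s,height,width,t0_s Optional session metadata to attach.
#' @return An event table tibble (without footprints).
#' @export
read_event_table <- function(path, dt_s = NA_real_, height = NA_integer_,
                             width = NA_integer_, t0_s = 0) {
  if (!file.exists(path)) stop_io(paste("file not found:", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format(conditionMessage(e)))
  if (!identical(names(df), event_table_columns)) {
    stop_format("CSV does not have the expected event-table columns")
  }
  df$id <- as.integer(df$id)
  df$onset_frame <- as.integer(df$onset_frame)
  df$offset_frame <- as.integer(df$offset_frame)
  df$area_px <- as.integer(df$area_px)
  df$label <- as.character(df$label)
  df$footprint <- rep(list(NULL), nrow(df))
  new_event_table(df, dt_s = dt_s, height = height, width = width, t0_s = t0_s)
}

#' Write an 8-bit RGB frame as a lossless PNG
#'
#' @param rgb_frame `height x width x 3` array of integers 0-255 (as produced
#'   by [encode_pseudocolor()]).
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
render_frame_png <- function(rgb_frame, path) {
  if (!is.array(rgb_frame) || length(dim(rgb_frame)) != 3 || dim(rgb_frame)[3] != 3) {
    stop_validation("rgb_frame must be a height x width x 3 array")
  }
  if (anyNA(rgb_frame) || min(rgb_frame) < 0 || max(rgb_frame) > 255 ||
      !all(rgb_frame == round(rgb_frame))) {
    stop_validation("rgb_frame values must be integers in 0..255")
  }
  ok <- tryCatch(png::writePNG(rgb_frame / 255, path),
                 error = function(e) stop_io(conditionMessage(e)))
  invisible(path)
}

#' Read an 8-bit RGB PNG back as a 0-255 integer array
#' @param path PNG path.
#' @return `height x width x 3` integer array.
#' @export
read_frame_png <- function(path) {
  if (!file.exists(path)) stop_io(paste("file not found:", path))
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  arr <- arr[, , 1:3, drop = FALSE] * 255
  storage.mode(arr) <- "integer"
  arr
}
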