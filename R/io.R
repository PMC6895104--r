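#' Time-lapse image stack
#'
#' Container for an ordered grayscale frame sequence with acquisition
#' metadata. Frames are stored as a 3-D array `[row, col, frame]` of floats
#' in `[0, 1]`. Coordinates throughout the package are 1-based with origin
#' at the top-left pixel: `x` is the column index (increasing rightward),
#' `y` the row index (increasing downward); `u`/`v` are displacements along
#' `x`/`y` in px, and multiplying by `pixel_size_um` converts px to microns.
#'
#' @param frames numeric array `[rows, cols, n_frames]` (or a list of
#'   matrices of equal dimension).
#' @param fps frames per second (> 0).
#' @param pixel_size_um microns per pixel (> 0).
#' @param source_path optional provenance string.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(frames, fps, pixel_size_um, source_path = NA_character_) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) != 3L) stop_arg("'frames' must be [rows, cols, n_frames]")
  if (!is.finite(fps) || fps <= 0) stop_arg("'fps' must be > 0")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop_arg("'pixel_size_um' must be > 0")
  structure(list(frames = frames, fps = fps, pixel_size_um = pixel_size_um,
                 source_path = source_path),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px, %g FPS, %g um/px\n",
              d[3], d[1], d[2], x$fps, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]
get_frame <- function(stack, t) stack$frames[, , t]

#' Read a time-lapse stack from disk
#'
#' Reads a multi-page TIFF into an [image_stack()]. RGB pages are converted
#' to grayscale by Rec. 709 luminance. `fps` and `pixel_size_um` must come
#' from the arguments (typically a config file) when the file carries no
#' usable metadata -- there is no silent default. Video containers (AVI/MP4)
#' are not read directly; convert them to a multi-page TIFF first (e.g. with
#' ffmpeg or ImageJ).
#'
#' @param path path to a multi-page TIFF with at least 2 pages.
#' @param fps,pixel_size_um acquisition metadata overrides; required when the
#'   file does not provide them (TIFF rarely does).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, fps = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop_arg("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("avi", "mp4", "mov", "mkv"))
    stop_arg("video containers are not read directly; convert '", path,
             "' to a multi-page TIFF (e.g. ffmpeg -i in.avi out.tif, or ImageJ)")
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop_arg("need a time series: '", path, "' has ",
                                   length(pages), " frame(s)")
  to_gray <- function(p) {
    if (length(dim(p)) == 3L) {
      # luminance; alpha (if any) ignored
      0.2126 * p[, , 1] + 0.7152 * p[, , 2] + 0.0722 * p[, , 3]
    } else p
  }
  frames <- simplify2array(lapply(pages, to_gray))
  if (is.null(fps)) stop_arg("fps not present in file metadata and not supplied; ",
                             "pass fps explicitly (no silent default)")
  if (is.null(pixel_size_um))
    stop_arg("pixel_size_um not present in file metadata and not supplied; ",
             "pass pixel_size_um explicitly (no silent default)")
  frames <- pmin(pmax(frames, 0), 1)
  image_stack(frames, fps = fps, pixel_size_um = pixel_size_um,
              source_path = normalizePath(path))
}

#' Write a stack as multi-page TIFF
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(n_frames(stack)), function(t) get_frame(stack, t))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# Fixed column order and float format shared by all field writers so output
# is byte-stable across runs.
field_columns <- c("frame", "reference", "grid_x", "grid_y",
                   "u_px", "v_px", "quality", "valid")

field_to_rows <- function(f) {
  nx <- length(f$grid_x); ny <- length(f$grid_y)
  data.frame(frame = f$frame_index, reference = f$reference_index,
             grid_x = rep(f$grid_x, each = ny),
             grid_y = rep(f$grid_y, times = nx),
             u_px = as.vector(f$u), v_px = as.vector(f$v),
             quality = as.vector(f$quality), valid = as.vector(f$valid))
}

#' Write displacement fields to CSV
#'
#' One row per vector with columns `frame, reference, grid_x, grid_y, u_px,
#' v_px, quality, valid`. Floats are written with `%.6g` so the round trip
#' through [read_fields()] is exact to about 1e-6 relative; the writer is
#' byte-stable for identical input.
#'
#' @param fields a single displacement field or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fields <- function(fields, path) {
  if (inherits(fields, "displacement_field")) fields <- list(fields)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(field_columns, collapse = ","), con)
  for (f in fields) {
    rows <- field_to_rows(f)
    lines <- sprintf("%d,%d,%.6g,%.6g,%.6g,%.6g,%.6g,%d",
                     rows$frame, rows$reference, rows$grid_x, rows$grid_y,
                     rows$u_px, rows$v_px, rows$quality, as.integer(rows$valid))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read displacement fields from CSV
#'
#' Inverse of [write_fields()]. Rows with non-finite `u_px`/`v_px` are kept
#' but flagged invalid (never silently zeroed).
#'
#' @param path CSV path written by [write_fields()].
#' @param pixel_size_um metadata to re-attach (px values are stored).
#' @return A list of `displacement_field` objects, one per frame.
#' @export
read_fields <- function(path, pixel_size_um = NA_real_) {
  df <- utils::read.csv(path)
  if (!all(field_columns %in% names(df)))
    stop_arg("'", path, "' is not a displacement-field CSV")
  if (nrow(df) == 0) return(list())
  bad <- !is.finite(df$u_px) | !is.finite(df$v_px)
  df$valid <- df$valid == 1 & !bad
  df$u_px[bad] <- 0; df$v_px[bad] <- 0
  lapply(split(df, df$frame), function(d) {
    gx <- sort(unique(d$grid_x)); gy <- sort(unique(d$grid_y))
    ny <- length(gy); nx <- length(gx)
    ord <- order(match(d$grid_x, gx), match(d$grid_y, gy))
    d <- d[ord, ]
    new_displacement_field(
      grid_x = gx, grid_y = gy,
      u = matrix(d$u_px, ny, nx), v = matrix(d$v_px, ny, nx),
      quality = matrix(d$quality, ny, nx),
      valid = matrix(d$valid, ny, nx),
      frame_index = d$frame[1], reference_index = d$reference[1],
      spacing_px = if (nx > 1) gx[2] - gx[1] else NA_real_,
      pixel_size_um = pixel_size_um)
  })
}
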