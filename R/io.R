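#' Rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the region covers pixel rows
#' `[top, bottom)` and columns `[left, right)`. This convention is used by
#' every function in the package that takes or returns a region.
#'
#' @param top,left First row / column inside the region (0-based).
#' @param bottom,right First row / column past the region.
#' @return A list of class `"roi"` with fields `top`, `left`, `bottom`,
#'   `right`.
#' @examples
#' roi(0, 0, 4, 4)  # the top-left 4 x 4 block
#' @export
roi <- function(top, left, bottom, right) {
  vals <- c(top = top, left = left, bottom = bottom, right = right)
  if (any(vals != floor(vals))) stop_egsvm("ROI coordinates must be integers")
  if (top < 0 || left < 0) stop_egsvm("ROI coordinates must be non-negative")
  if (bottom <= top) stop_egsvm("ROI requires top < bottom")
  if (right <= left) stop_egsvm("ROI requires left < right")
  structure(list(top = as.integer(top), left = as.integer(left),
                 bottom = as.integer(bottom), right = as.integer(right)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows [%d, %d), cols [%d, %d)\n",
              x$top, x$bottom, x$left, x$right))
  invisible(x)
}

as_roi <- function(w) {
  if (inherits(w, "roi")) return(w)
  if (is.data.frame(w)) {
    if (nrow(w) != 1) stop_egsvm("expected a single-row window")
    return(roi(w$top, w$left, w$bottom, w$right))
  }
  if (is.numeric(w) && length(w) == 4) return(roi(w[1], w[2], w[3], w[4]))
  stop_egsvm("cannot interpret object as a region of interest")
}

validate_gray_image <- function(img, what = "gray image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_egsvm(what, " must be a numeric matrix")
  if (nrow(img) < 2 || ncol(img) < 2)
    stop_egsvm(what, " must be at least 2 x 2")
  if (anyNA(img) || any(!is.finite(img)))
    stop_egsvm(what, " contains non-finite values")
  if (any(img < 0 | img > 255) || any(img != floor(img)))
    stop_egsvm(what, " values must be integers in [0, 255]")
  invisible(img)
}

validate_temperature_map <- function(tmap, physiologic = TRUE) {
  if (!is.matrix(tmap) || !is.numeric(tmap))
    stop_egsvm("temperature map must be a numeric matrix")
  if (nrow(tmap) < 2 || ncol(tmap) < 2)
    stop_egsvm("temperature map must be at least 2 x 2")
  bad <- which(!is.finite(tmap), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_egsvm(sprintf("non-finite temperature at row %d, column %d",
                       bad[1, 1], bad[1, 2]))
  if (physiologic) {
    bad <- which(tmap < 15 | tmap > 45, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop_egsvm(sprintf(
        "temperature %.2f degC at row %d, column %d outside physiologic band [15, 45]",
        tmap[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
  }
  invisible(tmap)
}

#' Read a thermogram or temperature matrix from disk
#'
#' Reads either an 8-bit single-channel raster (PNG or TIFF), returning a
#' gray-level matrix with integer values 0-255, or a plain-text matrix of
#' surface temperatures in degrees Celsius (`temp_csv`: comma- or
#' tab-separated floats, one row of the image per line, optionally preceded
#' by a single `#`-prefixed header line). Multi-channel (pseudo-color)
#' rasters are rejected rather than decoded: inputs must be single-channel.
#'
#' @param path Path to the file.
#' @param format One of `"png8"`, `"tiff8"`, `"temp_csv"`; inferred from the
#'   file extension when `NULL`.
#' @return An integer gray-level matrix for rasters, or a numeric temperature
#'   matrix (degrees Celsius) for `temp_csv`.
#' @seealso [temperature_to_gray()], [write_gray_png()]
#' @export
load_gray_image <- function(path, format = NULL) {
  if (!file.exists(path)) stop_egsvm("cannot read file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      png = "png8", tif = "tiff8", tiff = "tiff8",
      csv = "temp_csv", tsv = "temp_csv",
      stop_egsvm("cannot infer format from extension: ", path))
  }
  format <- match.arg(format, c("png8", "tiff8", "temp_csv"))
  switch(format,
    png8 = read_raster_8bit(png::readPNG(path), path),
    tiff8 = read_raster_8bit(tiff::readTIFF(path), path),
    temp_csv = read_temperature_text(path))
}

read_raster_8bit <- function(arr, path) {
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] != 1)
      stop_egsvm("multi-channel raster rejected (single-channel input required): ",
                 path)
    arr <- arr[, , 1]
  }
  img <- round(arr * 255)
  storage.mode(img) <- "integer"
  validate_gray_image(img)
  img
}

read_temperature_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop_egsvm("empty temperature file: ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1)
    stop_egsvm("ragged rows in temperature file: ", path)
  tmap <- do.call(rbind, lapply(rows, function(r) {
    suppressWarnings(as.numeric(trimws(r)))
  }))
  bad <- which(!is.finite(tmap), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_egsvm(sprintf("invalid temperature value at row %d, column %d in %s",
                       bad[1, 1], bad[1, 2], path))
  validate_temperature_map(tmap)
  tmap
}

#' Convert a temperature map to an 8-bit gray image
#'
#' Linear min-max mapping to gray levels:
#' `gray = round(255 * (t - t_min) / (t_max - t_min))`, rounded half-up and
#' clipped to `[0, 255]`. The mapping is order-preserving in temperature.
#' With `t_min`/`t_max` left `NULL` the per-image minimum and maximum are
#' used, so every converted image spans the full gray range.
#'
#' @param tmap Numeric matrix of temperatures (degrees Celsius).
#' @param t_min,t_max Mapping bounds in degrees Celsius, or `NULL` for the
#'   map's own min/max.
#' @return Integer gray-level matrix, same shape as `tmap`.
#' @examples
#' tm <- matrix(c(30, 32, 34, 32), 2, 2)
#' temperature_to_gray(tm)
#' @export
temperature_to_gray <- function(tmap, t_min = NULL, t_max = NULL) {
  validate_temperature_map(tmap, physiologic = FALSE)
  if (is.null(t_min)) t_min <- min(tmap)
  if (is.null(t_max)) t_max <- max(tmap)
  if (t_max <= t_min)
    stop_egsvm("degenerate temperature range: t_max must exceed t_min")
  g <- clip(round_half_up(255 * (tmap - t_min) / (t_max - t_min)), 0, 255)
  storage.mode(g) <- "integer"
  g
}

#' Crop a region of interest from a gray image
#'
#' @param img Integer gray-level matrix.
#' @param region An [roi()] (0-based, half-open), a length-4 numeric
#'   `c(top, left, bottom, right)`, or a single-row window data frame.
#' @return The sub-image covered by the region.
#' @export
crop_roi <- function(img, region) {
  validate_gray_image(img)
  r <- as_roi(region)
  if (r$bottom > nrow(img) || r$right > ncol(img))
    stop_egsvm(sprintf("ROI [%d,%d)x[%d,%d) exceeds image of %d x %d",
                       r$top, r$bottom, r$left, r$right, nrow(img), ncol(img)))
  img[(r$top + 1):r$bottom, (r$left + 1):r$right, drop = FALSE]
}

#' Write a gray image as 8-bit PNG
#'
#' Round-trips exactly: reloading with [load_gray_image()] reproduces the
#' matrix bit for bit.
#'
#' @param img Integer gray-level matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  validate_gray_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a temperature map as plain-text CSV
#'
#' One image row per line, values comma-separated with four decimal places;
#' output is byte-identical for identical inputs.
#'
#' @param tmap Numeric temperature matrix (degrees Celsius).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(tmap, path) {
  validate_temperature_map(tmap, physiologic = FALSE)
  lines <- apply(tmap, 1, function(r) paste(sprintf("%.4f", r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a "top,left,bottom,right" region string
#'
#' Convenience for configuration files and command lines.
#'
#' @param s A string such as `"0,0,128,128"` (0-based, half-open), or `NULL`
#'   for no cropping.
#' @return An [roi()] or `NULL`.
#' @export
parse_roi <- function(s) {
  if (is.null(s) || !nzchar(s)) return(NULL)
  parts <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  if (length(parts) != 4 || anyNA(parts))
    stop_egsvm("ROI must be four integers: top,left,bottom,right")
  roi(parts[1], parts[2], parts[3], parts[4])
}
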