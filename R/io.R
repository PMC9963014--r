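# Raster I/O.
#
# RGB input comes from 8-bit TIFF/PNG (JPEG when the jpeg package is
# available); an alpha band populates the valid-pixel mask. Single-band
# grids (index, FVC, grade, label) are written as Esri ASCII grids (.asc):
# a plain-text, GDAL-readable raster format whose header carries the
# lower-left corner and cell size, with an explicit NODATA value. Values
# are printed at full double precision so real grids round-trip to well
# below 1e-6.

file_ext <- function(path) tolower(tools::file_ext(path))

#' Read an RGB raster
#'
#' Reads a 3-band (or RGBA) raster into an [rgb_image()]. The first three
#' bands are taken as red, green, blue in that order (use `band_order` to
#' reorder). An alpha band, where present, marks pixels with alpha 0 as
#' invalid.
#'
#' @param path Path to a TIFF, PNG or JPEG file.
#' @param channel_scale `"native8bit"` (default) keeps channels on the 0-255
#'   scale; `"unit"` divides by 255.
#' @param band_order Integer vector of length 3 picking the R, G, B bands.
#' @return An `rgbfvc_rgb` image.
#' @export
read_rgb <- function(path, channel_scale = c("native8bit", "unit"),
                     band_order = c(1L, 2L, 3L)) {
  channel_scale <- match.arg(channel_scale)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- file_ext(path)
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path) * 255,
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        abort("reading JPEG requires the 'jpeg' package")
      }
      jpeg::readJPEG(path) * 255
    },
    abort(sprintf("unsupported raster format: .%s", ext))
  )
  if (ext %in% c("tif", "tiff") && max(arr) <= 1) arr <- arr * 255
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3) {
    abort("raster must have at least 3 bands (R, G, B)")
  }
  if (!is.numeric(arr)) abort("raster has a non-numeric pixel type")
  mask <- if (dim(arr)[3] >= 4) arr[, , 4] > 0 else default_mask(arr[, , 1])
  sc <- if (channel_scale == "unit") 1 / 255 else 1
  rgb_image(
    red = arr[, , band_order[1]] * sc,
    green = arr[, , band_order[2]] * sc,
    blue = arr[, , band_order[3]] * sc,
    mask = mask
  )
}

#' Write an RGB image
#'
#' Writes an 8-bit TIFF or PNG; invalid pixels get a zero alpha band.
#' Channel values are rounded to integers 0-255 on write (the synthetic
#' generator already produces integer-valued channels, so its scenes
#' round-trip bit-exactly).
#'
#' @param image An `rgbfvc_rgb`.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path) {
  d <- dim(image)
  nb <- if (all(image$mask)) 3L else 4L
  arr <- array(0, dim = c(d[1], d[2], nb))
  clamp01 <- function(m) pmin(pmax(round(m) / 255, 0), 1)
  arr[, , 1] <- clamp01(image$red)
  arr[, , 2] <- clamp01(image$green)
  arr[, , 3] <- clamp01(image$blue)
  if (nb == 4L) arr[, , 4] <- ifelse(image$mask, 1, 0)
  ext <- file_ext(path)
  switch(ext,
    tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    png = png::writePNG(arr, path),
    abort(sprintf("unsupported output format: .%s", ext))
  )
  invisible(path)
}

asc_georef <- function(georef) {
  g <- list(xllcorner = 0, yllcorner = 0, cellsize = 1)
  if (!is.null(georef)) for (k in names(g)) if (!is.null(georef[[k]])) g[[k]] <- georef[[k]]
  g
}

grid_payload <- function(grid) {
  if (inherits(grid, "rgbfvc_index") || inherits(grid, "rgbfvc_fvc")) {
    list(values = grid$values, integer = FALSE)
  } else if (inherits(grid, "rgbfvc_grades")) {
    list(values = grid$grades, integer = TRUE)
  } else if (inherits(grid, "rgbfvc_labels")) {
    list(values = grid$labels, integer = TRUE)
  } else if (inherits(grid, "rgbfvc_change")) {
    list(values = grid$values, integer = FALSE)
  } else if (is.matrix(grid)) {
    list(values = grid, integer = is.integer(grid))
  } else {
    abort("unsupported grid type for write_raster()")
  }
}

#' Write a single-band grid as an Esri ASCII raster
#'
#' Accepts an index image, FVC map, grade map, label map, change map or a
#' bare matrix. Integer grids (grades, labels) are written as integers,
#' real grids at full double precision. Invalid pixels are written as the
#' declared NODATA value; the georeference header (lower-left corner, cell
#' size) is carried through when the grid has one.
#'
#' @param grid The grid object to write.
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  p <- grid_payload(grid)
  mask <- if (is.matrix(grid)) default_mask(grid) else grid$mask
  if (any(!is.finite(p$values[mask]))) abort("grid is not finite on valid pixels")
  g <- asc_georef(if (is.matrix(grid)) NULL else grid$georef)
  nodata <- -9999
  vals <- p$values
  vals[!mask] <- nodata
  fmt <- if (p$integer) function(v) sprintf("%d", as.integer(v)) else function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(vals)),
    sprintf("nrows %d", nrow(vals)),
    sprintf("xllcorner %.17g", g$xllcorner),
    sprintf("yllcorner %.17g", g$yllcorner),
    sprintf("cellsize %.17g", g$cellsize),
    sprintf("NODATA_value %d", as.integer(nodata))
  ), con)
  writeLines(apply(vals, 1, function(r) paste(fmt(r), collapse = " ")), con)
  invisible(path)
}

#' Read an Esri ASCII raster
#'
#' @param path Path to a `.asc` file written by [write_raster()] or any
#'   GDAL-style Esri ASCII grid.
#' @return A list with `values` (numeric matrix), `mask` (logical matrix)
#'   and `georef` (lower-left corner + cell size).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nr <- as.integer(header$nrows); nc <- as.integer(header$ncols)
  nodata <- if (!is.null(header$nodata_value)) header$nodata_value else -9999
  vals <- matrix(
    scan(text = lines[i:(i + nr - 1)], quiet = TRUE),
    nrow = nr, ncol = nc, byrow = TRUE
  )
  mask <- vals != nodata
  vals[!mask] <- NA_real_
  list(
    values = vals, mask = mask,
    georef = list(xllcorner = header$xllcorner, yllcorner = header$yllcorner,
                  cellsize = header$cellsize)
  )
}

#' Read a land-cover label raster
#'
#' @param path Path to a single-band integer Esri ASCII raster.
#' @param class_names Named character vector mapping integer codes to class
#'   names; every code present in the raster must be listed.
#' @param vegetation Name of the designated vegetation class.
#' @return An `rgbfvc_labels` map.
#' @export
read_labels <- function(path, class_names, vegetation = "vegetation") {
  r <- read_raster(path)
  vals <- r$values
  if (any(abs(vals[r$mask] - round(vals[r$mask])) > 0)) {
    abort("label raster is not integer-valued")
  }
  vals[!r$mask] <- 0L
  label_map(matrix(as.integer(round(vals)), nrow(vals), ncol(vals)),
            class_names = class_names, mask = r$mask,
            vegetation = vegetation, georef = r$georef)
}
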