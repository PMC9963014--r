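# Shared grid containers. All grids are matrices with nrow = image height
# (rows, top to bottom) and ncol = width; a logical valid-pixel mask of the
# same shape rides along. Nodata is always the mask, never a sentinel value
# inside arithmetic.

check_grid_dims <- function(..., mask) {
  grids <- list(...)
  d <- dim(grids[[1]])
  for (g in grids) {
    if (!is.matrix(g)) abort("grid values must be matrices")
    if (!identical(dim(g), d)) abort("grid dimensions do not match")
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), d)) {
      abort("valid_mask must be a logical matrix matching the grid dimensions")
    }
  }
  invisible(d)
}

default_mask <- function(values) {
  array(TRUE, dim = dim(values))
}

#' Construct an RGB image grid
#'
#' The basic raster container of the package: three real-valued channel
#' matrices (red, green, blue) in the native 8-bit range 0-255 by default,
#' plus a logical valid-pixel mask. Channels are carried as real numbers so
#' index arithmetic never truncates.
#'
#' @param red,green,blue Numeric matrices of identical dimensions
#'   (rows = image height).
#' @param mask Logical matrix marking valid pixels; defaults to all valid.
#' @param georef Optional opaque georeference carried through to outputs
#'   (a list such as `list(xllcorner =, yllcorner =, cellsize =)`).
#' @return An object of class `rgbfvc_rgb`.
#' @examples
#' img <- rgb_image(matrix(10, 2, 2), matrix(200, 2, 2), matrix(30, 2, 2))
#' dim(img)
#' @export
rgb_image <- function(red, green, blue, mask = NULL, georef = NULL) {
  if (is.null(mask)) mask <- default_mask(red)
  check_grid_dims(red, green, blue, mask = mask)
  for (ch in list(red, green, blue)) {
    if (any(!is.finite(ch[mask]))) abort("channel values must be finite on valid pixels")
  }
  structure(
    list(red = red, green = green, blue = blue, mask = mask, georef = georef),
    class = "rgbfvc_rgb"
  )
}

#' Construct a land-cover label map
#'
#' @param labels Integer matrix of class codes.
#' @param class_names Named character vector mapping code to class name,
#'   e.g. `c("1" = "vegetation", "2" = "bare_ground")`. Every valid pixel's
#'   code must appear in the mapping.
#' @param mask Logical validity matrix; defaults to all valid.
#' @param vegetation Name of the designated vegetation class.
#' @param georef Optional opaque georeference.
#' @return An object of class `rgbfvc_labels`.
#' @export
label_map <- function(labels, class_names, mask = NULL,
                      vegetation = "vegetation", georef = NULL) {
  if (is.null(mask)) mask <- default_mask(labels)
  check_grid_dims(labels, mask = mask)
  codes <- suppressWarnings(as.integer(names(class_names)))
  if (anyNA(codes)) abort("class_names must be named by integer codes")
  present <- unique(labels[mask])
  missing <- setdiff(present, codes)
  if (length(missing) > 0) {
    abort(sprintf("label codes not in class_names: %s",
                  paste(missing, collapse = ", ")))
  }
  if (!vegetation %in% class_names) {
    abort(sprintf("class_names has no '%s' class", vegetation))
  }
  structure(
    list(labels = labels, class_names = class_names, mask = mask,
         vegetation = vegetation, georef = georef),
    class = "rgbfvc_labels"
  )
}

new_index_image <- function(values, index, polarity, mask, georef = NULL,
                            cive_preset = NULL) {
  check_grid_dims(values, mask = mask)
  structure(
    list(values = values, index = index, polarity = polarity, mask = mask,
         cive_preset = cive_preset, georef = georef),
    class = "rgbfvc_index"
  )
}

new_fvc_map <- function(values, endpoints = NULL, mask = NULL, georef = NULL) {
  if (is.null(mask)) mask <- default_mask(values)
  check_grid_dims(values, mask = mask)
  v <- values[mask]
  if (any(v < -1e-12 | v > 1 + 1e-12)) abort("FVC values must lie in [0, 1]")
  structure(
    list(values = values, endpoints = endpoints, mask = mask, georef = georef),
    class = "rgbfvc_fvc"
  )
}

#' Construct a fractional-cover map directly
#'
#' Mostly used for ground-truth grids; pipeline FVC maps come from
#' [compute_fvc()].
#'
#' @param values Numeric matrix of cover fractions in \[0, 1\].
#' @param mask Logical validity matrix.
#' @param georef Optional opaque georeference.
#' @return An object of class `rgbfvc_fvc`.
#' @export
fvc_map <- function(values, mask = NULL, georef = NULL) {
  new_fvc_map(values, endpoints = NULL, mask = mask, georef = georef)
}

new_grade_map <- function(grades, scheme, mask, georef = NULL) {
  check_grid_dims(grades, mask = mask)
  structure(
    list(grades = grades, scheme = scheme, mask = mask, georef = georef),
    class = "rgbfvc_grades"
  )
}

#' @export
dim.rgbfvc_rgb <- function(x) dim(x$red)
#' @export
dim.rgbfvc_labels <- function(x) dim(x$labels)
#' @export
dim.rgbfvc_index <- function(x) dim(x$values)
#' @export
dim.rgbfvc_fvc <- function(x) dim(x$values)
#' @export
dim.rgbfvc_grades <- function(x) dim(x$grades)

#' @export
print.rgbfvc_rgb <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgbfvc_rgb> %d x %d pixels, %d valid\n", d[2], d[1], sum(x$mask)))
  invisible(x)
}

#' @export
print.rgbfvc_index <- function(x, ...) {
  d <- dim(x)
  v <- x$values[x$mask]
  cat(sprintf("<rgbfvc_index> %s (%s), %d x %d pixels, %d valid, range [%.4g, %.4g]\n",
              x$index, x$polarity, d[2], d[1], sum(x$mask),
              min(v), max(v)))
  invisible(x)
}

#' @export
print.rgbfvc_fvc <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgbfvc_fvc> %d x %d pixels, %d valid, mean FVC %.4f\n",
              d[2], d[1], sum(x$mask), mean(x$values[x$mask])))
  if (!is.null(x$endpoints)) {
    cat(sprintf("  endpoints: %s soil %.6g, veg %.6g\n",
                x$endpoints$index, x$endpoints$vi_soil, x$endpoints$vi_veg))
  }
  invisible(x)
}

#' @export
print.rgbfvc_grades <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgbfvc_grades> %s scheme, %d x %d pixels, %d valid\n",
              x$scheme$name, d[2], d[1], sum(x$mask)))
  invisible(x)
}

#' @export
print.rgbfvc_labels <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgbfvc_labels> %d classes, %d x %d pixels, %d valid\n",
              length(x$class_names), d[2], d[1], sum(x$mask)))
  invisible(x)
}

grid_to_tibble <- function(values, mask, value_col = "value") {
  d <- dim(values)
  tb <- tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2]),
    !!value_col := as.vector(values),
    valid = as.vector(mask)
  )
  tb
}

#' @method as_tibble rgbfvc_rgb
#' @export
as_tibble.rgbfvc_rgb <- function(x, ...) {
  d <- dim(x)
  img <- x
  tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2]),
    red = as.vector(img$red), green = as.vector(img$green),
    blue = as.vector(img$blue),
    valid = as.vector(img$mask)
  )
}

#' @method as_tibble rgbfvc_index
#' @export
as_tibble.rgbfvc_index <- function(x, ...) grid_to_tibble(x$values, x$mask)

#' @method as_tibble rgbfvc_fvc
#' @export
as_tibble.rgbfvc_fvc <- function(x, ...) grid_to_tibble(x$values, x$mask, "fvc")

#' @method as_tibble rgbfvc_grades
#' @export
as_tibble.rgbfvc_grades <- function(x, ...) grid_to_tibble(x$grades, x$mask, "grade")

#' @method as_tibble rgbfvc_labels
#' @export
as_tibble.rgbfvc_labels <- function(x, ...) {
  tb <- grid_to_tibble(x$labels, x$mask, "code")
  tb$class <- unname(x$class_names[as.character(tb$code)])
  tb
}
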