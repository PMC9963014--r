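# The dimidiate (pixel-dichotomy) model.
#
# Each pixel's index value is assumed to mix a pure-vegetation and a
# pure-soil endmember, so cover = (VI - VI_soil) / (VI_veg - VI_soil).
# Pure-pixel endpoints are read off the index histogram as percentile cuts
# (default 2% / 98%), polarity-aware: for a decreasing index (CIVE) the
# soil endpoint sits in the high tail. Values outside the endpoint range
# are noise pixels and clamp to 0 (below soil) or 1 (above vegetation).

#' Construct an endpoint pair by hand
#'
#' Builds the pure-soil / pure-vegetation endpoint container directly, e.g.
#' to reproduce published endpoint tables instead of estimating them from
#' an image. The ordering must be consistent with the index polarity:
#' soil < veg for increasing indices, soil > veg for CIVE.
#'
#' @param vi_soil Index value of bare-soil pure pixels.
#' @param vi_veg Index value of 100% vegetation pure pixels.
#' @param index Index name the endpoints belong to.
#' @param confidence Cumulative-fraction cut used to obtain them, if any.
#' @return An object of class `rgbfvc_endpoints`.
#' @examples
#' endpoint_pair(0.105882, -0.819608, "CIVE")
#' @export
endpoint_pair <- function(vi_soil, vi_veg, index, confidence = NA_real_) {
  index <- toupper(index)
  if (!index %in% INDEX_ORDER) abort(sprintf("unknown vegetation index: %s", index))
  if (vi_soil == vi_veg) abort("degenerate endpoints: vi_soil equals vi_veg")
  polarity <- index_polarity(index)
  ok <- if (polarity == "increasing") vi_soil < vi_veg else vi_soil > vi_veg
  if (!ok) {
    abort(sprintf(
      "endpoint ordering inconsistent with %s polarity (%s): vi_soil %g, vi_veg %g",
      index, polarity, vi_soil, vi_veg))
  }
  structure(
    list(vi_soil = vi_soil, vi_veg = vi_veg, index = index,
         polarity = polarity, confidence = confidence),
    class = "rgbfvc_endpoints"
  )
}

#' @export
print.rgbfvc_endpoints <- function(x, ...) {
  cat(sprintf("<rgbfvc_endpoints> %s: soil %.6g, veg %.6g (confidence %s)\n",
              x$index, x$vi_soil, x$vi_veg,
              if (is.na(x$confidence)) "supplied" else format(x$confidence)))
  invisible(x)
}

#' @method as_tibble rgbfvc_endpoints
#' @export
as_tibble.rgbfvc_endpoints <- function(x, ...) {
  tibble(index = x$index, vi_soil = x$vi_soil, vi_veg = x$vi_veg,
         polarity = x$polarity, confidence = x$confidence)
}

# Nearest-rank percentile: the ceil(q * n)-th order statistic of the sorted
# valid pixels. Integer-rank semantics make the estimate reproducible and
# oracle-checkable, unlike interpolated quantiles.
nearest_rank <- function(sorted, q) {
  n <- length(sorted)
  sorted[min(n, max(1L, as.integer(ceiling(q * n))))]
}

#' Estimate pure-pixel endpoints from an index histogram
#'
#' Reads the pure-soil and pure-vegetation index values off the cumulative
#' distribution of valid pixels: at confidence c (default 0.02), the soil
#' endpoint is the value at cumulative fraction c and the vegetation
#' endpoint at 1 - c for an increasing index; for a decreasing index (CIVE)
#' the two tails swap roles. Percentiles use the nearest-rank rule.
#'
#' @param index_image An `rgbfvc_index` image with at least 100 valid pixels.
#' @param confidence Cumulative-pixel cut in (0, 0.5); default 0.02.
#' @return An `rgbfvc_endpoints` pair.
#' @export
estimate_endpoints <- function(index_image, confidence = 0.02) {
  if (!(confidence > 0 && confidence < 0.5)) {
    abort("confidence must lie strictly between 0 and 0.5")
  }
  x <- index_image$values[index_image$mask]
  if (length(x) < 100) abort("need at least 100 valid pixels to estimate endpoints")
  s <- sort(x)
  lo <- nearest_rank(s, confidence)
  hi <- nearest_rank(s, 1 - confidence)
  if (lo == hi) abort("degenerate index distribution: both endpoints coincide")
  if (index_image$polarity == "increasing") {
    endpoint_pair(lo, hi, index_image$index, confidence)
  } else {
    endpoint_pair(hi, lo, index_image$index, confidence)
  }
}

#' Apply the dimidiate pixel model
#'
#' Converts an index image into fractional vegetation cover:
#' F = (VI - VI_soil) / (VI_veg - VI_soil), clamped to \[0, 1\] so that
#' noise pixels beyond the pure-soil (pure-vegetation) endpoint are
#' classified as fully uncovered (fully covered).
#'
#' @param index_image An `rgbfvc_index` image.
#' @param endpoints An `rgbfvc_endpoints` pair for the same index, either
#'   estimated by [estimate_endpoints()] or supplied via [endpoint_pair()].
#' @return An `rgbfvc_fvc` map carrying the endpoints used.
#' @export
compute_fvc <- function(index_image, endpoints) {
  if (!inherits(endpoints, "rgbfvc_endpoints")) abort("endpoints must be an rgbfvc_endpoints")
  if (!identical(endpoints$index, index_image$index)) {
    abort(sprintf("endpoint/index mismatch: endpoints are for %s, image is %s",
                  endpoints$index, index_image$index))
  }
  f <- (index_image$values - endpoints$vi_soil) /
    (endpoints$vi_veg - endpoints$vi_soil)
  f <- pmin(pmax(f, 0), 1)
  f[!index_image$mask] <- NA_real_
  new_fvc_map(f, endpoints = endpoints, mask = index_image$mask,
              georef = index_image$georef)
}

#' Mean fractional cover of a map
#'
#' @param fvc An `rgbfvc_fvc` map with at least one valid pixel.
#' @return The arithmetic mean cover fraction over valid pixels.
#' @export
mean_fvc <- function(fvc) {
  v <- fvc$values[fvc$mask]
  if (length(v) == 0) abort("FVC map has no valid pixels")
  mean(v)
}

#' Cover-grade classification schemes
#'
#' Two standard discretizations of fractional cover. `five_level` splits
#' \[0, 1\] into 0-20%, 20-40%, 40-60%, 60-80% and 80-100% (codes 1-5).
#' `six_level` adds a dedicated zero class: exactly 0, then (0, 20%),
#' 20-40%, ..., 80-100% (codes 0-5). Intervals are lower-inclusive /
#' upper-exclusive except the top, which includes 1.
#'
#' @param name `"five_level"` or `"six_level"`.
#' @return A `rgbfvc_scheme` list with breakpoints, codes and labels.
#' @export
grade_scheme <- function(name = c("five_level", "six_level")) {
  name <- match.arg(name)
  upper <- c("20-40%", "40-60%", "60-80%", "80-100%")
  if (name == "five_level") {
    codes <- 1:5
    labels <- c("0-20%", upper)
  } else {
    codes <- 0:5
    labels <- c("0", "1-20%", upper)
  }
  structure(list(name = name, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                 codes = codes, labels = setNames(labels, codes)),
            class = "rgbfvc_scheme")
}

#' Discretize an FVC map into cover grades
#'
#' @param fvc An `rgbfvc_fvc` map.
#' @param scheme A [grade_scheme()] or its name.
#' @return An `rgbfvc_grades` map.
#' @examples
#' m <- fvc_map(matrix(c(0, 0.1, 0.2, 1), 2, 2))
#' grade_fvc(m, "six_level")$grades
#' @export
grade_fvc <- function(fvc, scheme = "five_level") {
  if (is.character(scheme)) scheme <- grade_scheme(scheme)
  v <- fvc$values
  g <- findInterval(v, c(0.2, 0.4, 0.6, 0.8)) + 1L
  if (scheme$name == "six_level") g[v == 0] <- 0L
  g <- matrix(as.integer(g), nrow(v), ncol(v))
  g[!fvc$mask] <- NA_integer_
  new_grade_map(g, scheme = scheme, mask = fvc$mask, georef = fvc$georef)
}

#' Share of area in each cover grade
#'
#' @param grades An `rgbfvc_grades` map with at least one valid pixel.
#' @return A tibble with one row per grade of the scheme (including empty
#'   grades): `grade`, `label`, `n` and `fraction`; fractions sum to 1.
#' @export
grade_area_fractions <- function(grades) {
  g <- grades$grades[grades$mask]
  if (length(g) == 0) abort("grade map has no valid pixels")
  codes <- grades$scheme$codes
  n <- vapply(codes, function(k) sum(g == k), integer(1))
  tibble(
    grade = as.integer(codes),
    label = unname(grades$scheme$labels[as.character(codes)]),
    n = n,
    fraction = n / length(g)
  )
}
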