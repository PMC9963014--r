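# Multi-date change analysis: per-date mean cover and grade-area shares,
# and pairwise difference maps that localise degradation. Scenes are
# assumed co-registered; mismatched dimensions are an error.

#' Summarise a dated sequence of FVC maps
#'
#' For each date: the mean cover fraction and the area share of each cover
#' grade (six-level scheme by default, so "no cover" is its own class).
#'
#' @param scenes Named list of `rgbfvc_fvc` maps; names are the date labels
#'   and their order is preserved. All maps must come from the same index
#'   when their endpoints record one.
#' @param scheme Grade scheme for the area shares (name or [grade_scheme()]).
#' @return An `rgbfvc_series` tibble with columns `date`, `mean_fvc` and a
#'   `grade_fractions` list-column; [tidy()] unnests the grade shares,
#'   [glance()] gives the overall trend summary.
#' @export
series_summary <- function(scenes, scheme = "six_level") {
  if (length(scenes) == 0) abort("no scenes supplied")
  dates <- names(scenes)
  if (is.null(dates) || any(dates == "") || anyDuplicated(dates)) {
    abort("scenes must be uniquely named by date label")
  }
  idx <- unique(unlist(lapply(scenes, function(s) {
    if (!is.null(s$endpoints)) s$endpoints$index else NULL
  })))
  if (length(idx) > 1) {
    abort(sprintf("scenes mix indices: %s", paste(idx, collapse = ", ")))
  }
  if (is.character(scheme)) scheme <- grade_scheme(scheme)
  out <- tibble(
    date = dates,
    mean_fvc = vapply(scenes, mean_fvc, numeric(1), USE.NAMES = FALSE),
    grade_fractions = unname(lapply(scenes, function(s) {
      grade_area_fractions(grade_fvc(s, scheme))
    }))
  )
  structure(out, class = c("rgbfvc_series", class(out)),
            index = if (length(idx) == 1) idx else NA_character_,
            scheme = scheme$name)
}

#' @rdname series_summary
#' @param x An `rgbfvc_series`.
#' @param ... Unused.
#' @export
tidy.rgbfvc_series <- function(x, ...) {
  tidyr::unnest(
    tibble(date = x$date, grade_fractions = x$grade_fractions),
    "grade_fractions"
  )
}

#' @rdname series_summary
#' @export
glance.rgbfvc_series <- function(x, ...) {
  tibble(
    n_dates = nrow(x),
    index = attr(x, "index"),
    first_mean_fvc = x$mean_fvc[1],
    last_mean_fvc = x$mean_fvc[nrow(x)],
    net_change = x$mean_fvc[nrow(x)] - x$mean_fvc[1]
  )
}

#' Difference map between two dates
#'
#' Per-pixel later-minus-earlier cover change on jointly valid pixels, in
#' \[-1, 1\]. Negative patches flag local degradation even when the
#' area-wide mean is improving.
#'
#' @param earlier,later `rgbfvc_fvc` maps of identical dimensions.
#' @return An object of class `rgbfvc_change` (`values` matrix + `mask`);
#'   `mean_change()` gives its mean over valid pixels.
#' @export
change_map <- function(earlier, later) {
  if (!identical(dim(earlier), dim(later))) {
    abort("FVC maps have different dimensions")
  }
  joint <- earlier$mask & later$mask
  v <- later$values - earlier$values
  v[!joint] <- NA_real_
  structure(list(values = v, mask = joint, georef = earlier$georef),
            class = "rgbfvc_change")
}

#' @rdname change_map
#' @param change An `rgbfvc_change` map.
#' @export
mean_change <- function(change) {
  v <- change$values[change$mask]
  if (length(v) == 0) abort("change map has no valid pixels")
  mean(v)
}

#' @export
print.rgbfvc_change <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rgbfvc_change> %d x %d pixels, %d valid, mean change %+.4f\n",
              d[2], d[1], sum(x$mask), mean(x$values[x$mask])))
  invisible(x)
}

#' @method as_tibble rgbfvc_change
#' @export
as_tibble.rgbfvc_change <- function(x, ...) grid_to_tibble(x$values, x$mask, "change")
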