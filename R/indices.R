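# Visible-band vegetation indices.
#
# Seven greenness scores computable from R, G, B alone. All increase with
# vegetation greenness except CIVE, which decreases: its polarity drives
# which histogram tail the dichotomy treats as bare soil. The CIVE green
# coefficient has two presets: "literature" is the standard formulation
# 0.441 R - 0.811 G + 0.385 B + 18.78745; "paper" keeps a positive green
# term (0.44 R + 0.88 G + 0.39 B + 18.79) as some transcriptions print it.
# The literature preset is the default: only a negative green coefficient
# yields the expected negative CIVE values over dense vegetation.

INDEX_ORDER <- c("EXG", "GRVI", "EXGR", "NGBDI", "CIVE", "RGBVI", "VDVI")

INDEX_LONG_NAMES <- c(
  EXG = "excess green",
  GRVI = "green-red vegetation index",
  EXGR = "excess green minus excess red",
  NGBDI = "normalized green-blue difference index",
  CIVE = "color index of vegetation extraction",
  RGBVI = "red-green-blue vegetation index",
  VDVI = "visible-band difference vegetation index"
)

#' Catalogue of the visible-band vegetation indices
#'
#' @return A tibble with one row per index: `index` (short name), `long_name`,
#'   `polarity` (`"increasing"` if the index rises with vegetation greenness,
#'   `"decreasing"` for CIVE) and `normalized` (whether values are confined
#'   to \[-1, 1\]).
#' @examples
#' fvc_indices()
#' @export
fvc_indices <- function() {
  tibble(
    index = INDEX_ORDER,
    long_name = unname(INDEX_LONG_NAMES[INDEX_ORDER]),
    polarity = ifelse(INDEX_ORDER == "CIVE", "decreasing", "increasing"),
    normalized = INDEX_ORDER %in% c("GRVI", "NGBDI", "RGBVI", "VDVI")
  )
}

index_polarity <- function(index) {
  if (index == "CIVE") "decreasing" else "increasing"
}

# Scalar-friendly formula evaluation; returns values plus a logical
# "defined" marker that is FALSE where a normalized index's denominator
# vanishes (e.g. a pure-black pixel for GRVI).
index_formula <- function(index, r, g, b, cive_preset = "literature") {
  switch(index,
    EXG = list(values = 2 * g - r - b, defined = rep(TRUE, length(r))),
    GRVI = {
      den <- g + r
      list(values = ifelse(den == 0, NA_real_, (g - r) / den), defined = den != 0)
    },
    EXGR = list(values = (2 * g - r - b) - (1.4 * r - g),
                defined = rep(TRUE, length(r))),
    NGBDI = {
      den <- g + b
      list(values = ifelse(den == 0, NA_real_, (g - b) / den), defined = den != 0)
    },
    CIVE = {
      v <- if (cive_preset == "paper") {
        0.44 * r + 0.88 * g + 0.39 * b + 18.79
      } else {
        0.441 * r - 0.811 * g + 0.385 * b + 18.78745
      }
      list(values = v, defined = rep(TRUE, length(r)))
    },
    RGBVI = {
      den <- g^2 + r * b
      list(values = ifelse(den == 0, NA_real_, (g^2 - r * b) / den), defined = den != 0)
    },
    VDVI = {
      den <- g + (r + b) / 2
      list(values = ifelse(den == 0, NA_real_, (g - (r + b) / 2) / den), defined = den != 0)
    },
    abort(sprintf("unknown vegetation index: %s", index))
  )
}

#' Compute a visible-band vegetation index
#'
#' Applies one of the seven index formulas per pixel. Pixels where a
#' normalized index's denominator is zero (e.g. pure black for GRVI) are
#' marked invalid in the output mask rather than assigned an arbitrary
#' value, so they cannot bias the endpoint percentiles downstream.
#'
#' @param image An `rgbfvc_rgb` image.
#' @param index Index name (case-insensitive): one of EXG, GRVI, EXGR,
#'   NGBDI, CIVE, RGBVI, VDVI.
#' @param cive_preset For CIVE only: `"literature"` (default) or `"paper"`.
#' @return An `rgbfvc_index` image tagged with the index and its polarity.
#' @examples
#' img <- rgb_image(matrix(60, 1, 1), matrix(180, 1, 1), matrix(0, 1, 1))
#' compute_index(img, "GRVI")$values  # (180 - 60) / (180 + 60) = 0.5
#' @export
compute_index <- function(image, index, cive_preset = c("literature", "paper")) {
  cive_preset <- match.arg(cive_preset)
  index <- toupper(index)
  if (!index %in% INDEX_ORDER) abort(sprintf("unknown vegetation index: %s", index))
  res <- index_formula(index, as.vector(image$red), as.vector(image$green),
                       as.vector(image$blue), cive_preset)
  d <- dim(image)
  values <- matrix(res$values, d[1], d[2])
  mask <- image$mask & matrix(res$defined, d[1], d[2])
  values[!mask] <- NA_real_
  new_index_image(values, index = index, polarity = index_polarity(index),
                  mask = mask, georef = image$georef,
                  cive_preset = if (index == "CIVE") cive_preset else NULL)
}
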