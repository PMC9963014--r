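# Seeded synthetic scenes with ground truth.
#
# A scene is a five-class land-cover mosaic (vegetation, bare ground,
# road, sedimentation pond, building) laid out as contiguous blobs: one
# smooth Gaussian random field is partitioned by its rank into class bands
# whose sizes match the requested area fractions, so patch geometry is
# spatially coherent and grade-area statistics are nontrivial. Pixel
# colors are drawn around per-class mean RGB values with a per-channel
# spread, plus additive sensor noise; a configurable share of pixels are
# convex vegetation/soil blends (the two-endmember mixing the dimidiate
# model assumes), whose blend weight is the pixel's true cover fraction.

SCENE_CLASSES <- c("vegetation", "bare_ground", "road", "pond", "building")

default_class_colors <- function() {
  m <- rbind(
    vegetation = c(40, 120, 50),
    bare_ground = c(150, 130, 110),
    road = c(170, 170, 170),
    pond = c(120, 130, 125),
    building = c(180, 190, 210)
  )
  colnames(m) <- c("red", "green", "blue")
  m
}

#' Specify a synthetic scene
#'
#' Defaults mirror a restoration-area scene late in recovery: class area
#' shares follow the proportions of a largely revegetated mining district
#' (about 74% vegetation), with well-separated green vegetation against
#' gray/brown ground classes.
#'
#' @param width,height Scene size in pixels.
#' @param class_fractions Named fractions for vegetation, bare_ground,
#'   road, pond, building; must sum to 1.
#' @param class_colors 5 x 3 matrix of mean RGB (0-255) per class, rows
#'   named as `class_fractions`.
#' @param color_spread Per-channel standard deviation of within-class
#'   color variation (8-bit units).
#' @param mixed_pixel_fraction Share of pixels replaced by convex
#'   vegetation/bare-ground blends with blend weight ~ Uniform(0, 1).
#' @param noise_sd Additive per-channel sensor noise standard deviation.
#' @param smoothness Gaussian correlation length (pixels) of the class
#'   layout field; larger values give larger patches.
#' @param seed Integer RNG seed; scenes are bit-reproducible given the seed.
#' @return A `rgbfvc_scene_spec` list.
#' @export
scene_spec <- function(width = 256, height = 256,
                       class_fractions = c(vegetation = 0.737,
                                           bare_ground = 0.071,
                                           road = 0.103,
                                           pond = 0.018,
                                           building = 0.071),
                       class_colors = default_class_colors(),
                       color_spread = 15,
                       mixed_pixel_fraction = 0.05,
                       noise_sd = 5,
                       smoothness = 8,
                       seed = 1L) {
  if (width < 2 || height < 2) abort("degenerate scene dimensions")
  if (!setequal(names(class_fractions), SCENE_CLASSES)) {
    abort(sprintf("class_fractions must name exactly: %s",
                  paste(SCENE_CLASSES, collapse = ", ")))
  }
  class_fractions <- class_fractions[SCENE_CLASSES]
  if (abs(sum(class_fractions) - 1) > 1e-9) abort("class fractions must sum to 1")
  if (any(class_fractions < 0)) abort("class fractions must be non-negative")
  class_colors <- as.matrix(class_colors)[SCENE_CLASSES, , drop = FALSE]
  if (any(class_colors < 0 | class_colors > 255)) {
    abort("class colors must lie in the 0-255 channel domain")
  }
  if (!(mixed_pixel_fraction >= 0 && mixed_pixel_fraction <= 1)) {
    abort("mixed_pixel_fraction must lie in [0, 1]")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         class_fractions = class_fractions, class_colors = class_colors,
         color_spread = color_spread,
         mixed_pixel_fraction = mixed_pixel_fraction,
         noise_sd = noise_sd, smoothness = smoothness,
         seed = as.integer(seed)),
    class = "rgbfvc_scene_spec"
  )
}

# Smooth periodic Gaussian random field via FFT convolution.
smooth_field <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), h, w)
  if (sigma <= 0) return(z)
  dy <- pmin(0:(h - 1), h - (0:(h - 1)))
  dx <- pmin(0:(w - 1), w - (0:(w - 1)))
  k <- outer(exp(-dy^2 / (2 * sigma^2)), exp(-dx^2 / (2 * sigma^2)))
  k <- k / sum(k)
  Re(fft(fft(z) * fft(k), inverse = TRUE)) / (h * w)
}

# Class layout: rank the field and cut it into bands sized by the class
# fractions. Vegetation takes the top band so that growing its fraction
# expands the same patches coherently across a multi-date sweep.
assign_classes <- function(field, fractions) {
  n <- length(field)
  order_classes <- c(setdiff(SCENE_CLASSES, "vegetation"), "vegetation")
  counts <- diff(round(cumsum(c(0, fractions[order_classes])) * n))
  r <- rank(field, ties.method = "first")
  cls <- order_classes[findInterval(r - 1, cumsum(counts), left.open = FALSE) + 1L]
  code <- match(cls, SCENE_CLASSES)
  matrix(as.integer(code), nrow(field), ncol(field))
}

generate_scene_core <- function(spec, field, color_seed) {
  h <- spec$height; w <- spec$width; n <- h * w
  labels <- assign_classes(field, spec$class_fractions)
  truth <- matrix(as.numeric(labels == 1L), h, w)
  withr::with_seed(color_seed, {
    mu <- spec$class_colors[as.vector(labels), , drop = FALSE]
    chans <- lapply(1:3, function(j) mu[, j] + rnorm(n, 0, spec$color_spread))
    # Convex vegetation/soil blends: weights are uniform on (0,1); pixels
    # with majority vegetation weight are placed on vegetation-labelled
    # pixels (and vice versa) so label tallies stay exact. Blends need both
    # endmembers present in the scene.
    m <- round(spec$mixed_pixel_fraction * n)
    if (spec$class_fractions[["vegetation"]] == 0 ||
        spec$class_fractions[["bare_ground"]] == 0) m <- 0L
    if (m > 0) {
      wgt <- runif(m)
      veg_idx <- which(as.vector(labels) == 1L)
      bare_idx <- which(as.vector(labels) == 2L)
      hi <- which(wgt >= 0.5); lo <- which(wgt < 0.5)
      pick_veg <- veg_idx[sample.int(length(veg_idx), min(length(hi), length(veg_idx)))]
      pick_bare <- bare_idx[sample.int(length(bare_idx), min(length(lo), length(bare_idx)))]
      sel <- c(pick_veg, pick_bare)
      wsel <- c(wgt[hi][seq_along(pick_veg)], wgt[lo][seq_along(pick_bare)])
      if (length(sel) > 0) {
        for (j in 1:3) {
          veg_draw <- spec$class_colors["vegetation", j] + rnorm(length(sel), 0, spec$color_spread)
          soil_draw <- spec$class_colors["bare_ground", j] + rnorm(length(sel), 0, spec$color_spread)
          chans[[j]][sel] <- wsel * veg_draw + (1 - wsel) * soil_draw
        }
        truth[sel] <- wsel
      }
    }
    chans <- lapply(chans, function(v) {
      v <- v + rnorm(n, 0, spec$noise_sd)
      matrix(pmin(pmax(round(v), 0), 255), h, w)
    })
  })
  class_names <- setNames(SCENE_CLASSES, seq_along(SCENE_CLASSES))
  structure(
    list(
      image = rgb_image(chans[[1]], chans[[2]], chans[[3]]),
      labels = label_map(labels, class_names),
      truth_fvc = fvc_map(truth),
      spec = spec
    ),
    class = "rgbfvc_scene"
  )
}

#' Generate a synthetic scene with ground truth
#'
#' Deterministic given the spec's seed: the same spec yields bit-identical
#' scenes. Realized class areas match the requested fractions to within
#' rounding (a pixel), by construction of the rank-based layout.
#'
#' @param spec A [scene_spec()].
#' @return An `rgbfvc_scene`: `image` (`rgbfvc_rgb`), `labels`
#'   (`rgbfvc_labels`), `truth_fvc` (`rgbfvc_fvc`; 1 on pure vegetation,
#'   the blend weight on mixed pixels, 0 elsewhere) and the echoed `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(width = 64, height = 64, seed = 7))
#' mean_fvc(sc$truth_fvc)
#' @export
generate_scene <- function(spec) {
  field <- withr::with_seed(spec$seed, smooth_field(spec$height, spec$width, spec$smoothness))
  generate_scene_core(spec, field, color_seed = spec$seed + 1L)
}

#' @export
print.rgbfvc_scene <- function(x, ...) {
  cat(sprintf("<rgbfvc_scene> %d x %d, seed %d, truth mean FVC %.4f\n",
              x$spec$width, x$spec$height, x$spec$seed, mean_fvc(x$truth_fvc)))
  invisible(x)
}

#' Generate a dated sequence of scenes along a vegetation trend
#'
#' All scenes share the same layout field (so non-vegetation structure is
#' comparable across dates) while the vegetation area follows the given
#' fractions; the non-vegetation classes share the remainder in the base
#' spec's proportions.
#'
#' @param base A [scene_spec()] providing everything but the vegetation
#'   fraction.
#' @param veg_fractions Ordered vegetation fractions in \[0, 1\], one per
#'   date.
#' @return A list of `rgbfvc_scene`s, one per fraction, in order.
#' @export
trend_scenes <- function(base, veg_fractions) {
  if (length(veg_fractions) == 0) abort("veg_fractions is empty")
  if (any(veg_fractions < 0 | veg_fractions > 1)) {
    abort("vegetation fractions must lie in [0, 1]")
  }
  field <- withr::with_seed(base$seed, smooth_field(base$height, base$width, base$smoothness))
  others <- base$class_fractions[setdiff(SCENE_CLASSES, "vegetation")]
  rest <- sum(others)
  lapply(seq_along(veg_fractions), function(i) {
    f <- veg_fractions[i]
    fr <- if (rest > 0) others * (1 - f) / rest else setNames(rep((1 - f) / 4, 4), names(others))
    spec_i <- base
    spec_i$class_fractions <- c(vegetation = unname(f), fr)[SCENE_CLASSES]
    generate_scene_core(spec_i, field, color_seed = base$seed + i)
  })
}
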