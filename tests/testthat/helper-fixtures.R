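# Small in-code fixtures shared across the suite.

# Uniform-color image, channels in native 0-255 units.
flat_rgb <- function(r, g, b, h = 2, w = 2) {
  rgb_image(matrix(r, h, w), matrix(g, h, w), matrix(b, h, w))
}

# Random image with reproducible channels.
random_rgb <- function(h = 16, w = 16, seed = 42) {
  withr::with_seed(seed, {
    rgb_image(
      matrix(runif(h * w, 0, 255), h, w),
      matrix(runif(h * w, 0, 255), h, w),
      matrix(runif(h * w, 0, 255), h, w)
    )
  })
}

# Independent scalar (per-pixel loop) implementations of the seven index
# formulas, used as the oracle against the vectorized path.
scalar_index <- function(index, r, g, b, cive_preset = "literature") {
  switch(index,
    EXG = 2 * g - r - b,
    GRVI = if (g + r == 0) NA_real_ else (g - r) / (g + r),
    EXGR = (2 * g - r - b) - (1.4 * r - g),
    NGBDI = if (g + b == 0) NA_real_ else (g - b) / (g + b),
    CIVE = if (cive_preset == "paper") {
      0.44 * r + 0.88 * g + 0.39 * b + 18.79
    } else {
      0.441 * r - 0.811 * g + 0.385 * b + 18.78745
    },
    RGBVI = if (g^2 + r * b == 0) NA_real_ else (g^2 - r * b) / (g^2 + r * b),
    VDVI = if (g + (r + b) / 2 == 0) NA_real_ else (g - (r + b) / 2) / (g + (r + b) / 2)
  )
}

# Sort-and-count nearest-rank endpoint oracle: walks the sorted values and
# picks the first order statistic whose cumulative pixel share reaches the
# requested fraction.
oracle_endpoints <- function(x, confidence) {
  s <- sort(x)
  n <- length(s)
  pick <- function(q) {
    for (i in seq_len(n)) if (i / n >= q - 1e-15) return(s[i])
    s[n]
  }
  c(lo = pick(confidence), hi = pick(1 - confidence))
}

# Label map where every pixel is the given class code.
constant_labels <- function(code, class_names, h = 10, w = 10, ...) {
  label_map(matrix(as.integer(code), h, w), class_names = class_names, ...)
}

five_classes <- c("1" = "vegetation", "2" = "bare_ground", "3" = "road",
                  "4" = "pond", "5" = "building")
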