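make_index <- function(values, index = "EXG") {
  img <- rgb_image(values * 0, values, values * 0)  # G = values, so EXG = 2*values
  vi <- compute_index(img, "EXG")
  vi$values <- values
  vi$index <- toupper(index)
  vi$polarity <- if (toupper(index) == "CIVE") "decreasing" else "increasing"
  vi
}

test_that("endpoints of 1..100 at 2% confidence are the 2nd and 98th values", {
  vi <- make_index(matrix(1:100, 10, 10))
  ep <- estimate_endpoints(vi, 0.02)
  expect_equal(ep$vi_soil, 2)
  expect_equal(ep$vi_veg, 98)
})

test_that("decreasing polarity swaps the soil and vegetation tails", {
  vi <- make_index(matrix(1:100, 10, 10), "CIVE")
  ep <- estimate_endpoints(vi, 0.02)
  expect_equal(ep$vi_soil, 98)
  expect_equal(ep$vi_veg, 2)
})

test_that("endpoint estimation matches the sort-and-count oracle on random arrays", {
  for (case in 1:6) {
    n <- c(100, 441, 1024, 2500, 7000, 10000)[case]
    conf <- c(0.02, 0.05, 0.02, 0.1, 0.02, 0.3)[case]
    x <- withr::with_seed(1000 + case, rnorm(n))
    side <- ceiling(sqrt(n))
    m <- matrix(NA_real_, side, side)
    m[seq_len(n)] <- x
    vi <- make_index(matrix(0, side, side))
    vi$values <- m
    vi$mask <- !is.na(m)
    ep <- estimate_endpoints(vi, conf)
    o <- oracle_endpoints(x, conf)
    expect_identical(ep$vi_soil, unname(o["lo"]), info = paste("n =", n))
    expect_identical(ep$vi_veg, unname(o["hi"]), info = paste("n =", n))
  }
})

test_that("degenerate distributions and tiny samples are rejected", {
  expect_error(estimate_endpoints(make_index(matrix(5, 10, 10))), "degenerate")
  expect_error(estimate_endpoints(make_index(matrix(1:99, 9, 11)[, 1:9])), "100 valid pixels")
  expect_error(estimate_endpoints(make_index(matrix(1:100, 10, 10)), 0.6), "confidence")
})

test_that("manual endpoint pairs enforce polarity-consistent ordering", {
  expect_error(endpoint_pair(5, 5, "EXG"), "degenerate")
  expect_error(endpoint_pair(10, 2, "EXG"), "ordering")
  expect_error(endpoint_pair(-0.8, 0.1, "CIVE"), "ordering")
  ep <- endpoint_pair(0.105882, -0.819608, "CIVE")
  expect_equal(ep$polarity, "decreasing")
})

test_that("the dimidiate model clamps noise pixels beyond the pure endpoints", {
  ep <- endpoint_pair(0.105882, -0.819608, "CIVE")
  vals <- matrix(c(0.2, -0.9, (0.105882 + -0.819608) / 2, 0.105882), 2, 2)
  vi <- make_index(vals, "CIVE")
  f <- compute_fvc(vi, ep)
  expect_identical(f$values[1, 1], 0)    # above the soil endpoint -> bare
  expect_identical(f$values[2, 1], 1)    # beyond the vegetation endpoint -> full cover
  expect_equal(f$values[1, 2], 0.5)      # affine midpoint
  expect_identical(f$values[2, 2], 0)    # exactly at the soil endpoint
})

test_that("compute_fvc rejects endpoints from a different index", {
  vi <- make_index(matrix(1:100, 10, 10), "EXG")
  expect_error(compute_fvc(vi, endpoint_pair(0, 1, "GRVI")), "mismatch")
})

test_that("the dichotomy is affine-invariant in the index scale", {
  vi <- make_index(matrix(withr::with_seed(7, rnorm(400)), 20, 20))
  ep <- estimate_endpoints(vi, 0.02)
  f1 <- compute_fvc(vi, ep)
  for (ab in list(c(3.5, -2), c(-1.25, 10), c(0.001, 0))) {
    vi2 <- vi
    vi2$values <- ab[1] * vi$values + ab[2]
    ep2 <- endpoint_pair(ab[1] * ep$vi_soil + ab[2], ab[1] * ep$vi_veg + ab[2],
                         if (ab[1] < 0) "CIVE" else "EXG")
    vi2$index <- ep2$index
    vi2$polarity <- ep2$polarity
    f2 <- compute_fvc(vi2, ep2)
    expect_equal(f2$values, f1$values, tolerance = 1e-9)
  }
})

test_that("negating the index and flipping polarity reproduces the FVC map exactly", {
  # size chosen so the confidence cut is strictly between ranks, where the
  # nearest-rank cuts of the two tails mirror each other exactly
  vi <- make_index(matrix(withr::with_seed(11, runif(961, -30, 50)), 31, 31), "EXG")
  f1 <- compute_fvc(vi, estimate_endpoints(vi, 0.02))
  vi2 <- vi
  vi2$values <- -vi$values
  vi2$index <- "CIVE"; vi2$polarity <- "decreasing"
  f2 <- compute_fvc(vi2, estimate_endpoints(vi2, 0.02))
  expect_identical(f1$values, f2$values)
})

test_that("clamping pins at least the confidence share of pixels to each extreme", {
  vi <- make_index(matrix(withr::with_seed(3, rnorm(10000)), 100, 100))
  conf <- 0.02
  f <- compute_fvc(vi, estimate_endpoints(vi, conf))
  v <- f$values[f$mask]
  expect_true(all(v >= 0 & v <= 1))
  expect_gte(mean(v == 0), conf - 1e-3)
  expect_gte(mean(v == 1), conf - 1e-3)
})

test_that("mean_fvc equals a scalar-loop mean over valid pixels", {
  vals <- matrix(withr::with_seed(9, runif(32 * 32)), 32, 32)
  mask <- matrix(withr::with_seed(10, runif(32 * 32) > 0.2), 32, 32)
  vals[!mask] <- NA_real_
  f <- fvc_map(ifelse(mask, vals, 0), mask = mask)
  f$values[!mask] <- NA_real_
  acc <- 0; cnt <- 0
  for (i in 1:32) for (j in 1:32) if (mask[i, j]) { acc <- acc + vals[i, j]; cnt <- cnt + 1 }
  expect_equal(mean_fvc(f), acc / cnt)
  expect_equal(mean_fvc(fvc_map(matrix(0.5, 4, 4))), 0.5)
  expect_equal(mean_fvc(fvc_map(matrix(c(0, 1), 4, 4))), 0.5)
})

test_that("grade boundaries follow the lower-inclusive convention with a zero class", {
  vals <- matrix(c(0, 0.1, 0.2, 0.4, 0.79999, 0.8, 1, 0.5999), 2, 4)
  f <- fvc_map(vals)
  five <- grade_fvc(f, "five_level")
  expect_equal(as.vector(five$grades), c(1L, 1L, 2L, 3L, 4L, 5L, 5L, 3L))
  six <- grade_fvc(f, "six_level")
  expect_equal(as.vector(six$grades), c(0L, 1L, 2L, 3L, 4L, 5L, 5L, 3L))
  # scalar oracle over random values
  v <- withr::with_seed(21, runif(500))
  g <- grade_fvc(fvc_map(matrix(v, 20, 25)), "five_level")$grades
  oracle <- vapply(v, function(x) {
    if (x < 0.2) 1L else if (x < 0.4) 2L else if (x < 0.6) 3L else if (x < 0.8) 4L else 5L
  }, integer(1))
  expect_identical(as.vector(g), oracle)
})

test_that("grade-area fractions tally every grade and sum to one", {
  f <- fvc_map(matrix(c(rep(0.1, 75), rep(0.9, 25)), 10, 10))
  tab <- grade_area_fractions(grade_fvc(f, "five_level"))
  expect_equal(tab$fraction[tab$grade == 1], 0.75)
  expect_equal(tab$fraction[tab$grade == 5], 0.25)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-12)
  # random map vs scalar tally
  v <- withr::with_seed(31, runif(400))
  g <- grade_fvc(fvc_map(matrix(v, 20, 20)), "six_level")
  tab2 <- grade_area_fractions(g)
  expect_equal(sum(tab2$fraction), 1, tolerance = 1e-12)
  for (k in 0:5) {
    expect_equal(tab2$n[tab2$grade == k], sum(g$grades == k), info = paste("grade", k))
  }
  # single-grade map concentrates all area
  tab3 <- grade_area_fractions(grade_fvc(fvc_map(matrix(0.5, 5, 5)), "five_level"))
  expect_equal(tab3$fraction[tab3$grade == 3], 1)
})
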