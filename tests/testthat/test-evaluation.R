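test_that("reference FVC from class counts matches the published worked example", {
  counts <- c(vegetation = 13143311, bare_ground = 1267092, road = 1838215,
              pond = 320001, building = 1257173)
  expect_equal(round(fvc_from_counts(counts), 6), 0.737320)
  expect_equal(fvc_from_counts(c(vegetation = 42)), 1)
  expect_equal(fvc_from_counts(c(vegetation = 0, road = 10)), 0)
  expect_error(fvc_from_counts(c(vegetation = 0, road = 0)), "zero")
  expect_error(fvc_from_counts(c(road = 5)), "vegetation")
})

test_that("reference FVC ignores how non-vegetation classes are split", {
  base <- c(vegetation = 500, bare_ground = 100, road = 200, pond = 50, building = 150)
  merged <- c(vegetation = 500, other = 500)
  permuted <- base[c("pond", "vegetation", "building", "road", "bare_ground")]
  expect_equal(fvc_from_counts(merged), fvc_from_counts(base))
  expect_equal(fvc_from_counts(permuted), fvc_from_counts(base))
})

test_that("class tallies cover all classes and respect the validity mask", {
  lm <- constant_labels(1, five_classes)
  tab <- count_classes(lm)
  expect_equal(tab$n[tab$class == "vegetation"], 100)
  expect_equal(sum(tab$n), 100)
  mask <- matrix(TRUE, 10, 10); mask[1, ] <- FALSE
  lm2 <- constant_labels(2, five_classes, mask = mask)
  tab2 <- count_classes(lm2)
  expect_equal(tab2$n[tab2$class == "bare_ground"], 90)
  expect_equal(sum(tab2$n), 90)
})

test_that("extraction error reproduces the published per-model rows", {
  rows <- list(
    list("EXG", 0.514216, 0.223104, "30.26"),
    list("GRVI", 0.629308, 0.108012, "14.65"),
    list("EXGR", 0.580621, 0.156699, "21.25"),
    list("NGBDI", 0.434810, 0.302510, "41.03"),
    list("RGBVI", 0.509429, 0.227891, "30.91"),
    list("VDVI", 0.570686, 0.166634, "22.60"),
    list("CIVE", 0.750179, 0.012859, "1.74")
  )
  fi <- 0.737320
  for (r in rows) {
    rep <- extraction_error(fi, r[[2]])
    expect_equal(rep$difference, r[[3]], tolerance = 1e-9, info = r[[1]])
    expect_equal(sprintf("%.2f", rep$ec), r[[4]], info = r[[1]])
  }
  expect_equal(extraction_error(0.5, 0.5)$ec, 0)
  expect_error(extraction_error(0, 0.5), "positive")
})

test_that("extraction error is scale-free in the cover units", {
  rep1 <- extraction_error(0.7, 0.6)
  rep2 <- extraction_error(0.7 * 3, 0.6 * 3)
  expect_equal(rep1$ec, rep2$ec)
})

test_that("model comparison ranks by extraction error with stable ties", {
  fv <- c(EXG = 0.514216, GRVI = 0.629308, EXGR = 0.580621, NGBDI = 0.434810,
          RGBVI = 0.509429, VDVI = 0.570686, CIVE = 0.750179)
  tab <- compare_models(0.737320, fv)
  expect_equal(tab$model[1], "CIVE")
  expect_equal(tab$rank, 1:7)
  expect_equal(tab$ec, sort(tab$ec))
  # equidistant models above/below the reference tie; canonical order breaks the tie
  tie <- compare_models(0.5, c(VDVI = 0.4, GRVI = 0.6))
  expect_equal(tie$ec[1], tie$ec[2])
  expect_equal(tie$model, c("GRVI", "VDVI"))
  one <- compare_models(0.5, c(only = 0.5))
  expect_equal(nrow(one), 1)
  expect_equal(one$ec, 0)
  expect_error(compare_models(0.5, numeric(0)), "no model")
})

test_that("identical maps give perfect agreement", {
  lm <- label_map(matrix(rep(1:5, 20), 10, 10), five_classes)
  ag <- agreement(lm, lm)
  s <- glance(ag)
  expect_equal(s$overall_accuracy, 1)
  expect_equal(s$kappa, 1)
})

test_that("kappa matches the hand-worked confusion example", {
  # reference rows: [[40, 10], [20, 30]] -> p_o = 0.7, p_e = 0.5, kappa = 0.4
  s <- agreement_stats(matrix(c(40, 20, 10, 30), 2, 2))
  expect_equal(s$overall_accuracy, 0.7)
  expect_equal(s$expected_accuracy, 0.5)
  expect_equal(s$kappa, 0.4)
})

test_that("a constant prediction against a balanced reference scores kappa zero", {
  ref <- label_map(matrix(rep(c(1L, 2L), 50), 10, 10),
                   c("1" = "vegetation", "2" = "bare_ground"))
  prd <- constant_labels(1, c("1" = "vegetation", "2" = "bare_ground"))
  s <- glance(agreement(ref, prd))
  expect_equal(s$overall_accuracy, 0.5)
  expect_equal(s$kappa, 0)
})

test_that("kappa never exceeds overall accuracy on random confusion matrices", {
  for (s in 1:25) {
    conf <- withr::with_seed(4000 + s, {
      k <- sample(2:5, 1)
      matrix(rpois(k * k, lambda = sample(1:50, 1)), k, k)
    })
    if (sum(conf) == 0) next
    st <- agreement_stats(conf)
    if (!is.na(st$kappa)) {
      expect_lte(st$kappa, st$overall_accuracy + 1e-12)
    }
  }
})

test_that("confusion margins equal the per-map class tallies", {
  ref <- label_map(matrix(withr::with_seed(8, sample(1:5, 100, TRUE)), 10, 10), five_classes)
  prd <- label_map(matrix(withr::with_seed(9, sample(1:5, 100, TRUE)), 10, 10), five_classes)
  ag <- agreement(ref, prd)
  ref_tab <- count_classes(ref); prd_tab <- count_classes(prd)
  expect_equal(unname(rowSums(ag$confusion)[ref_tab$class]), ref_tab$n)
  expect_equal(unname(colSums(ag$confusion)[prd_tab$class]), prd_tab$n)
  expect_equal(sum(tidy(ag)$n), 100)
})

test_that("agreement with a sparse sample map uses only jointly valid pixels", {
  full <- label_map(matrix(rep(1:5, 20), 10, 10), five_classes)
  mask <- matrix(FALSE, 10, 10); mask[1, 1:5] <- TRUE
  sample_map <- label_map(full$labels, five_classes, mask = mask)
  ag <- agreement(sample_map, full)
  expect_equal(glance(ag)$n, 5)
  expect_equal(glance(ag)$overall_accuracy, 1)
  expect_error(agreement(full, constant_labels(1, five_classes, h = 5, w = 5)),
               "dimensions")
})

test_that("kappa is undefined when both maps are the same constant", {
  lm <- constant_labels(1, five_classes)
  s <- glance(agreement(lm, lm))
  expect_equal(s$overall_accuracy, 1)
  expect_true(is.na(s$kappa))
})
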