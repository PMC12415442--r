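# Codebook, mask quantification, case aggregation, dominant/secondary.

test_that("codebook encodes the tier and severity structure", {
  cb <- pattern_codebook()
  expect_equal(nrow(cb), 6)
  expect_false(anyDuplicated(cb$code) > 0)
  tiers3 <- setNames(cb$tier3, cb$name)
  expect_equal(tiers3[["lepidic"]], 1)
  expect_equal(unname(tiers3[c("acinar", "papillary")]), c(2, 2))
  expect_equal(unname(tiers3[c("micropapillary", "solid",
                               "complex_glandular")]), c(3, 3, 3))
  tiers4 <- setNames(cb$tier4, cb$name)
  expect_equal(tiers4[["complex_glandular"]], 3)
  expect_equal(unname(tiers4[c("micropapillary", "solid")]), c(4, 4))
  expect_equal(severity_order(),
               c("lepidic", "acinar", "papillary", "complex_glandular",
                 "micropapillary", "solid"))
})

test_that("correction weights default to the calibrated values", {
  w <- correction_weights()
  expect_equal(unname(w[c("lepidic", "acinar", "papillary",
                          "micropapillary", "solid", "complex_glandular")]),
               c(1.41, 1.35, 1.06, 1.14, 1.0, 1.10))
  expect_error(correction_weights(lepidic = 0), "positive")
})

test_that("quantify_mask matches hand arithmetic", {
  cb <- pattern_codebook()
  # single-class mask: 10 000 solid pixels
  m <- label_mask(matrix(5L, 100, 100))
  sc <- quantify_mask(m, cb)
  expect_equal(unname(sc$pct["solid"]), 100)
  expect_equal(unname(sc$weighted_area["solid"]), 10000 * 1.0)
  expect_equal(sum(sc$pct), 100)
  # 1000 lepidic + 1000 solid: weighted 1410 vs 1000
  m2 <- label_mask(matrix(c(rep(1L, 1000), rep(5L, 1000)), 40, 50))
  sc2 <- quantify_mask(m2, cb)
  expect_equal(unname(sc2$weighted_area[c("lepidic", "solid")]),
               c(1410, 1000))
  expect_equal(unname(sc2$pct["lepidic"]), 100 * 1410 / 2410)
  expect_equal(unname(sc2$pct["solid"]), 100 * 1000 / 2410)
  # 500 px of each pattern: pct proportional to the weights
  m3 <- label_mask(matrix(rep(1:6, each = 500), 50, 60))
  sc3 <- quantify_mask(m3, cb)
  wsum <- 1.41 + 1.35 + 1.06 + 1.14 + 1.0 + 1.10
  expect_equal(unname(sc3$pct["lepidic"]), 100 * 1.41 / wsum,
               tolerance = 1e-12)
  expect_equal(sc3$raw_pixels, setNames(rep(500L, 6),
               c("lepidic", "acinar", "papillary", "micropapillary",
                 "solid", "complex_glandular")), ignore_attr = TRUE)
})

test_that("quantify_mask handles background, bad codes, units", {
  cb <- pattern_codebook()
  m <- label_mask(matrix(c(0L, 0L, 2L, 2L), 2, 2))
  sc <- quantify_mask(m, cb)
  expect_equal(sc$background_pixels, 2)
  expect_equal(unname(sc$pct["acinar"]), 100)
  expect_error(quantify_mask(label_mask(matrix(9L, 2, 2)), cb), "9")
  empty <- quantify_mask(label_mask(matrix(0L, 4, 4)), cb)
  expect_true(empty$empty)
  expect_equal(sum(empty$pct), 0)
  # mm2 conversion: mpp 0.5 -> pixel area (0.5/1000)^2 mm2
  mm <- quantify_mask(label_mask(matrix(5L, 10, 10), mpp = 0.5), cb)
  expect_equal(unname(mm$weighted_area["solid"]), 100 * (0.5 / 1000)^2)
  expect_equal(mm$unit, "mm2")
})

test_that("weight identity and pixel-permutation invariance hold", {
  cb <- pattern_codebook()
  set.seed(7)
  for (rep_ in 1:5) {
    v <- sample(0:6, 400, replace = TRUE)
    m <- label_mask(matrix(v, 20, 20))
    sc <- quantify_mask(m, cb, unit_weights())
    raw <- sc$raw_pixels
    expect_equal(sc$pct[raw > 0], 100 * raw[raw > 0] / sum(raw))
    expect_equal(sum(raw) + sc$background_pixels, 400)
    perm <- label_mask(matrix(sample(v), 20, 20))
    expect_equal(quantify_mask(perm, cb)$pct, quantify_mask(m, cb)$pct)
  }
})

test_that("case aggregation pools areas, not slide percentages", {
  cb <- pattern_codebook()
  mk <- function(pat_code, n) quantify_mask(
    label_mask(matrix(pat_code, 1, n)), cb, unit_weights())
  # 9000 acinar-units vs 1000 solid-units -> 90/10, dominant acinar
  cc <- aggregate_case(list(mk(2L, 9000), mk(5L, 1000)), "c1")
  expect_equal(unname(cc$pct[c("acinar", "solid")]), c(90, 10))
  expect_equal(cc$dominant, "acinar")
  expect_equal(cc$secondary, "solid")
  # singleton and duplicated-slide symmetry
  one <- mk(3L, 500)
  expect_equal(aggregate_case(list(one), "c2")$pct, one$pct)
  expect_equal(aggregate_case(list(one, one), "c3")$pct, one$pct)
  # n copies equal the single slide
  sc <- quantify_mask(label_mask(matrix(c(1L, 2L, 5L, 5L), 2, 2)), cb)
  many <- aggregate_case(rep(list(sc), 5), "c4")
  expect_equal(many$pct, sc$pct)
  # unit mismatch is an error
  mm <- quantify_mask(label_mask(matrix(2L, 2, 2), mpp = 0.5), cb)
  expect_error(aggregate_case(list(one, mm), "c5"), "unit mismatch")
})

test_that("dominant/secondary resolution follows the rules", {
  expect_equal(dominant_secondary(c(acinar = 60, lepidic = 40))[1:2],
               list(dominant = "acinar", secondary = "lepidic"))
  # proxy when nothing reaches the 5% floor
  ds <- dominant_secondary(c(acinar = 97, solid = 3))
  expect_equal(ds$secondary, "acinar")
  expect_true(ds$secondary_is_proxy)
  # exact 5% qualifies (floor is >=)
  ds5 <- dominant_secondary(c(acinar = 95, solid = 5))
  expect_equal(ds5$secondary, "solid")
  expect_false(ds5$secondary_is_proxy)
  # ties break toward higher severity: solid > micropapillary
  tie <- dominant_secondary(c(micropapillary = 50, solid = 50))
  expect_equal(tie$dominant, "solid")
  expect_equal(tie$secondary, "micropapillary")
  expect_error(dominant_secondary(c(acinar = 0)), "empty")
})
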