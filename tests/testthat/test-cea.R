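test_that("the ICER reproduces the published per-unit costs", {
  # euros per ACT point gained
  expect_equal(round(icer(11544, 14043, 13.71, 21.33), 2), 327.95)
  # euros per severe exacerbation avoided (effectiveness = avoided count)
  expect_equal(round(icer(10292, 13204, 0, 5.50 - 0.66)), 602)
  # free gain
  expect_equal(icer(100, 100, 1, 3), 0)
  # undefined ratio: NA plus a pointer to net benefit, never infinity
  expect_warning(res <- icer(100, 300, 2, 2), "nmb")
  expect_true(is.na(res))
})

test_that("k-point and fractional-effect costs match the published table", {
  expect_equal(round(cost_per_k_points(11544, 14043, 13.71, 21.33, 3), 2),
               983.86)
  expect_equal(round(cost_per_k_points(11544, 14043, 13.71, 21.33, 7), 2),
               2295.67)
  expect_equal(cost_per_k_points(11544, 14043, 13.71, 21.33, 0), 0)
  expect_equal(round(cer_fractional(2912, 0.8814)), 3304)
  expect_equal(cer_fractional(2912, 1), 2912)
  # printed 8201 stems from unrounded means; printed-rate inputs give 8199
  expect_equal(round(cer_fractional(2499, 0.3048)), 8199)
  expect_error(cer_fractional(100, 0), "\\(0, 1\\]")
  expect_error(cer_fractional(100, 1.2), "\\(0, 1\\]")
})

test_that("net monetary and net health benefit match the worked example", {
  expect_equal(nmb(0.138, 2499, 24000), 813)
  expect_equal(round(nhb(0.138, 2499, 24000), 3), 0.034)
  expect_equal(nmb(0.138, 2499, 22000), 0.138 * 22000 - 2499)
  expect_equal(nmb(0, 0, 5000), 0)
  expect_error(nmb(1, 1, 0), "> 0")
  expect_error(nhb(1, 1, -5), "> 0")
})

test_that("NHB equals NMB/WTP and NMB sign agrees with ICER vs WTP", {
  set.seed(7)
  for (i in 1:500) {
    de <- runif(1, -2, 2); dc <- runif(1, -5e4, 5e4); w <- runif(1, 1, 1e5)
    expect_equal(nhb(de, dc, w), nmb(de, dc, w) / w, tolerance = 1e-12)
    if (de > 0) {
      expect_equal(nmb(de, dc, w) > 0, dc / de < w)
    }
  }
})

test_that("ICER is translation-invariant in costs and scales linearly", {
  base <- icer(1000, 3000, 1, 3)
  expect_equal(icer(1000 + 500, 3000 + 500, 1, 3), base)
  expect_equal(icer(2 * 1000, 2 * 3000, 1, 3), 2 * base)
})

test_that("plane quadrants partition every sign combination", {
  q <- plane_quadrant(0.138, 2499)
  expect_equal(q$quadrant, "NE")
  expect_equal(q$decision, "trade-off")
  expect_equal(plane_quadrant(1, -1)$decision, "dominant")
  expect_equal(plane_quadrant(-1, 1)$decision, "dominated")
  expect_equal(plane_quadrant(-1, -1)$quadrant, "SW")
  # axis tie-breaks
  expect_equal(plane_quadrant(0, -1)$decision, "dominant")
  expect_equal(plane_quadrant(0, 1)$decision, "dominated")
  expect_equal(plane_quadrant(1, 0)$decision, "dominant")
  expect_equal(plane_quadrant(-1, 0)$decision, "dominated")
  expect_equal(plane_quadrant(0, 0)$decision, "equivalent")
  # exhaustive and single-valued over a sign grid
  g <- expand.grid(de = c(-1, 0, 1), dc = c(-1, 0, 1))
  labs <- plane_quadrant(g$de, g$dc)
  expect_false(any(is.na(labs$quadrant)))
  expect_true(all(labs$decision %in%
                    c("trade-off", "dominant", "dominated", "equivalent")))
})

test_that("ce_result bundles the full decision summary and serialises", {
  res <- ce_result(11544, 14043, 0.729, 0.867, wtp = 24000,
                   measure = "utility")
  expect_equal(res$delta_cost, 2499)
  expect_equal(res$delta_eff, 0.138)
  expect_equal(res$nmb, 813)
  expect_equal(res$quadrant, "NE")
  js <- jsonlite::fromJSON(ce_result_json(res))
  expect_equal(js$nmb, 813)
  expect_equal(js$measure, "utility")
})
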