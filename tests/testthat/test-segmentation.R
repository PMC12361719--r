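test_that("slices map to the nearest reference level with posterior ties", {
  rt <- defaultRuleTable()
  expect_equal(sliceRuleLevel(9.1, rt), 9)
  expect_equal(sliceRuleLevel(7.8, rt), 7)
  expect_equal(sliceRuleLevel(3.25, rt), 2.5)  # 0.75 tie with 4 -> posterior
  expect_equal(sliceRuleLevel(10.4, rt), 10)
  expect_error(sliceRuleLevel(1.0, rt), class = "mtlseg_range")
  expect_error(sliceRuleLevel(12.0, rt), class = "mtlseg_range")
})

## Golden protocol tests: engine intervals on the fixture slice per
## column of the placement table, against hand-derived positions
## (fixture landmarks: PHG edge 13, crown mid 16, CS medial edge 19,
## medial-bank half 21.5, fundus 24, lateral-bank quarter 25.25,
## fundus-FG mid 28.5, FG crown mid 33).
test_that("engine output matches hand-derived intervals for every protocol column", {
  rt <- defaultRuleTable()
  golden <- list(
    list(d = 10.4, presence = "BA36",
         iv = makeIntervals(10.4, 21.5, 25.25, "BA36")),
    list(d = 9.1, presence = c("BA35", "BA36"),
         iv = rbind(makeIntervals(9.1, 6, 24, "BA35"),
                    makeIntervals(9.1, 24, 28.5, "BA36"))),
    list(d = 7.8, presence = c("BA35", "BA36"),
         iv = rbind(makeIntervals(7.8, 3, 24, "BA35"),
                    makeIntervals(7.8, 24, 33, "BA36"))),
    list(d = 5.2, presence = c("ERC", "BA35", "BA36"),
         iv = rbind(makeIntervals(5.2, 8, 16, "BA35", "medial_flank"),
                    makeIntervals(5.2, 16, 19, "ERC"),
                    makeIntervals(5.2, 19, 24, "BA35"),
                    makeIntervals(5.2, 24, 33, "BA36"))),
    list(d = 3.9, presence = c("ERC", "BA35", "BA36"),
         iv = rbind(makeIntervals(3.9, 13, 19, "ERC"),
                    makeIntervals(3.9, 19, 24, "BA35"),
                    makeIntervals(3.9, 24, 33, "BA36"))),
    list(d = 2.6, presence = c("ERC", "BA35", "BA36"),
         iv = rbind(makeIntervals(2.6, 13, 19, "ERC"),
                    makeIntervals(2.6, 19, 24, "BA35"),
                    makeIntervals(2.6, 24, 33, "BA36")))
  )
  for (g in golden) {
    lm <- fixtureLandmarks(g$d)
    got <- applyRulesSlice(lm, g$d, rt, g$presence)
    expect_equal(got, g$iv, ignore_attr = TRUE)
  }
})

test_that("segmentCase labels the protocol slice runs per region", {
  rt <- defaultRuleTable()
  coh <- generateCohort(cohortConfigFromRules(rt, n_cases = 1, seed = 12))
  stack <- cohortStacks(coh)[[1]]
  map <- segmentCase(stack, rt)
  iv <- labelIntervals(map)
  slices_of <- function(lab)
    sort(unique(iv$slice_distance_mm[iv$label == lab]))
  expect_equal(slices_of("ERC"), c(2.6, 3.9, 5.2))
  expect_equal(slices_of("BA35"), c(2.6, 3.9, 5.2, 6.5, 7.8, 9.1))
  expect_equal(slices_of("BA36"), c(2.6, 3.9, 5.2, 6.5, 7.8, 9.1, 10.4))
  ## determinism
  expect_equal(labelIntervals(segmentCase(stack, rt)), iv)
})

test_that("a stack missing a protocol slice raises a gap error naming it", {
  rt <- defaultRuleTable()
  coh <- generateCohort(cohortConfigFromRules(rt, n_cases = 1, seed = 12))
  stack <- cohortStacks(coh)[[1]]
  dd <- vapply(stack, sliceDistance, numeric(1))
  broken <- stack[abs(dd - 6.5) > 1e-6]
  expect_error(segmentCase(broken, rt), "6.5", class = "mtlseg_gap")
})

test_that("each slice is partitioned: adjacent labels share borders exactly, no gaps", {
  rt <- defaultRuleTable()
  coh <- generateCohort(cohortConfigFromRules(rt, n_cases = 4, seed = 14))
  for (map in segmentCohort(coh, rt)) {
    iv <- labelIntervals(map)
    for (d in unique(iv$slice_distance_mm)) {
      s <- iv[iv$slice_distance_mm == d, ]
      s <- s[order(s$s_start), ]
      if (nrow(s) > 1)
        expect_identical(s$s_start[-1], s$s_end[-nrow(s)])
    }
  }
})

test_that("each region's labeled slices form a contiguous posterior-anchored run", {
  rt <- defaultRuleTable()
  coh <- generateCohort(cohortConfigFromRules(rt, n_cases = 3, seed = 15))
  th <- rt@sliceThickness
  for (map in segmentCohort(coh, rt)) {
    iv <- labelIntervals(map)
    for (lab in unique(iv$label)) {
      dd <- sort(unique(iv$slice_distance_mm[iv$label == lab]))
      expect_equal(dd[1], rt@posteriorBound)
      if (length(dd) > 1)
        expect_equal(diff(dd), rep(th, length(dd) - 1))
    }
  }
})

test_that("engine reproduces zero-noise ground truth with DSI 1 for every label", {
  rt <- defaultRuleTable()
  coh <- generateCohort(cohortConfigFromRules(rt, n_cases = 5, seed = 16))
  maps <- segmentCohort(coh, rt)
  for (cid in names(maps)) {
    tl <- truthLabelMap(coh, cid, posterior_bound_mm = rt@posteriorBound)
    for (lab in c("ERC", "BA35", "BA36"))
      expect_equal(as.numeric(dsi(maps[[cid]], tl, lab)), 1.0)
  }
})

test_that("borders walking off the contour clamp to the terminus with a warning", {
  rt <- defaultRuleTable()
  rules <- rt@rules
  rules$offset_mm[rules$level == 9 & rules$region == "BA35" &
                    rules$side == "medial"] <- 100
  rt2 <- ruleTable(rt@sliceThickness, rt@anchor, rt@starts, rt@levels,
                   rules, rt@flank, rt@posteriorBound)
  lm <- fixtureLandmarks(9.1)
  expect_warning(
    got <- applyRulesSlice(lm, 9.1, rt2, c("BA35", "BA36")),
    class = "mtlseg_border_clamped")
  expect_equal(got$s_start[got$label == "BA35"], 0)
})

test_that("inverted intervals raise a degenerate-slice error naming the label", {
  rt <- defaultRuleTable()
  rules <- rt@rules
  ## push the ERC medial border lateral of the ERC lateral border
  k <- rules$level == 5 & rules$region == "ERC" & rules$side == "medial"
  rules$offset_mm[k] <- 10
  rules$direction[k] <- "lateral"
  rt2 <- ruleTable(rt@sliceThickness, rt@anchor, rt@starts, rt@levels,
                   rules, rt@flank[0, ], rt@posteriorBound)
  lm <- fixtureLandmarks(5.2)
  expect_error(applyRulesSlice(lm, 5.2, rt2, c("ERC", "BA35", "BA36")),
               "ERC", class = "mtlseg_degenerate_slice")
})

test_that("rasterization matches the area-count oracle and paints disjoint bands", {
  ## straight 10 mm interval on a long flat crown, 1 mm ribbon, 0.5 mm
  ## voxels: expected count = length * ribbon / res^2 = 40
  pts <- rbind(c(-2, -13), c(-2, -6), c(0, 0), c(6, 0), c(10, -3),
               c(14, 0), c(18, 0), c(40, 0))
  kv <- c(medial_terminus = 1L, phg_superior_edge = 3L,
          cs_medial_mouth = 4L, cs_fundus = 5L, cs_lateral_mouth = 6L,
          fg_crown_apex = 7L, lateral_terminus = 8L)
  ct <- SliceContour("fix", 2.6, pts, kv)
  cum <- arcLengthPositions(ct)
  s0 <- cum[7]  # FG crown apex: flat straight stretch begins here
  lmap <- LabelMap("fix", makeIntervals(2.6, s0, s0 + 10, "ERC"))
  ras <- rasterizeLabels(lmap, list(ct), 0.5, 1)
  n_erc <- sum(ras$array == 1)
  oracle <- 10 * 1 / 0.5^2
  expect_lt(abs(n_erc - oracle), 0.15 * oracle + 4)

  ## empty label map -> all-zero volume
  empty <- LabelMap("fix", makeIntervals(2.6, 1, 2, "ERC")[0, ])
  expect_true(all(rasterizeLabels(empty, list(ct), 0.5, 1)$array == 0))

  ## two adjacent intervals: no voxel is labeled by both (single
  ## assignment), and both labels appear
  two <- LabelMap("fix", rbind(makeIntervals(2.6, s0, s0 + 5, "ERC"),
                               makeIntervals(2.6, s0 + 5, s0 + 10, "BA35")))
  r2 <- rasterizeLabels(two, list(ct), 0.5, 1)
  expect_gt(sum(r2$array == 1), 0)
  expect_gt(sum(r2$array == 2), 0)
  counts <- sum(r2$array > 0)
  expect_equal(sum(r2$array == 1) + sum(r2$array == 2), counts)

  expect_warning(rasterizeLabels(lmap, list(ct), 2, 1),
                 class = "mtlseg_resolution")
  expect_error(rasterizeLabels(lmap, list(ct), 0), class = "mtlseg_domain")
})
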