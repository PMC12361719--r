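## Helper: StatsRow tables assembled from the printed protocol medians
## (extent medians 4.75 / 9.25 / 10.25 mm; BA35 medial offsets 7.19,
## 9.96, -5.40 mm), with the remaining landmark cells at their measured
## near-zero medians.
printedExtentStats <- function() {
  data.frame(
    region = rep(c("ERC", "BA35", "BA36"), times = 5),
    anchor = rep(c("hippocampus", "amygdala", "temporal_pole",
                   "limen_insulae", "collateral_sulcus"), each = 3),
    n = 20,
    mean = NA_real_,
    median = c(4.75, 9.25, 10.25, 1.25, 5.75, 7.50, 21.75, 15.50, 15.00,
               0.75, -4.00, -5.25, 14.80, 9.20, 7.05),
    sd = c(1.58, 2.60, 3.84, 1.46, 2.47, 3.83, 2.22, 3.27, 3.81,
           1.93, 2.53, 3.88, 4.36, 4.43, 5.28),
    stringsAsFactors = FALSE)
}

printedDistanceStats <- function() {
  row <- function(region, side, segment, landmark, level, median)
    data.frame(region = region, side = side, segment = segment,
               landmark = landmark, slice_level = as.character(level),
               n = 20, n_absent = 0, mean = NA_real_, median = median,
               sd = NA_real_, stringsAsFactors = FALSE)
  rbind(
    row("ERC", "medial", "primary", "s_phg_crown_midpoint", 5, 0.92),
    row("ERC", "medial", "primary", "s_phg_superior_edge", 5, -2.38),
    row("ERC", "medial", "primary", "s_phg_superior_edge", 4, -3.11),
    row("ERC", "medial", "primary", "s_phg_superior_edge", 2.5, -1.33),
    row("ERC", "lateral", "primary", "s_cs_medial_edge", 5, -1.85),
    row("ERC", "lateral", "primary", "s_cs_medial_edge", 4, -0.88),
    row("ERC", "lateral", "primary", "s_cs_medial_edge", 2.5, -2.44),
    row("BA35", "medial", "primary", "s_phg_superior_edge", 9, 7.19),
    row("BA35", "medial", "primary", "s_phg_superior_edge", 7, 9.96),
    row("BA35", "medial", "medial_flank", "s_phg_superior_edge", 5, -5.40),
    row("BA35", "lateral", "primary", "s_cs_fundus", 9, 0.00),
    row("BA35", "lateral", "primary", "s_cs_fundus", 7, 0.00),
    row("BA35", "lateral", "primary", "s_cs_fundus", 5, 0.30),
    row("BA35", "lateral", "primary", "s_cs_fundus", 4, 0.86),
    row("BA35", "lateral", "primary", "s_cs_fundus", 2.5, 0.81),
    row("BA36", "medial", "primary", "s_medial_bank_half", 10, 0.00),
    row("BA36", "lateral", "primary", "s_lateral_bank_quarter", 10, 1.86),
    row("BA36", "lateral", "primary", "s_fundus_fg_midpoint", 9, 0.00),
    row("BA36", "lateral", "primary", "s_fg_crown_midpoint", 7, 0.00),
    row("BA36", "lateral", "primary", "s_fg_crown_midpoint", 5, 0.00),
    row("BA36", "lateral", "primary", "s_fg_crown_midpoint", 4, 0.00),
    row("BA36", "lateral", "primary", "s_fg_crown_midpoint", 2.5, 0.00))
}

test_that("distance summaries use sample SD and midpoint medians", {
  rec <- data.frame(region = "BA35", side = "medial", segment = "primary",
                    landmark = "s_phg_superior_edge", slice_level = "9",
                    distance_mm = c(1, 2, 3), absent = FALSE)
  s <- summarizeDistances(rec)
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$sd, 1)
  rec0 <- rec[c(1, 1, 1, 1), ]
  rec0$distance_mm <- 0
  expect_equal(summarizeDistances(rec0)$sd, 0)
  ## even n: midpoint of the central pair
  rec4 <- rec[c(1, 1, 1, 1), ]
  rec4$distance_mm <- c(1, 2, 4, 10)
  expect_equal(summarizeDistances(rec4)$median, 3)
})

test_that("grid quantization reproduces nearest multiples with away-from-zero ties", {
  expect_equal(quantizeToGrid(4.75, 1.3), 5.2)
  expect_equal(quantizeToGrid(9.25, 1.3), 9.1)
  expect_equal(quantizeToGrid(10.25, 1.3), 10.4)
  expect_equal(quantizeToGrid(1.95, 1.3), 2.6)  # exact half-grid tie, up
  expect_error(quantizeToGrid(-1, 1.3), class = "mtlseg_domain")
  expect_error(quantizeToGrid(5, 0), class = "mtlseg_domain")
  ## property: exact multiple, and never further than half a slice
  set.seed(1)
  m <- runif(200, 0.1, 20)
  th <- runif(200, 0.3, 2)
  q <- mapply(quantizeToGrid, m, th)
  expect_true(all(abs(q / th - round(q / th)) < 1e-9))
  expect_true(all(abs(q - m) <= th / 2 + 1e-9))
})

test_that("offset rounding keeps the magnitude with away-from-zero ties", {
  expect_equal(roundOffset(9.96), 10)
  expect_equal(roundOffset(7.19), 7)
  expect_equal(roundOffset(-5.40), 5)
  expect_equal(roundOffset(2.5), 3)
  expect_equal(roundOffset(-2.5), 3)
  expect_error(roundOffset(NA_real_), class = "mtlseg_domain")
})

test_that("anchor selection prefers the identifiable anchor among the two lowest-SD candidates", {
  es <- printedExtentStats()
  sel <- selectAnchor(es)
  expect_equal(sel$anchor, "hippocampus")
  ## the amygdala ranks first on SD alone
  expect_equal(sel$ranking$anchor[1], "amygdala")
  expect_equal(sel$ranking$anchor[2], "hippocampus")

  ## dominance: two anchors, both easy, first clearly better
  es2 <- data.frame(region = rep(c("ERC", "BA35", "BA36"), 2),
                    anchor = rep(c("a1", "a2"), each = 3),
                    n = 5, mean = NA, median = 5,
                    sd = rep(c(1, 9), each = 3))
  sel2 <- selectAnchor(es2, identifiability = c(a1 = "easy", a2 = "easy"))
  expect_equal(sel2$anchor, "a1")

  ## selection is invariant to input row order
  set.seed(3)
  es_perm <- es[sample(nrow(es)), ]
  expect_equal(selectAnchor(es_perm)$anchor, "hippocampus")
  expect_equal(selectAnchor(es_perm)$ranking$anchor,
               sel$ranking$anchor)

  ## all-hard: best SD anchor with a warning
  hard <- setNames(rep("hard", 5), unique(es$anchor))
  expect_warning(sel3 <- selectAnchor(es, identifiability = hard),
                 class = "mtlseg_anchor")
  expect_equal(sel3$anchor, "amygdala")

  expect_error(selectAnchor(es[es$anchor == "hippocampus", ]),
               class = "mtlseg_input")
})

test_that("the printed medians reproduce the published rule table", {
  drt <- deriveRuleTable(printedDistanceStats(), printedExtentStats())
  expect_equal(drt@anchor, "hippocampus")
  expect_equal(ruleStarts(drt), c(ERC = 5.2, BA35 = 9.1, BA36 = 10.4))
  expect_true(isTRUE(rulesEqual(drt, defaultRuleTable())))
  ## the three offset-bearing cells carry 7, 10 and 5 mm
  off <- drt@rules[drt@rules$region == "BA35" & drt@rules$side == "medial" &
                     !is.na(drt@rules$landmark), ]
  expect_equal(off$offset_mm[order(-off$level)], c(7, 10))
  expect_equal(drt@flank$offset_mm, 5)
  expect_true(all(off$direction == "medial"))
})

test_that("derivation errors name the missing cell", {
  ds <- printedDistanceStats()
  ds <- ds[!(ds$region == "BA35" & ds$side == "medial" &
               ds$slice_level == "7"), ]
  expect_error(deriveRuleTable(ds, printedExtentStats()),
               "BA35 medial", class = "mtlseg_derivation")
  es <- printedExtentStats()
  es <- es[es$anchor != "hippocampus", ]
  expect_error(deriveRuleTable(printedDistanceStats(), es,
                               anchor = "hippocampus"),
               class = "mtlseg_derivation")
})

test_that("measured direction policy flips the sign-conflicted cells", {
  drt <- deriveRuleTable(printedDistanceStats(), printedExtentStats(),
                         direction_policy = "measured")
  off <- drt@rules[drt@rules$region == "BA35" & drt@rules$side == "medial" &
                     !is.na(drt@rules$landmark), ]
  ## positive printed medians at the 9 and 7 mm levels become lateral
  expect_true(all(off$direction == "lateral"))
  ## the flank median is negative, so it stays medial
  expect_equal(drt@flank$direction, "medial")
})

test_that("rule derivation round-trips a zero-noise rule-generated cohort", {
  rt <- defaultRuleTable()
  coh <- generateCohort(cohortConfigFromRules(rt, n_cases = 6, seed = 17))
  m <- measureCohort(coh)
  drt <- deriveRuleTable(summarizeDistances(m$distances),
                         summarizeExtents(m$extents))
  expect_true(isTRUE(rulesEqual(rt, drt)))
})

test_that("derived offsets stay within 1 mm of generator truth under 2 mm noise", {
  rt <- defaultRuleTable()
  cfg <- cohortConfigFromRules(rt, n_cases = 200, seed = 11,
                               border_sd_mm = 2)
  coh <- suppressWarnings(generateCohort(cfg))
  m <- measureCohort(coh)
  drt <- deriveRuleTable(summarizeDistances(m$distances),
                         summarizeExtents(m$extents))
  truth <- rt@rules$offset_mm
  derived <- drt@rules$offset_mm
  expect_true(all(abs(derived - truth) <= 1))
  expect_true(all(abs(drt@flank$offset_mm - rt@flank$offset_mm) <= 1))
  expect_equal(ruleStarts(drt), ruleStarts(rt))
})

test_that("generator SD structure lets anchor selection recover the hippocampus", {
  coh <- generateCohort(cohortConfig(n_cases = 150, seed = 19),
                        contours = FALSE)
  recs <- do.call(rbind, lapply(cohortCases(coh), function(cs) {
    do.call(rbind, lapply(names(cs@anchors), function(a)
      data.frame(case_id = cs@caseId, region = rep(c("ERC", "BA35",
                                                     "BA36")),
                 anchor = a,
                 distance_mm = vapply(c("ERC", "BA35", "BA36"),
                                      function(r)
                                        anteriorExtentDistance(cs, r, a),
                                      numeric(1)))))
  }))
  es <- summarizeExtents(recs)
  sel <- selectAnchor(es)
  ## amygdala has the lowest summed SD (it tracks the shared extent
  ## component) but is hard to identify, so the hippocampus is chosen
  expect_equal(sel$ranking$anchor[1], "amygdala")
  expect_equal(sel$anchor, "hippocampus")
})
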