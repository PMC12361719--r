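## Fixtures built in code: a hand-computable contour whose arc-length
## positions are exact integers, and small helpers shared across tests.

## Straight-segment contour: vertex arc positions 0, 7, 13, 19, 24, 29,
## 33, 37 mm; landmark positions (hand-derived):
##   s_phg_superior_edge 13, s_phg_crown_midpoint 16, s_cs_medial_edge 19,
##   s_medial_bank_half 21.5, s_cs_fundus 24, s_lateral_bank_quarter 25.25,
##   s_fundus_fg_midpoint 28.5, s_fg_crown_midpoint 33; CS depth 3 mm.
fixtureContour <- function(case_id = "fix", slice_distance_mm = 5.2) {
  pts <- rbind(
    c(0, -13), c(0, -6), c(0, 0),     # medial surface up to the PHG edge
    c(6, 0),                          # crown -> medial CS mouth
    c(10, -3),                        # fundus (banks of length 5 each)
    c(14, 0),                         # lateral CS mouth
    c(18, 0),                         # FG crown apex
    c(22, 0)                          # lateral terminus
  )
  kv <- c(medial_terminus = 1L, phg_superior_edge = 3L,
          cs_medial_mouth = 4L, cs_fundus = 5L, cs_lateral_mouth = 6L,
          fg_crown_apex = 7L, lateral_terminus = 8L)
  SliceContour(case_id, slice_distance_mm, pts, kv)
}

fixtureLandmarks <- function(slice_distance_mm = 5.2) {
  deriveLandmarks(fixtureContour(slice_distance_mm = slice_distance_mm))
}

## Independent arc-length oracle: plain loop over segments (no shared
## code with arcLengthPositions).
oracleArcLengths <- function(pts) {
  out <- numeric(nrow(pts))
  for (i in 2:nrow(pts))
    out[i] <- out[i - 1] + sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
  out
}

## Dense-resampling landmark oracle: split every segment into `k` pieces,
## recompute key-vertex arc positions on the densified polyline, apply
## the landmark definitions directly.
oracleLandmarks <- function(contour, k = 64) {
  pts <- contourPoints(contour)
  kv <- keyVertices(contour)
  dense <- list(pts[1, , drop = FALSE])
  idx_map <- c(1L)
  for (i in 2:nrow(pts)) {
    tt <- seq_len(k) / k
    seg <- outer(1 - tt, pts[i - 1, ]) + outer(tt, pts[i, ])
    dense[[length(dense) + 1L]] <- seg
    idx_map <- c(idx_map, nrow(do.call(rbind, dense)))
  }
  dpts <- do.call(rbind, dense)
  cum <- oracleArcLengths(dpts)
  at <- function(name) cum[idx_map[kv[[name]]]]
  s_sup <- at("phg_superior_edge"); s_cme <- at("cs_medial_mouth")
  s_fun <- at("cs_fundus"); s_clm <- at("cs_lateral_mouth")
  s_lat <- at("lateral_terminus")
  fg <- (s_clm + s_lat) / 2
  c(s_phg_superior_edge = s_sup,
    s_phg_crown_midpoint = (s_sup + s_cme) / 2,
    s_cs_medial_edge = s_cme,
    s_medial_bank_half = (s_cme + s_fun) / 2,
    s_cs_fundus = s_fun,
    s_lateral_bank_quarter = s_fun + 0.25 * (s_clm - s_fun),
    s_fundus_fg_midpoint = (s_fun + fg) / 2,
    s_fg_crown_midpoint = fg)
}

## One generated case + contour for property tests
phantomContour <- function(seed = 42) {
  coh <- suppressWarnings(
    generateCohort(cohortConfig(n_cases = 1, seed = seed)))
  cohortStacks(coh)[[1]][[3]]
}

makeIntervals <- function(d, s0, s1, label, segment = "primary") {
  data.frame(slice_distance_mm = d, s_start = s0, s_end = s1,
             label = label, segment = segment, stringsAsFactors = FALSE)
}
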