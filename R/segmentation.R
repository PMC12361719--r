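#' Reference level governing a slice
#'
#' Maps a slice distance to the nearest reference level of the rule
#' table; equidistant ties resolve toward the posterior (smaller) level,
#' consistent with the protocol's posterior anchoring.
#'
#' @param slice_distance_mm slice distance (mm anterior to the
#'   hippocampus tip).
#' @param rule_table a \code{\linkS4class{RuleTable}}.
#' @param strict if TRUE (default), slices outside
#'   [posterior bound, max start] raise a range error; internal callers
#'   placing ground truth on posterior slices disable this.
#' @return the reference level (mm).
#' @examples
#' rt <- defaultRuleTable()
#' sliceRuleLevel(9.1, rt)  # 9
#' sliceRuleLevel(7.8, rt)  # 7
#' @export
sliceRuleLevel <- function(slice_distance_mm, rule_table, strict = TRUE) {
  d <- slice_distance_mm
  if (strict) {
    lo <- rule_table@posteriorBound
    hi <- max(rule_table@starts[.REGIONS])
    if (d < lo - 1e-9 || d > hi + 1e-9)
      stopf("mtlseg_range",
            "slice %.2f mm outside the protocol range [%.2f, %.2f]",
            d, lo, hi)
  }
  lv <- rule_table@levels
  dd <- abs(lv - d)
  cand <- lv[dd <= min(dd) + 1e-9]
  min(cand)
}

## Rule lookup with level fallback: if the (region, side) cell has no
## rule at the assigned level (possible off the canonical grid), use the
## cell from the nearest level that has one, ties posterior.
.ruleFor <- function(rule_table, level, region, side) {
  hit <- .findRule(rule_table, level, region, side)
  if (!is.null(hit)) return(hit)
  r <- rule_table@rules
  lv <- sort(unique(r$level[r$region == region & r$side == side]))
  if (length(lv) == 0) return(NULL)
  dd <- abs(lv - level)
  use <- min(lv[dd <= min(dd) + 1e-9])
  .findRule(rule_table, use, region, side)
}

#' Apply the placement rules on one slice
#'
#' Resolves every border on the slice to an arc-length position (landmark
#' position minus the offset for medial-directed rules, plus for
#' lateral), assembles the labeled intervals medial to lateral, and
#' shares border positions exactly between adjacent labels so the ribbon
#' is partitioned without gaps.  On the first ERC level the medial BA35
#' flank is emitted between its offset rule and the ERC medial border.
#' A border whose offset walks off the contour is clamped to the terminus
#' (with a warning); an inverted interval raises a degenerate-slice
#' error.
#'
#' If a rule references a region that is absent on the slice, the
#' dependent region absorbs the absent region's territory (the border
#' chains to the referenced region's own rule); this cannot occur on the
#' canonical slice grid.
#'
#' @param landmarks the slice's \code{\linkS4class{LandmarkSet}}.
#' @param slice_distance_mm slice distance (mm).
#' @param rule_table a \code{\linkS4class{RuleTable}}.
#' @param region_presence character vector of regions present on this
#'   slice (normally those whose start distance is at or anterior to the
#'   slice).
#' @return data.frame of intervals (slice_distance_mm, s_start, s_end,
#'   label, segment), medial to lateral.
#' @export
applyRulesSlice <- function(landmarks, slice_distance_mm, rule_table,
                            region_presence) {
  level <- sliceRuleLevel(slice_distance_mm, rule_table, strict = FALSE)
  pos <- landmarks@positions
  L <- landmarks@contourLength
  clamped <- 0L

  resolveBorder <- function(region, side, seen = character()) {
    if (region %in% seen)
      stopf("mtlseg_derivation", "circular rule reference at %s", region)
    rr <- .ruleFor(rule_table, level, region, side)
    if (is.null(rr))
      stopf("mtlseg_derivation",
            "no rule for %s %s border at level %g", region, side, level)
    if (!is.na(rr$reference)) {
      ref <- rr$reference
      if (ref %in% region_presence) {
        opp <- if (side == "medial") "lateral" else "medial"
        return(resolveBorder(ref, opp, c(seen, region)))
      }
      return(resolveBorder(ref, side, c(seen, region)))
    }
    s <- pos[[rr$landmark]] +
      (if (identical(rr$direction, "medial")) -1 else 1) * rr$offset_mm
    s2 <- min(max(s, 0), L)
    if (s2 != s) clamped <<- clamped + 1L
    s2
  }

  rows <- list()
  push <- function(label, s0, s1, segment = "primary") {
    if (s0 >= s1)
      stopf("mtlseg_degenerate_slice",
            "inverted %s interval on slice %.2f mm (%.3f >= %.3f)",
            label, slice_distance_mm, s0, s1)
    rows[[length(rows) + 1L]] <<- data.frame(
      slice_distance_mm = slice_distance_mm, s_start = s0, s_end = s1,
      label = label, segment = segment, stringsAsFactors = FALSE)
  }

  erc <- "ERC" %in% region_presence
  ba35 <- "BA35" %in% region_presence
  ba36 <- "BA36" %in% region_presence

  if (erc) {
    e_med <- resolveBorder("ERC", "medial")
    e_lat <- resolveBorder("ERC", "lateral")
    fl <- rule_table@flank
    fl <- fl[abs(fl$level - level) < 1e-9, , drop = FALSE]
    if (nrow(fl)) {
      f <- fl[1, ]
      s <- pos[[f$landmark]] +
        (if (identical(f$direction, "medial")) -1 else 1) * f$offset_mm
      s <- min(max(s, 0), L)
      push("BA35", s, e_med, "medial_flank")
    }
    push("ERC", e_med, e_lat)
  }
  if (ba35)
    push("BA35", resolveBorder("BA35", "medial"),
         resolveBorder("BA35", "lateral"))
  if (ba36)
    push("BA36", resolveBorder("BA36", "medial"),
         resolveBorder("BA36", "lateral"))

  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice_distance_mm = numeric(), s_start = numeric(),
               s_end = numeric(), label = character(),
               segment = character(), stringsAsFactors = FALSE)
  if (clamped > 0)
    warnf("mtlseg_border_clamped",
          "%d border(s) clamped to the contour terminus on slice %.2f mm",
          clamped, slice_distance_mm)
  res
}

## Engine core over pre-derived landmarks: one LandmarkSet per grid
## slice.  Used directly by the landmark-perturbation experiments.
.segmentFromLandmarks <- function(case_id, landmark_list, rule_table) {
  starts <- rule_table@starts
  rows <- lapply(landmark_list, function(lm) {
    d <- lm@sliceDistance
    presence <- .REGIONS[starts[.REGIONS] >= d - 1e-9]
    applyRulesSlice(lm, d, rule_table, presence)
  })
  LabelMap(case_id, do.call(rbind, rows))
}

#' Segment a slice stack with a rule table
#'
#' The deterministic protocol engine: labels every slice from the
#' posterior bound up to each region's start distance.  The expected
#' slice grid runs from the posterior bound to the anterior-most region
#' start in steps of the slice thickness; a stack missing any grid slice
#' raises a gap error listing the missing distances.  Identical input
#' yields identical output.
#'
#' @param stack list of \code{\linkS4class{SliceContour}} objects for one
#'   case (any order; extra slices outside the protocol range are
#'   ignored).
#' @param rule_table a \code{\linkS4class{RuleTable}}.
#' @return a \code{\linkS4class{LabelMap}}.
#' @export
segmentCase <- function(stack, rule_table) {
  dists <- vapply(stack, sliceDistance, numeric(1))
  th <- rule_table@sliceThickness
  grid <- seq(rule_table@posteriorBound,
              max(rule_table@starts[.REGIONS]) + 1e-9, by = th)
  idx <- vapply(grid, function(d) {
    i <- which(abs(dists - d) < 1e-6)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  if (anyNA(idx))
    stopf("mtlseg_gap", "stack is missing protocol slices at: %s mm",
          paste(sprintf("%.1f", grid[is.na(idx)]), collapse = ", "))
  lms <- lapply(idx, function(i) deriveLandmarks(stack[[i]]))
  cid <- caseId(stack[[1]])
  .segmentFromLandmarks(cid, lms, rule_table)
}

#' Segment every case of a cohort
#'
#' @param cohort an \code{\linkS4class{MTLCohort}} built with contours.
#' @param rule_table a \code{\linkS4class{RuleTable}}.
#' @return named list of \code{\linkS4class{LabelMap}} objects.
#' @export
segmentCohort <- function(cohort, rule_table) {
  if (length(cohort@stacks) == 0)
    stopf("mtlseg_input", "cohort has no contour stacks")
  lapply(cohort@stacks, segmentCase, rule_table = rule_table)
}
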