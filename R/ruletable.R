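## Rule-table construction, the default protocol table, rendering and
## comparison.

.ruleRow <- function(level, region, side, landmark = NA_character_,
                     offset = 0, direction = NA_character_,
                     reference = NA_character_) {
  data.frame(level = level, region = region, side = side,
             landmark = landmark, offset_mm = offset,
             direction = direction, reference = reference,
             stringsAsFactors = FALSE)
}

#' Construct a RuleTable
#'
#' Low-level constructor; most users will call
#' \code{\link{defaultRuleTable}} or \code{\link{deriveRuleTable}}.
#'
#' @param slice_thickness_mm slice thickness of the target grid (mm).
#' @param anchor anchor structure name.
#' @param starts named numeric region start distances (mm), exact
#'   multiples of the thickness.
#' @param levels reference levels (mm), strictly decreasing.
#' @param rules data.frame of border rules (see
#'   \code{\linkS4class{RuleTable}}).
#' @param flank data.frame of BA35 medial-flank rules.
#' @param posterior_bound_mm posterior bound of the labels (mm).
#' @param provenance free-form provenance list.
#' @return a validated \code{RuleTable}.
#' @export
ruleTable <- function(slice_thickness_mm, anchor, starts, levels, rules,
                      flank, posterior_bound_mm = 2.6,
                      provenance = list()) {
  new("RuleTable",
      sliceThickness = as.numeric(slice_thickness_mm),
      anchor = as.character(anchor),
      starts = starts,
      levels = as.numeric(levels),
      posteriorBound = as.numeric(posterior_bound_mm),
      rules = rules,
      flank = flank,
      provenance = provenance)
}

#' The published anterior-MTL placement protocol
#'
#' Returns the consolidated slice-wise placement rules for anterior ERC,
#' BA35 and BA36 relative to the anterior tip of the hippocampus, on a
#' 1.3 mm slice grid: region starts ERC 5.2 mm, BA35 9.1 mm, BA36
#' 10.4 mm; reference levels 10, 9, 7, 5, 4 and 2.5 mm anterior.  Border
#' rules per level:
#' \itemize{
#'   \item ERC medial: halfway point of the PHG crown on its first level
#'     (5 mm), the superior PHG edge posteriorly; ERC lateral: the medial
#'     CS edge throughout.
#'   \item BA35 medial: 7 / 10 / 5 mm medial to the superior PHG edge at
#'     the 9 / 7 / 5 mm levels, then shared with ERC's lateral border
#'     posteriorly; at the 5 mm level the 5 mm offset bounds the medial
#'     BA35 flank that embeds the emerging ERC.  BA35 lateral: the CS
#'     fundus throughout.
#'   \item BA36 medial: halfway point of the medial CS bank on its first
#'     level (10 mm), then shared with BA35's lateral border.  BA36
#'     lateral: quarter point of the lateral bank (closest to the fundus)
#'     at 10 mm, midpoint between the fundus and the FG crown midpoint at
#'     9 mm, the FG crown midpoint posteriorly.
#' }
#'
#' @param slice_thickness_mm slice thickness (mm), default 1.3.
#' @param starts named region start distances (mm); defaults are the
#'   protocol values on the 1.3 mm grid.
#' @param posterior_bound_mm posterior bound, default 2.6 mm (the first
#'   slice strictly anterior to the pre-existing posterior labels, which
#'   begin 1.3 mm anterior to the hippocampal head).
#' @return a \code{\linkS4class{RuleTable}}.
#' @examples
#' defaultRuleTable()
#' @export
defaultRuleTable <- function(slice_thickness_mm = 1.3,
                             starts = c(ERC = 5.2, BA35 = 9.1, BA36 = 10.4),
                             posterior_bound_mm = 2.6) {
  rules <- rbind(
    .ruleRow(10, "BA36", "medial", "s_medial_bank_half", 0, "medial"),
    .ruleRow(10, "BA36", "lateral", "s_lateral_bank_quarter", 0, "lateral"),
    .ruleRow(9, "BA35", "medial", "s_phg_superior_edge", 7, "medial"),
    .ruleRow(9, "BA35", "lateral", "s_cs_fundus", 0, "lateral"),
    .ruleRow(9, "BA36", "medial", reference = "BA35"),
    .ruleRow(9, "BA36", "lateral", "s_fundus_fg_midpoint", 0, "lateral"),
    .ruleRow(7, "BA35", "medial", "s_phg_superior_edge", 10, "medial"),
    .ruleRow(7, "BA35", "lateral", "s_cs_fundus", 0, "lateral"),
    .ruleRow(7, "BA36", "medial", reference = "BA35"),
    .ruleRow(7, "BA36", "lateral", "s_fg_crown_midpoint", 0, "lateral"),
    .ruleRow(5, "ERC", "medial", "s_phg_crown_midpoint", 0, "medial"),
    .ruleRow(5, "ERC", "lateral", "s_cs_medial_edge", 0, "lateral"),
    .ruleRow(5, "BA35", "medial", reference = "ERC"),
    .ruleRow(5, "BA35", "lateral", "s_cs_fundus", 0, "lateral"),
    .ruleRow(5, "BA36", "medial", reference = "BA35"),
    .ruleRow(5, "BA36", "lateral", "s_fg_crown_midpoint", 0, "lateral"),
    .ruleRow(4, "ERC", "medial", "s_phg_superior_edge", 0, "medial"),
    .ruleRow(4, "ERC", "lateral", "s_cs_medial_edge", 0, "lateral"),
    .ruleRow(4, "BA35", "medial", reference = "ERC"),
    .ruleRow(4, "BA35", "lateral", "s_cs_fundus", 0, "lateral"),
    .ruleRow(4, "BA36", "medial", reference = "BA35"),
    .ruleRow(4, "BA36", "lateral", "s_fg_crown_midpoint", 0, "lateral"),
    .ruleRow(2.5, "ERC", "medial", "s_phg_superior_edge", 0, "medial"),
    .ruleRow(2.5, "ERC", "lateral", "s_cs_medial_edge", 0, "lateral"),
    .ruleRow(2.5, "BA35", "medial", reference = "ERC"),
    .ruleRow(2.5, "BA35", "lateral", "s_cs_fundus", 0, "lateral"),
    .ruleRow(2.5, "BA36", "medial", reference = "BA35"),
    .ruleRow(2.5, "BA36", "lateral", "s_fg_crown_midpoint", 0, "lateral")
  )
  flank <- data.frame(level = 5, landmark = "s_phg_superior_edge",
                      offset_mm = 5, direction = "medial",
                      stringsAsFactors = FALSE)
  ruleTable(slice_thickness_mm, "hippocampus", starts,
            c(10, 9, 7, 5, 4, 2.5), rules, flank, posterior_bound_mm,
            provenance = list(source = "default protocol"))
}

.findRule <- function(rule_table, level, region, side) {
  r <- rule_table@rules
  hit <- r[r$level == level & r$region == region & r$side == side, ,
           drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit[1, , drop = FALSE]
}

#' Render a rule table as a human-readable grid
#'
#' Text rendering mirroring the protocol overview layout: one column per
#' reference level, one block per region with its medial and lateral
#' border rules.
#'
#' @param rule_table a \code{\linkS4class{RuleTable}}.
#' @return character vector of lines (invisibly printed with \code{cat}
#'   when interactive; returned for writing to file).
#' @export
renderRuleTable <- function(rule_table) {
  pretty <- c(
    s_phg_superior_edge = "superior PHG edge",
    s_phg_crown_midpoint = "halfway point of PHG crown",
    s_cs_medial_edge = "medial CS edge",
    s_medial_bank_half = "halfway point of medial CS bank",
    s_cs_fundus = "CS fundus",
    s_lateral_bank_quarter = "1/4 of lateral CS bank",
    s_fundus_fg_midpoint = "midpoint of CS fundus and FG crown midpoint",
    s_fg_crown_midpoint = "midpoint of FG crown"
  )
  cell <- function(level, region, side) {
    rr <- .findRule(rule_table, level, region, side)
    if (is.null(rr)) return("-")
    if (!is.na(rr$reference)) return(rr$reference)
    base <- pretty[[rr$landmark]]
    if (rr$offset_mm > 0)
      sprintf("%g mm %s to %s", rr$offset_mm, rr$direction, base)
    else base
  }
  lines <- c(
    sprintf("Placement rules (anchor: %s; starts ERC %.1f, BA35 %.1f, BA36 %.1f mm; grid %.1f mm)",
            rule_table@anchor, rule_table@starts[["ERC"]],
            rule_table@starts[["BA35"]], rule_table@starts[["BA36"]],
            rule_table@sliceThickness))
  for (region in .REGIONS) for (side in c("medial", "lateral")) {
    lines <- c(lines, sprintf("%s %s border:", region, side))
    for (lev in rule_table@levels) {
      lines <- c(lines, sprintf("  %4.1f mm anterior: %s", lev,
                                cell(lev, region, side)))
    }
  }
  if (nrow(rule_table@flank)) {
    f <- rule_table@flank
    lines <- c(lines, sprintf(
      "BA35 medial flank at level %g mm: from %g mm %s to %s to the ERC medial border",
      f$level[1], f$offset_mm[1], f$direction[1], pretty[[f$landmark[1]]]))
  }
  lines
}

#' Compare the scientific content of two rule tables
#'
#' Equality of thickness, anchor, starts, levels, posterior bound, border
#' rules and flank rules; provenance is ignored.
#'
#' @param a,b two \code{\linkS4class{RuleTable}} objects.
#' @param tol numeric tolerance on distances (mm).
#' @return TRUE, or a character vector describing the first differences.
#' @export
rulesEqual <- function(a, b, tol = 1e-9) {
  diffs <- character()
  if (abs(a@sliceThickness - b@sliceThickness) > tol)
    diffs <- c(diffs, "slice thickness differs")
  if (!identical(a@anchor, b@anchor)) diffs <- c(diffs, "anchor differs")
  if (!isTRUE(all.equal(a@starts[.REGIONS], b@starts[.REGIONS],
                        tolerance = tol)))
    diffs <- c(diffs, "starts differ")
  if (!isTRUE(all.equal(a@levels, b@levels, tolerance = tol)))
    diffs <- c(diffs, "levels differ")
  if (abs(a@posteriorBound - b@posteriorBound) > tol)
    diffs <- c(diffs, "posterior bound differs")
  key <- function(r) order(r$level, r$region, r$side)
  ra <- a@rules[key(a@rules), , drop = FALSE]
  rb <- b@rules[key(b@rules), , drop = FALSE]
  if (nrow(ra) != nrow(rb)) {
    diffs <- c(diffs, "different number of rules")
  } else {
    same <- ra$level == rb$level & ra$region == rb$region &
      ra$side == rb$side &
      (is.na(ra$landmark) & is.na(rb$landmark) |
         !is.na(ra$landmark) & !is.na(rb$landmark) &
         ra$landmark == rb$landmark &
         abs(ra$offset_mm - rb$offset_mm) <= tol &
         (ra$offset_mm == 0 | ra$direction == rb$direction)) &
      (is.na(ra$reference) & is.na(rb$reference) |
         !is.na(ra$reference) & !is.na(rb$reference) &
         ra$reference == rb$reference)
    if (!all(same))
      diffs <- c(diffs, sprintf(
        "rule differs at level %g %s %s", ra$level[!same][1],
        ra$region[!same][1], ra$side[!same][1]))
  }
  if (nrow(a@flank) != nrow(b@flank) ||
      (nrow(a@flank) && !isTRUE(all.equal(
        a@flank[order(a@flank$level), c("level", "landmark", "offset_mm",
                                        "direction")],
        b@flank[order(b@flank$level), c("level", "landmark", "offset_mm",
                                        "direction")],
        check.attributes = FALSE, tolerance = tol))))
    diffs <- c(diffs, "flank rules differ")
  if (length(diffs)) diffs else TRUE
}
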