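#' Summarize border-to-landmark distance records
#'
#' Per (region, side, segment, landmark, slice level) cell: n of
#' contributing (non-absent) records, mean, median and SD.  The median
#' for even n is the midpoint of the central pair; the SD is the sample
#' SD (n - 1 denominator).  Absences are excluded from the statistics but
#' reported in \code{n_absent}.  Cells with no contributing records are
#' omitted (with a message).
#'
#' @param records DistanceRecord data.frame from
#'   \code{\link{measureCohort}}.
#' @return StatsRow data.frame: region, side, segment, landmark,
#'   slice_level, n, n_absent, mean, median, sd.
#' @examples
#' rec <- data.frame(region = "BA35", side = "medial", segment = "primary",
#'   landmark = "s_phg_superior_edge", slice_level = "9",
#'   distance_mm = c(1, 2, 3), absent = FALSE)
#' summarizeDistances(rec)  # mean 2, median 2, sd 1
#' @export
summarizeDistances <- function(records) {
  key <- interaction(records$region, records$side, records$segment,
                     records$landmark, records$slice_level, drop = TRUE)
  out <- lapply(split(records, key), function(g) {
    x <- g$distance_mm[!g$absent]
    if (length(x) == 0) {
      message(sprintf("cell %s/%s/%s @ level %s: no records, omitted",
                      g$region[1], g$side[1], g$landmark[1],
                      g$slice_level[1]))
      return(NULL)
    }
    data.frame(region = g$region[1], side = g$side[1],
               segment = g$segment[1], landmark = g$landmark[1],
               slice_level = g$slice_level[1],
               n = length(x), n_absent = sum(g$absent),
               mean = mean(x), median = stats::median(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Summarize anterior-extent records
#'
#' Per (region, anchor): n, mean, median, SD of the extent distances.
#'
#' @param records ExtentRecord data.frame from \code{\link{measureCohort}}.
#' @return data.frame: region, anchor, n, mean, median, sd.
#' @export
summarizeExtents <- function(records) {
  key <- interaction(records$region, records$anchor, drop = TRUE)
  out <- lapply(split(records, key), function(g) {
    x <- g$distance_mm[is.finite(g$distance_mm)]
    if (length(x) == 0) return(NULL)
    data.frame(region = g$region[1], anchor = g$anchor[1], n = length(x),
               mean = mean(x), median = stats::median(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Select the anchor structure for the protocol
#'
#' Ranks candidate anchors by the sum of the extent-distance SDs across
#' the three regions (lower = less between-subject variability).  Among
#' the top two, the anchor flagged as easy to identify on MRI is
#' preferred — the amygdala tip tends to have the lowest variability but
#' is harder to delineate, which is why the hippocampus tip ends up as
#' the anchor.  If neither of the top two is easy, the best-SD anchor is
#' returned with a warning.
#'
#' @param extent_stats data.frame from \code{\link{summarizeExtents}}.
#' @param identifiability named character vector anchor -> "easy"/"hard".
#' @return list with \code{anchor} (chosen name), \code{ranking}
#'   (data.frame anchor, sum_sd, identifiability, rank) and \code{note}.
#' @export
selectAnchor <- function(extent_stats,
                         identifiability = .ANCHOR_IDENTIFIABILITY) {
  anchors <- unique(extent_stats$anchor)
  complete <- anchors[vapply(anchors, function(a)
    all(.REGIONS %in% extent_stats$region[extent_stats$anchor == a]),
    logical(1))]
  if (length(complete) < 2)
    stopf("mtlseg_input",
          "need >= 2 candidate anchors with stats for all three regions")
  sum_sd <- vapply(complete, function(a)
    sum(extent_stats$sd[extent_stats$anchor == a &
                          extent_stats$region %in% .REGIONS]), numeric(1))
  ident <- identifiability[complete]
  ident[is.na(ident)] <- "hard"
  ord <- order(sum_sd, complete)  # deterministic; input order irrelevant
  ranking <- data.frame(anchor = complete[ord], sum_sd = sum_sd[ord],
                        identifiability = unname(ident[ord]),
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  top2 <- ranking[seq_len(min(2, nrow(ranking))), ]
  note <- ""
  if (top2$identifiability[1] == "easy") {
    chosen <- top2$anchor[1]
  } else if (nrow(top2) > 1 && top2$identifiability[2] == "easy") {
    chosen <- top2$anchor[2]
    note <- sprintf(
      "%s has the lowest summed SD but is hard to identify on MRI; %s chosen",
      top2$anchor[1], chosen)
  } else {
    chosen <- ranking$anchor[1]
    note <- "no easily identifiable anchor among the top two; best-SD anchor returned"
    warnf("mtlseg_anchor", "%s", note)
  }
  list(anchor = chosen, ranking = ranking, note = note)
}

#' Quantize a start distance to the slice grid
#'
#' Nearest integer multiple of the slice thickness; exact half-grid ties
#' round away from zero.  E.g. a measured median anterior extent of
#' 4.75 mm on a 1.3 mm grid becomes 5.2 mm.
#'
#' @param median_mm measured median distance (mm, > 0); vectorized.
#' @param slice_thickness_mm slice thickness (mm, > 0).
#' @return quantized distance (mm), an exact multiple of the thickness.
#' @examples
#' quantizeToGrid(c(4.75, 9.25, 10.25), 1.3)  # 5.2, 9.1, 10.4
#' @export
quantizeToGrid <- function(median_mm, slice_thickness_mm) {
  if (any(!is.finite(median_mm)) || any(median_mm <= 0) ||
      !is.finite(slice_thickness_mm) || slice_thickness_mm <= 0)
    stopf("mtlseg_domain",
          "median and slice thickness must be positive and finite")
  slice_thickness_mm * floor(median_mm / slice_thickness_mm + 0.5)
}

#' Round a border offset to whole millimetres
#'
#' Nearest integer millimetre of the magnitude (the direction is carried
#' separately by the rule); exact .5 ties round away from zero.
#'
#' @param median_mm measured median signed distance (mm); vectorized.
#' @return non-negative integer offset (mm).
#' @examples
#' roundOffset(c(7.19, 9.96, -5.40))  # 7, 10, 5
#' @export
roundOffset <- function(median_mm) {
  if (any(!is.finite(median_mm)))
    stopf("mtlseg_domain", "offset median must be finite")
  floor(abs(median_mm) + 0.5)
}

#' Derive the placement rule table from cohort statistics
#'
#' Reproduces the protocol inference: the anchor is selected from the
#' extent statistics (unless given), region start distances are the
#' measured medians of the extent to the chosen anchor quantized to the
#' slice grid, and the offset-bearing border cells (the medial BA35
#' borders, including the flank) take their offsets from the rounded
#' medians of the corresponding measured cells.  The structural template
#' — which landmark each border follows at each level, where borders are
#' shared between adjacent regions, and which cells carry a numeric
#' offset — is the protocol's qualitative finding and is fixed; medians
#' of the pure landmark cells are recorded in the provenance but do not
#' perturb the rules.
#'
#' The emitted direction of non-zero offsets follows the template wording
#' by default (\code{direction_policy = "template"}, the protocol
#' deliverable); with \code{"measured"} the direction is taken from the
#' sign of the measured median (negative = medial).  The measured medians
#' are preserved in the provenance either way.
#'
#' @param distance_stats StatsRow data.frame from
#'   \code{\link{summarizeDistances}}.
#' @param extent_stats data.frame from \code{\link{summarizeExtents}}.
#' @param slice_thickness_mm slice thickness of the target grid (mm).
#' @param anchor anchor name, or NULL to select from the statistics.
#' @param identifiability anchor identifiability map for selection.
#' @param direction_policy "template" or "measured" (see Details).
#' @param posterior_bound_mm posterior bound of the labels (mm).
#' @return a \code{\linkS4class{RuleTable}}.
#' @export
deriveRuleTable <- function(distance_stats, extent_stats,
                            slice_thickness_mm = 1.3,
                            anchor = NULL,
                            identifiability = .ANCHOR_IDENTIFIABILITY,
                            direction_policy = c("template", "measured"),
                            posterior_bound_mm = 2.6) {
  direction_policy <- match.arg(direction_policy)
  sel <- NULL
  if (is.null(anchor)) {
    sel <- selectAnchor(extent_stats, identifiability)
    anchor <- sel$anchor
  }

  starts <- numeric(0)
  medians_used <- list()
  for (r in .REGIONS) {
    row <- extent_stats[extent_stats$region == r &
                          extent_stats$anchor == anchor, , drop = FALSE]
    if (nrow(row) == 0)
      stopf("mtlseg_derivation",
            "missing extent cell: region %s, anchor %s", r, anchor)
    starts[[r]] <- quantizeToGrid(row$median[1], slice_thickness_mm)
    medians_used[[paste0("extent_", r)]] <- row$median[1]
  }

  template <- defaultRuleTable(slice_thickness_mm, starts,
                               posterior_bound_mm)
  statFor <- function(level, region, side, segment, landmark) {
    hit <- distance_stats[
      distance_stats$region == region & distance_stats$side == side &
        distance_stats$segment == segment &
        distance_stats$landmark == landmark &
        distance_stats$slice_level == as.character(level), , drop = FALSE]
    if (nrow(hit) == 0)
      stopf("mtlseg_derivation",
            "missing stats cell: level %s, %s %s border vs %s",
            as.character(level), region, side, landmark)
    hit[1, ]
  }

  rules <- template@rules
  for (k in seq_len(nrow(rules))) {
    if (!is.na(rules$reference[k])) next
    st <- statFor(rules$level[k], rules$region[k], rules$side[k],
                  "primary", rules$landmark[k])
    medians_used[[sprintf("L%s_%s_%s", rules$level[k], rules$region[k],
                          rules$side[k])]] <- st$median
    ## only the offset-bearing template cells (BA35 medial borders) take
    ## their offset from the data; the remaining cells are qualitative
    ## landmark assignments whose medians are kept as provenance only
    if (template@rules$offset_mm[k] == 0) next
    off <- roundOffset(st$median)
    rules$offset_mm[k] <- off
    if (direction_policy == "measured" && off > 0)
      rules$direction[k] <- if (st$median < 0) "medial" else "lateral"
  }

  flank <- template@flank
  for (k in seq_len(nrow(flank))) {
    st <- statFor(flank$level[k], "BA35", "medial", "medial_flank",
                  flank$landmark[k])
    off <- roundOffset(st$median)
    flank$offset_mm[k] <- off
    if (direction_policy == "measured" && off > 0)
      flank$direction[k] <- if (st$median < 0) "medial" else "lateral"
    medians_used[[sprintf("flank_L%s", flank$level[k])]] <- st$median
  }

  ruleTable(slice_thickness_mm, anchor, starts, template@levels, rules,
            flank, posterior_bound_mm,
            provenance = list(medians = medians_used,
                              anchor_ranking = sel$ranking,
                              direction_policy = direction_policy))
}
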