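## Border-to-landmark distance and anterior-extent measurement stage.

## Default identifiability of anchor candidates on in vivo MRI; only the
## anterior amygdala tip is flagged as hard to delineate.
.ANCHOR_IDENTIFIABILITY <- c(
  hippocampus = "easy", amygdala = "hard", temporal_pole = "easy",
  limen_insulae = "easy", collateral_sulcus = "easy"
)

## Measurement template: which (region, side, segment, landmark) pairs
## are quantified at which reference levels, mirroring the border
## measurement tables; "first" rows are measured on the anterior-most
## slice where the region is present in each case.
.measurementTemplate <- function() {
  tpl <- function(region, side, segment, landmark, levels)
    data.frame(region = region, side = side, segment = segment,
               landmark = landmark, slice_level = as.character(levels),
               stringsAsFactors = FALSE)
  rbind(
    tpl("ERC", "medial", "primary", "s_phg_superior_edge",
        c(5, 4, 2.5, "first")),
    tpl("ERC", "medial", "primary", "s_phg_crown_midpoint", c(5, "first")),
    tpl("ERC", "lateral", "primary", "s_cs_medial_edge",
        c(5, 4, 2.5, "first")),
    tpl("BA35", "medial", "primary", "s_phg_superior_edge",
        c(9, 7, "first")),
    tpl("BA35", "medial", "medial_flank", "s_phg_superior_edge", 5),
    tpl("BA35", "lateral", "primary", "s_cs_fundus",
        c(9, 7, 5, 4, 2.5, "first")),
    tpl("BA36", "medial", "primary", "s_medial_bank_half", c(10, "first")),
    tpl("BA36", "lateral", "primary", "s_cs_fundus", c(10, "first")),
    tpl("BA36", "lateral", "primary", "s_lateral_bank_quarter",
        c(10, "first")),
    tpl("BA36", "lateral", "primary", "s_fundus_fg_midpoint", 9),
    tpl("BA36", "lateral", "primary", "s_fg_crown_midpoint", c(7, 5, 4, 2.5))
  )
}

#' Signed border-to-landmark distance
#'
#' Arc-length difference between a border annotation and a landmark on
#' the same slice: positive when the border lies lateral to the landmark,
#' negative when medial.
#'
#' @param border one border annotation: a one-row data.frame with columns
#'   \code{s} and \code{slice_distance_mm} (as produced by
#'   \code{\link{placeTrueBorders}}).
#' @param landmarks the slice's \code{\linkS4class{LandmarkSet}}.
#' @param landmark landmark name (one of the LandmarkSet vocabulary).
#' @return signed distance (mm).
#' @examples
#' b <- data.frame(s = 9, slice_distance_mm = 5.2)
#' # against a landmark at s = 12 the border is 3 mm medial: -3
#' @export
signedBorderDistance <- function(border, landmarks, landmark) {
  if (!landmark %in% .LANDMARKS)
    stopf("mtlseg_domain", "unknown landmark '%s'", landmark)
  if (abs(border$slice_distance_mm[1] - landmarks@sliceDistance) > 1e-6)
    stopf("mtlseg_pairing",
          "border (slice %.2f mm) and landmarks (slice %.2f mm) disagree",
          border$slice_distance_mm[1], landmarks@sliceDistance)
  border$s[1] - landmarks@positions[[landmark]]
}

#' Anterior-extent distance of a region to an anchor structure
#'
#' Axial distance between the region's anterior-most extent and the
#' anchor position, with the anchor's sign convention: posterior anchors
#' (hippocampus, amygdala) give extent minus anchor position, anterior
#' anchors (temporal pole, limen insulae, collateral sulcus tip) give
#' anchor position minus extent.  The hippocampus anchor sits at 0 by
#' construction, so its distance is the extent itself.
#'
#' @param case a \code{\linkS4class{CasePhantom}}.
#' @param region region name.
#' @param anchor anchor name.
#' @param orientation named character vector mapping anchors to
#'   "posterior"/"anterior"; defaults taken from the cohort defaults.
#' @return distance (mm), or NA (absence marker) if the region or anchor
#'   is not annotated for the case.
#' @export
anteriorExtentDistance <- function(case, region, anchor,
                                   orientation = NULL) {
  if (!region %in% names(case@extents) || !anchor %in% names(case@anchors))
    return(NA_real_)
  if (is.null(orientation))
    orientation <- c(hippocampus = "posterior", amygdala = "posterior",
                     temporal_pole = "anterior", limen_insulae = "anterior",
                     collateral_sulcus = "anterior")
  ext <- case@extents[[region]]
  pos <- case@anchors[[anchor]]
  if (identical(orientation[[anchor]], "anterior")) pos - ext else ext - pos
}

## Nearest stack slice to a reference level; equidistant ties resolve
## toward the posterior slice (the protocol is anchored posteriorly).
.nearestSlice <- function(distances, level) {
  dd <- abs(distances - level)
  cand <- distances[dd <= min(dd) + 1e-9]
  min(cand)
}

#' Measure a cohort: border distances and anterior extents
#'
#' Reproduces the measurement stage on a phantom cohort.  For each case,
#' the stack slice nearest each reference level is selected (equidistant
#' ties resolve posterior) and every template (region, side, landmark)
#' cell is measured as a signed arc-length distance from the true border
#' to the landmark.  Cases lacking a region at a level contribute an
#' absence record, so records plus absences always total the cohort size
#' per cell.  Additional "first slide of the region" measurements are
#' taken on the anterior-most slice where each region is present.
#' Anterior-extent distances of every region to every anchor are measured
#' per case.
#'
#' @param cohort an \code{\linkS4class{MTLCohort}} built with contours.
#' @param reference_levels numeric reference levels (mm anterior to the
#'   hippocampus tip).
#' @return list with components \code{distances} (DistanceRecord
#'   data.frame: case_id, slice_level, slice_distance_mm, region, side,
#'   segment, landmark, distance_mm, absent) and \code{extents}
#'   (ExtentRecord data.frame: case_id, region, anchor, distance_mm).
#' @export
measureCohort <- function(cohort, reference_levels = c(10, 9, 7, 5, 4, 2.5)) {
  if (length(cohort@cases) == 0)
    stopf("mtlseg_input", "empty cohort")
  if (length(cohort@stacks) == 0)
    stopf("mtlseg_input", "cohort has no contour stacks; regenerate with contours = TRUE")
  tpl <- .measurementTemplate()
  orientation <- structure(cohort@config$anchor_params$orientation,
                           names = cohort@config$anchor_params$anchor)
  dist_rows <- list()
  ext_rows <- list()

  for (case in cohort@cases) {
    cid <- case@caseId
    stack <- cohort@stacks[[cid]]
    dists <- vapply(stack, sliceDistance, numeric(1))
    tr <- cohort@truth[cohort@truth$case_id == cid, , drop = FALSE]
    lm_by_d <- list()
    lmAt <- function(d) {
      k <- sprintf("%.6f", d)
      if (is.null(lm_by_d[[k]])) {
        i <- which(abs(dists - d) < 1e-9)[1]
        lm_by_d[[k]] <<- deriveLandmarks(stack[[i]])
      }
      lm_by_d[[k]]
    }
    firstSlice <- function(region) {
      dd <- tr$slice_distance_mm[tr$region == region]
      if (length(dd)) max(dd) else NA_real_
    }
    for (j in seq_len(nrow(tpl))) {
      cell <- tpl[j, ]
      d <- if (cell$slice_level == "first") firstSlice(cell$region) else
        .nearestSlice(dists, as.numeric(cell$slice_level))
      lvl <- if (cell$slice_level == "first")
        paste0("first_", cell$region) else cell$slice_level
      hit <- if (is.na(d)) tr[0, ] else
        tr[abs(tr$slice_distance_mm - d) < 1e-9 & tr$region == cell$region &
             tr$side == cell$side & tr$segment == cell$segment, ,
           drop = FALSE]
      if (nrow(hit) == 0) {
        dist_rows[[length(dist_rows) + 1L]] <- data.frame(
          case_id = cid, slice_level = lvl, slice_distance_mm = d,
          region = cell$region, side = cell$side, segment = cell$segment,
          landmark = cell$landmark, distance_mm = NA_real_, absent = TRUE,
          stringsAsFactors = FALSE)
      } else {
        lm <- lmAt(d)
        dist_rows[[length(dist_rows) + 1L]] <- data.frame(
          case_id = cid, slice_level = lvl, slice_distance_mm = d,
          region = cell$region, side = cell$side, segment = cell$segment,
          landmark = cell$landmark,
          distance_mm = signedBorderDistance(hit[1, ], lm, cell$landmark),
          absent = FALSE, stringsAsFactors = FALSE)
      }
    }
    for (region in .REGIONS) for (anchor in names(case@anchors)) {
      ext_rows[[length(ext_rows) + 1L]] <- data.frame(
        case_id = cid, region = region, anchor = anchor,
        distance_mm = anteriorExtentDistance(case, region, anchor,
                                             orientation),
        stringsAsFactors = FALSE)
    }
  }
  list(distances = do.call(rbind, dist_rows),
       extents = do.call(rbind, ext_rows))
}
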