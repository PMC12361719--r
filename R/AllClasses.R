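#' @import methods
NULL

#' SliceContour: a coronal pial-surface polyline with tagged key vertices
#'
#' Represents the pial surface of the medial temporal lobe on one coronal
#' slice as an ordered polyline running medial to lateral, together with a
#' map of anatomical key vertices: the medial contour terminus, the
#' superior edge of the parahippocampal gyrus (PHG), the medial mouth,
#' fundus and lateral mouth of the collateral sulcus (CS), the crown apex
#' of the fusiform gyrus (FG), and the lateral terminus.  The coordinate
#' frame is the coronal plane with the first coordinate increasing
#' laterally and the second increasing superiorly (right-handed; left/right
#' hemispheres are mirrored upstream into this canonical orientation).
#'
#' @slot caseId character scalar identifying the case.
#' @slot sliceDistance numeric scalar, distance anterior to the anterior
#'   tip of the hippocampus in mm (positive = anterior).
#' @slot points numeric matrix (n x 2) of vertices in mm.
#' @slot keyVertices named integer vector mapping key-vertex names to
#'   vertex indices; names must be exactly the seven canonical keys and
#'   indices must be strictly increasing in medial -> lateral order.
#'
#' @export
setClass("SliceContour",
  representation(
    caseId = "character",
    sliceDistance = "numeric",
    points = "matrix",
    keyVertices = "integer"
  )
)

setValidity("SliceContour", function(object) {
  p <- object@points
  kv <- object@keyVertices
  if (!is.numeric(p) || ncol(p) != 2)
    return("points must be a numeric matrix with 2 columns")
  if (nrow(p) < 8)
    return("contour must have at least 8 vertices")
  if (anyNA(p))
    return("contour vertices must be finite")
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg <= 0))
    return(sprintf("duplicate consecutive vertices (first at index %d)",
                   which(seg <= 0)[1]))
  if (!identical(sort(names(kv)), sort(.KEY_VERTICES)))
    return(sprintf("keyVertices must name exactly: %s",
                   paste(.KEY_VERTICES, collapse = ", ")))
  idx <- kv[.KEY_VERTICES]
  if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(p)))
    return("key-vertex indices out of range")
  if (any(diff(idx) <= 0))
    return("key-vertex indices must be strictly increasing medial -> lateral")
  yf <- p[kv[["cs_fundus"]], 2]
  y1 <- p[kv[["cs_medial_mouth"]], 2]
  y2 <- p[kv[["cs_lateral_mouth"]], 2]
  if (yf >= y1 || yf >= y2)
    return("cs_fundus must lie inferior to both CS mouth vertices")
  if (length(object@caseId) != 1L)
    return("caseId must be a single string")
  if (length(object@sliceDistance) != 1L || !is.finite(object@sliceDistance))
    return("sliceDistance must be a finite scalar (mm)")
  TRUE
})

#' Construct a SliceContour
#'
#' @param case_id case identifier.
#' @param slice_distance_mm distance anterior to the hippocampus tip (mm).
#' @param points n x 2 numeric matrix of vertices (mm), medial to lateral.
#' @param key_vertices named integer vector of key-vertex indices (see
#'   \code{\linkS4class{SliceContour}}).
#' @return a validated \code{SliceContour}.
#' @examples
#' pts <- cbind(c(0, 0, 0, 6, 10, 14, 18, 22),
#'              c(-13, -6, 0, 0, -3, 0, 0, 0))
#' kv <- c(medial_terminus = 1L, phg_superior_edge = 3L, cs_medial_mouth = 4L,
#'         cs_fundus = 5L, cs_lateral_mouth = 6L, fg_crown_apex = 7L,
#'         lateral_terminus = 8L)
#' SliceContour("case01", 5.2, pts, kv)
#' @export
SliceContour <- function(case_id, slice_distance_mm, points, key_vertices) {
  new("SliceContour",
      caseId = as.character(case_id),
      sliceDistance = as.numeric(slice_distance_mm),
      points = unname(as.matrix(points)),
      keyVertices = structure(as.integer(key_vertices),
                              names = names(key_vertices)))
}

#' LandmarkSet: protocol landmark positions on one slice
#'
#' Arc-length positions (mm from the medial terminus, increasing
#' laterally) of the eight protocol landmarks, plus the collateral sulcus
#' depth and the slice distance.  Positions are weakly increasing in the
#' canonical order and lie within the contour domain.
#'
#' @slot positions named numeric vector over the eight landmark names.
#' @slot csDepth collateral sulcus depth (mm, >= 0).
#' @slot sliceDistance slice distance anterior to the hippocampus tip (mm).
#' @slot contourLength total arc length of the source contour (mm).
#' @export
setClass("LandmarkSet",
  representation(
    positions = "numeric",
    csDepth = "numeric",
    sliceDistance = "numeric",
    contourLength = "numeric"
  )
)

setValidity("LandmarkSet", function(object) {
  s <- object@positions
  if (!identical(names(s), .LANDMARKS))
    return(sprintf("positions must be named, in order: %s",
                   paste(.LANDMARKS, collapse = ", ")))
  if (anyNA(s)) return("landmark positions must be finite")
  if (any(diff(s) < -1e-9))
    return("landmark positions must be weakly increasing medial -> lateral")
  if (any(s < -1e-9) || any(s > object@contourLength + 1e-9))
    return("landmark positions must lie within [0, contour length]")
  if (object@csDepth < 0) return("csDepth must be >= 0")
  TRUE
})

#' Construct a LandmarkSet
#'
#' Usually produced by \code{\link{deriveLandmarks}}; the constructor is
#' exported for building fixtures and for readers.
#'
#' @param positions named numeric vector of arc-length positions (mm) over
#'   the eight canonical landmark names.
#' @param cs_depth_mm collateral sulcus depth (mm).
#' @param slice_distance_mm slice distance (mm anterior to hippocampus tip).
#' @param contour_length_mm total arc length of the source contour (mm).
#' @return a validated \code{LandmarkSet}.
#' @export
LandmarkSet <- function(positions, cs_depth_mm, slice_distance_mm,
                        contour_length_mm) {
  new("LandmarkSet",
      positions = positions[.LANDMARKS],
      csDepth = as.numeric(cs_depth_mm),
      sliceDistance = as.numeric(slice_distance_mm),
      contourLength = as.numeric(contour_length_mm))
}

#' RuleTable: machine-readable slice-wise border placement rules
#'
#' The protocol deliverable: region start distances on the slice grid,
#' the reference levels, and per (level, region, side) a border rule.
#' A rule is either a landmark rule (landmark name + non-negative offset
#' in mm + direction, medial or lateral) or a reference rule (the border
#' is shared with a named adjacent region, e.g. BA36's medial border is
#' BA35's lateral border).
#'
#' @slot sliceThickness slice thickness of the target grid (mm).
#' @slot anchor anchor structure name (e.g. "hippocampus").
#' @slot starts named numeric, region start distances (mm), exact
#'   multiples of the slice thickness.
#' @slot levels numeric, reference levels (mm), strictly decreasing.
#' @slot posteriorBound posterior bound of the new labels (mm).
#' @slot rules data.frame with columns level, region, side, landmark,
#'   offset_mm, direction, reference.
#' @slot flank data.frame with columns level, landmark, offset_mm,
#'   direction: the BA35 medial-flank rule (one row per flank level).
#' @slot provenance list of free-form provenance (medians used, config).
#' @export
setClass("RuleTable",
  representation(
    sliceThickness = "numeric",
    anchor = "character",
    starts = "numeric",
    levels = "numeric",
    posteriorBound = "numeric",
    rules = "data.frame",
    flank = "data.frame",
    provenance = "list"
  )
)

setValidity("RuleTable", function(object) {
  th <- object@sliceThickness
  if (length(th) != 1L || !is.finite(th) || th <= 0)
    return("sliceThickness must be a positive scalar")
  st <- object@starts
  if (!all(.REGIONS %in% names(st)))
    return("starts must cover ERC, BA35, BA36")
  k <- st / th
  if (any(abs(k - round(k)) > 1e-6))
    return("start distances must be exact multiples of the slice thickness")
  if (any(diff(object@levels) >= 0))
    return("levels must be strictly decreasing anterior -> posterior")
  r <- object@rules
  need <- c("level", "region", "side", "landmark", "offset_mm",
            "direction", "reference")
  if (!all(need %in% names(r)))
    return(sprintf("rules must have columns: %s", paste(need, collapse = ", ")))
  lmk <- r$landmark[!is.na(r$landmark)]
  if (!all(lmk %in% .LANDMARKS))
    return("every landmark rule must use a landmark from the LandmarkSet vocabulary")
  ref <- r$reference[!is.na(r$reference)]
  if (!all(ref %in% .REGIONS))
    return("reference rules must name a region")
  if (any(is.na(r$landmark) & is.na(r$reference)))
    return("each rule needs a landmark or a region reference")
  if (!all(r$level %in% object@levels))
    return("rule levels must be among the reference levels")
  TRUE
})

#' LabelMap: ordered labeled arc-length intervals per slice
#'
#' One row per labeled interval: slice distance, interval
#' \code{[s_start, s_end)} in arc length (mm), label (ERC/BA35/BA36) and
#' segment ("primary" or "medial_flank" for the anterior BA35 flank).
#' Within a slice, intervals are sorted medial to lateral and do not
#' overlap.
#'
#' @slot caseId case identifier.
#' @slot intervals data.frame with columns slice_distance_mm, s_start,
#'   s_end, label, segment.
#' @export
setClass("LabelMap",
  representation(
    caseId = "character",
    intervals = "data.frame"
  )
)

setValidity("LabelMap", function(object) {
  iv <- object@intervals
  need <- c("slice_distance_mm", "s_start", "s_end", "label", "segment")
  if (!all(need %in% names(iv)))
    return(sprintf("intervals must have columns: %s",
                   paste(need, collapse = ", ")))
  if (nrow(iv) == 0) return(TRUE)
  if (!all(iv$label %in% .REGIONS))
    return("labels must be among ERC, BA35, BA36")
  if (any(iv$s_start >= iv$s_end))
    return("each interval must satisfy s_start < s_end")
  for (d in unique(iv$slice_distance_mm)) {
    s <- iv[iv$slice_distance_mm == d, , drop = FALSE]
    s <- s[order(s$s_start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$s_start[-1] < s$s_end[-nrow(s)] - 1e-9))
      return(sprintf("overlapping intervals on slice %.3f", d))
  }
  TRUE
})

#' Construct a LabelMap
#' @param case_id case identifier.
#' @param intervals data.frame with columns slice_distance_mm, s_start,
#'   s_end, label, segment.
#' @return a validated \code{LabelMap}.
#' @export
LabelMap <- function(case_id, intervals) {
  if (nrow(intervals))
    intervals <- intervals[order(intervals$slice_distance_mm,
                                 intervals$s_start), , drop = FALSE]
  rownames(intervals) <- NULL
  new("LabelMap", caseId = as.character(case_id), intervals = intervals)
}

#' CasePhantom: per-case synthetic anatomy parameters
#'
#' Scalar description of one phantom case: anterior extents of the three
#' cortical regions, axial positions of the candidate anchor structures,
#' collateral sulcus depth and class, disease-group flag, and the
#' per-case contour shape parameters used to draw its slices.
#'
#' @slot caseId case identifier.
#' @slot hemisphere "L" or "R".
#' @slot diseaseGroup logical, neurodegenerative-disease case.
#' @slot csDepthClass "shallow" or "deep".
#' @slot csDepth CS depth at the hippocampus-tip level (mm).
#' @slot extents named numeric: anterior extent per region (mm anterior to
#'   the hippocampus tip).
#' @slot anchors named numeric: axial positions of anchor structures on
#'   the same axis (hippocampus tip at 0).
#' @slot shape named numeric list of contour shape parameters.
#' @export
setClass("CasePhantom",
  representation(
    caseId = "character",
    hemisphere = "character",
    diseaseGroup = "logical",
    csDepthClass = "character",
    csDepth = "numeric",
    extents = "numeric",
    anchors = "numeric",
    shape = "numeric"
  )
)

setValidity("CasePhantom", function(object) {
  if (!all(.REGIONS %in% names(object@extents)))
    return("extents must cover ERC, BA35, BA36")
  if (any(object@extents <= 0))
    return("region extents must be positive")
  if (!object@csDepthClass %in% c("shallow", "deep"))
    return("csDepthClass must be 'shallow' or 'deep'")
  ok <- if (object@csDepthClass == "deep") object@csDepth >= 7 else
    object@csDepth < 7
  if (!ok)
    return("csDepth inconsistent with csDepthClass at the hippocampus-tip slice")
  TRUE
})

#' MTLCohort: a generated phantom cohort
#'
#' Container for a synthetic cohort: per-case phantoms, per-case slice
#' stacks of \code{SliceContour} objects, the ground-truth border
#' annotation table, and the generating configuration.
#'
#' @slot cases list of \code{CasePhantom}.
#' @slot stacks named list (per case) of lists of \code{SliceContour},
#'   posterior to anterior; empty when contours were not built.
#' @slot truth data.frame of ground-truth border annotations with columns
#'   case_id, slice_distance_mm, region, side, segment, s.
#' @slot config the \code{\link{cohortConfig}} used.
#' @slot clamped integer count of truth borders clamped to the contour
#'   domain during generation.
#' @export
setClass("MTLCohort",
  representation(
    cases = "list",
    stacks = "list",
    truth = "data.frame",
    config = "list",
    clamped = "integer"
  )
)

setMethod("show", "SliceContour", function(object) {
  cat(sprintf("SliceContour %s @ %.2f mm anterior: %d vertices, %.2f mm arc\n",
              object@caseId, object@sliceDistance, nrow(object@points),
              sum(sqrt(rowSums(diff(object@points)^2)))))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet @ %.2f mm (CS depth %.2f mm, contour %.2f mm):\n",
              object@sliceDistance, object@csDepth, object@contourLength))
  print(round(object@positions, 3))
})

setMethod("show", "RuleTable", function(object) {
  cat(sprintf(
    "RuleTable (anchor: %s, thickness %.2f mm, posterior bound %.2f mm)\n",
    object@anchor, object@sliceThickness, object@posteriorBound))
  cat("starts:", paste(sprintf("%s %.1f", names(object@starts)[
    match(.REGIONS, names(object@starts))], object@starts[.REGIONS]),
    collapse = ", "), "mm\n")
  cat("levels:", paste(object@levels, collapse = ", "), "mm;",
      nrow(object@rules), "border rules,",
      nrow(object@flank), "flank rule(s)\n")
})

setMethod("show", "LabelMap", function(object) {
  iv <- object@intervals
  cat(sprintf("LabelMap %s: %d intervals on %d slices\n", object@caseId,
              nrow(iv), length(unique(iv$slice_distance_mm))))
  if (nrow(iv)) {
    len <- tapply((iv$s_end - iv$s_start), iv$label, sum)
    cat("total ribbon length (mm):",
        paste(sprintf("%s %.1f", names(len), len), collapse = ", "), "\n")
  }
})

setMethod("show", "CasePhantom", function(object) {
  cat(sprintf("CasePhantom %s (%s, %s CS %.1f mm%s)\n", object@caseId,
              object@hemisphere, object@csDepthClass, object@csDepth,
              if (object@diseaseGroup) ", disease" else ""))
  cat("extents (mm anterior to hippocampus):",
      paste(sprintf("%s %.2f", .REGIONS, object@extents[.REGIONS]),
            collapse = ", "), "\n")
})

setMethod("show", "MTLCohort", function(object) {
  cat(sprintf("MTLCohort: %d cases, %s, %d truth borders (%d clamped)\n",
              length(object@cases),
              if (length(object@stacks)) sprintf(
                "%d contour stacks", length(object@stacks)) else "no contours",
              nrow(object@truth), object@clamped))
})
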