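#' Accessors for mtlseg classes
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{caseId} (identifier), \code{sliceDistance} (mm anterior to the
#' hippocampus tip), \code{contourPoints} (vertex matrix),
#' \code{keyVertices} (named indices), \code{landmarkPositions} (named
#' arc-length positions), \code{labelIntervals} (interval table),
#' \code{ruleStarts} (region start distances), \code{cohortCases},
#' \code{cohortStacks}, \code{cohortTruth} (cohort components).
#'
#' @param x an mtlseg object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setGeneric("sliceDistance", function(x) standardGeneric("sliceDistance"))
#' @rdname accessors
#' @export
setGeneric("contourPoints", function(x) standardGeneric("contourPoints"))
#' @rdname accessors
#' @export
setGeneric("keyVertices", function(x) standardGeneric("keyVertices"))
#' @rdname accessors
#' @export
setGeneric("landmarkPositions", function(x) standardGeneric("landmarkPositions"))
#' @rdname accessors
#' @export
setGeneric("labelIntervals", function(x) standardGeneric("labelIntervals"))
#' @rdname accessors
#' @export
setGeneric("ruleStarts", function(x) standardGeneric("ruleStarts"))
#' @rdname accessors
#' @export
setGeneric("cohortCases", function(x) standardGeneric("cohortCases"))
#' @rdname accessors
#' @export
setGeneric("cohortStacks", function(x) standardGeneric("cohortStacks"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname accessors
setMethod("caseId", "SliceContour", function(x) x@caseId)
#' @rdname accessors
setMethod("caseId", "LabelMap", function(x) x@caseId)
#' @rdname accessors
setMethod("caseId", "CasePhantom", function(x) x@caseId)
#' @rdname accessors
setMethod("sliceDistance", "SliceContour", function(x) x@sliceDistance)
#' @rdname accessors
setMethod("sliceDistance", "LandmarkSet", function(x) x@sliceDistance)
#' @rdname accessors
setMethod("contourPoints", "SliceContour", function(x) x@points)
#' @rdname accessors
setMethod("keyVertices", "SliceContour", function(x) x@keyVertices)
#' @rdname accessors
setMethod("landmarkPositions", "LandmarkSet", function(x) x@positions)
#' @rdname accessors
setMethod("labelIntervals", "LabelMap", function(x) x@intervals)
#' @rdname accessors
setMethod("ruleStarts", "RuleTable", function(x) x@starts[.REGIONS])
#' @rdname accessors
setMethod("cohortCases", "MTLCohort", function(x) x@cases)
#' @rdname accessors
setMethod("cohortStacks", "MTLCohort", function(x) x@stacks)
#' @rdname accessors
setMethod("cohortTruth", "MTLCohort", function(x) x@truth)

#' Dice Similarity Index between two segmentations
#'
#' Computes \eqn{DSI = 2|A \cap B| / (|A| + |B|)} for one label, either in
#' interval mode (two \code{\linkS4class{LabelMap}} objects; the measure is
#' total arc length of the labeled intervals) or in raster mode (two
#' integer label arrays of identical dimension; the measure is voxel
#' counts).  When the label is empty in both inputs the DSI is defined as
#' 1 and the result carries attribute \code{bothEmpty = TRUE}.
#'
#' @param a,b two segmentations of the same geometry domain.
#' @param label label name ("ERC", "BA35", "BA36") in interval mode, or
#'   label name/integer code in raster mode.
#' @return numeric DSI in [0, 1]; attributes \code{sizeA}, \code{sizeB}
#'   carry the two input measures (mm of ribbon, or voxel counts).
#' @examples
#' iv <- function(s0, s1) data.frame(slice_distance_mm = 2.6, s_start = s0,
#'   s_end = s1, label = "ERC", segment = "primary")
#' dsi(LabelMap("c", iv(0, 4)), LabelMap("c", iv(2, 6)), "ERC")  # 0.5
#' @export
setGeneric("dsi", function(a, b, label) standardGeneric("dsi"))
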