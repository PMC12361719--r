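#' Cumulative arc length along a contour
#'
#' Arc-length position of every vertex of the polyline, in mm from the
#' medial terminus.  This parameterization underlies all landmark and
#' border positions: borders live on the cortical ribbon, so distances
#' along the pial contour, not Euclidean chords, are the protocol's
#' currency.
#'
#' @param contour a \code{\linkS4class{SliceContour}}.
#' @return numeric vector, one entry per vertex, starting at 0 and
#'   monotonically increasing; the last entry is the total contour length.
#' @examples
#' pts <- cbind(c(0, 0, 0, 6, 10, 14, 18, 22), c(-13, -6, 0, 0, -3, 0, 0, 0))
#' kv <- c(medial_terminus = 1L, phg_superior_edge = 3L, cs_medial_mouth = 4L,
#'         cs_fundus = 5L, cs_lateral_mouth = 6L, fg_crown_apex = 7L,
#'         lateral_terminus = 8L)
#' arcLengthPositions(SliceContour("c", 5.2, pts, kv))
#' @export
arcLengthPositions <- function(contour) {
  p <- contour@points
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg <= 0))
    stopf("mtlseg_malformed_contour",
          "duplicate consecutive vertices at index %d", which(seg <= 0)[1])
  c(0, cumsum(seg))
}

#' Total arc length of a contour
#' @param contour a \code{\linkS4class{SliceContour}}.
#' @return total polyline length (mm).
#' @export
totalArcLength <- function(contour) {
  p <- contour@points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Coordinate at an arc-length position
#'
#' Linear interpolation along the polyline; an \code{s} falling exactly at
#' a vertex returns that vertex.
#'
#' @param contour a \code{\linkS4class{SliceContour}}.
#' @param s arc-length position(s) in mm, each within
#'   \code{[0, totalArcLength(contour)]}.
#' @return numeric matrix (length(s) x 2) of coordinates (mm).
#' @export
pointAtArcLength <- function(contour, s) {
  cum <- arcLengthPositions(contour)
  L <- cum[length(cum)]
  if (any(s < -1e-9) || any(s > L + 1e-9))
    stopf("mtlseg_out_of_domain",
          "arc length %.6f mm outside [0, %.6f]",
          s[which(s < -1e-9 | s > L + 1e-9)[1]], L)
  s <- pmin(pmax(s, 0), L)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(cum) - 1L)
  t <- (s - cum[i]) / (cum[i + 1L] - cum[i])
  p <- contour@points
  p[i, , drop = FALSE] * (1 - t) + p[i + 1L, , drop = FALSE] * t
}

#' Collateral sulcus depth
#'
#' Depth of the collateral sulcus on one slice: the Euclidean distance
#' from the fundus vertex to the midpoint of the straight chord joining
#' the two sulcal mouth vertices.
#'
#' @param contour a \code{\linkS4class{SliceContour}} with CS key vertices.
#' @return depth in mm (>= 0).
#' @export
csDepth <- function(contour) {
  kv <- contour@keyVertices
  p <- contour@points
  f <- p[kv[["cs_fundus"]], ]
  m1 <- p[kv[["cs_medial_mouth"]], ]
  m2 <- p[kv[["cs_lateral_mouth"]], ]
  if (f[2] >= m1[2] && f[2] >= m2[2])
    stopf("mtlseg_malformed_sulcus",
          "cs_fundus lies superior to both CS mouths")
  mid <- (m1 + m2) / 2
  sqrt(sum((f - mid)^2))
}

#' Classify collateral sulcus depth
#'
#' Dichotomizes CS depth at the conventional 7 mm cut measured at the
#' hippocampus-tip level: depths strictly below 7 mm are shallow, 7 mm
#' and above are deep.
#'
#' @param depth_mm CS depth (mm, >= 0); vectorized.
#' @param threshold_mm dichotomization threshold, default 7.
#' @return character vector, "shallow" or "deep".
#' @examples
#' classifyCSDepth(c(6.9, 7, 12))
#' @export
classifyCSDepth <- function(depth_mm, threshold_mm = 7) {
  if (any(!is.finite(depth_mm)) || any(depth_mm < 0))
    stopf("mtlseg_domain", "CS depth must be finite and >= 0")
  ifelse(depth_mm < threshold_mm, "shallow", "deep")
}

#' Mirror a contour across the vertical axis
#'
#' Reflects the coronal coordinates about a vertical axis (lateral
#' coordinate negated and shifted back over the original span), keeping
#' the vertex order along the ribbon and the key-vertex tags.  Used to
#' bring right-hemisphere acquisitions into the canonical medial-first
#' orientation; arc lengths and hence all landmark and border positions
#' are invariant under this reflection.
#'
#' @param contour a \code{\linkS4class{SliceContour}}.
#' @return the reflected \code{SliceContour}.
#' @export
mirrorContour <- function(contour) {
  p <- contour@points
  p[, 1] <- max(p[, 1]) + min(p[, 1]) - p[, 1]
  SliceContour(contour@caseId, contour@sliceDistance, p, contour@keyVertices)
}
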