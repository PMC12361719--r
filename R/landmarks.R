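#' Derive all protocol landmarks on one slice
#'
#' Computes the eight protocol landmark positions on the contour, by arc
#' length from the medial terminus:
#' \itemize{
#'   \item \code{s_phg_superior_edge}: the tagged superior PHG edge vertex;
#'   \item \code{s_phg_crown_midpoint}: arc-length midpoint of the PHG
#'     crown, i.e. between the superior PHG edge and the medial CS mouth;
#'   \item \code{s_cs_medial_edge}: the medial mouth of the CS;
#'   \item \code{s_medial_bank_half}: arc-length halfway point of the
#'     medial bank of the CS (medial mouth to fundus);
#'   \item \code{s_cs_fundus}: the CS fundus;
#'   \item \code{s_lateral_bank_quarter}: the quarter point of the lateral
#'     bank closest to the fundus (fundus + 1/4 of the fundus-to-lateral-
#'     mouth arc);
#'   \item \code{s_fg_crown_midpoint}: arc-length midpoint of the fusiform
#'     crown, i.e. between the lateral CS mouth and the lateral terminus;
#'   \item \code{s_fundus_fg_midpoint}: arc-length midpoint between the CS
#'     fundus and the FG crown midpoint.
#' }
#' Bank and crown fractions are taken along the pial contour (arc length),
#' not along Euclidean chords, because the borders being placed live on
#' the cortical ribbon.
#'
#' @param contour a \code{\linkS4class{SliceContour}} with all seven key
#'   vertices tagged.
#' @return a \code{\linkS4class{LandmarkSet}}.
#' @examples
#' pts <- cbind(c(0, 0, 0, 6, 10, 14, 18, 22), c(-13, -6, 0, 0, -3, 0, 0, 0))
#' kv <- c(medial_terminus = 1L, phg_superior_edge = 3L, cs_medial_mouth = 4L,
#'         cs_fundus = 5L, cs_lateral_mouth = 6L, fg_crown_apex = 7L,
#'         lateral_terminus = 8L)
#' deriveLandmarks(SliceContour("c", 5.2, pts, kv))
#' @export
deriveLandmarks <- function(contour) {
  kv <- contour@keyVertices
  missing <- setdiff(.KEY_VERTICES, names(kv)[!is.na(kv)])
  if (length(missing))
    stopf("mtlseg_missing_landmark",
          "missing key vertex: %s", missing[1])
  cum <- arcLengthPositions(contour)
  at <- function(name) cum[kv[[name]]]

  s_sup <- at("phg_superior_edge")
  s_cme <- at("cs_medial_mouth")
  s_fun <- at("cs_fundus")
  s_clm <- at("cs_lateral_mouth")
  s_lat <- at("lateral_terminus")

  s_fg_crown <- (s_clm + s_lat) / 2
  pos <- c(
    s_phg_superior_edge   = s_sup,
    s_phg_crown_midpoint  = (s_sup + s_cme) / 2,
    s_cs_medial_edge      = s_cme,
    s_medial_bank_half    = (s_cme + s_fun) / 2,
    s_cs_fundus           = s_fun,
    s_lateral_bank_quarter = s_fun + 0.25 * (s_clm - s_fun),
    s_fundus_fg_midpoint  = (s_fun + s_fg_crown) / 2,
    s_fg_crown_midpoint   = s_fg_crown
  )
  LandmarkSet(pos, csDepth(contour), contour@sliceDistance,
              cum[length(cum)])
}

#' CS depth stored on a LandmarkSet
#' @param landmarks a \code{\linkS4class{LandmarkSet}}.
#' @return CS depth (mm).
#' @export
landmarkCSDepth <- function(landmarks) landmarks@csDepth

#' Contour length stored on a LandmarkSet
#' @param landmarks a \code{\linkS4class{LandmarkSet}}.
#' @return total arc length of the source contour (mm).
#' @export
landmarkContourLength <- function(landmarks) landmarks@contourLength
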