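## Parametric coronal contour for the phantom: medial temporal pial
## surface from the medial terminus over the PHG crown, down and up the
## collateral sulcus, across the fusiform crown to the lateral terminus.

## Shape parameter vector sampled once per case (all mm):
##   h_med   arc height of the medial PHG surface (>= 13 so that medial
##           offsets up to 10 mm from the superior PHG edge stay on-contour)
##   w_phg   PHG crown width (superior edge to medial CS mouth)
##   w_cs    separation of the CS mouths
##   depth   CS depth (fundus to mouth-chord midpoint)
##   theta   fundus tilt off vertical (radians; asymmetric sulcus)
##   w_fg    fusiform crown width (lateral CS mouth to lateral terminus)
##   apex_h  height of the FG crown apex
##   bow     perpendicular bowing of the sulcal banks
##   stack_max / slice_thickness: slice-stack extent bookkeeping

.buildContourPoints <- function(shape) {
  h <- shape[["h_med"]]
  w1 <- shape[["w_phg"]]
  wc <- shape[["w_cs"]]
  d <- shape[["depth"]]
  th <- shape[["theta"]]
  wf <- shape[["w_fg"]]
  ah <- shape[["apex_h"]]
  bow <- shape[["bow"]]

  pts <- list()
  key <- integer()
  add <- function(x, y, name = NULL) {
    pts[[length(pts) + 1L]] <<- c(x, y)
    if (!is.null(name)) key[[name]] <<- length(pts)
  }

  ## medial PHG surface, terminus -> superior edge at the origin
  add(-2.0, -h, "medial_terminus")
  add(-1.8, -0.85 * h)
  add(-1.2, -0.60 * h)
  add(-0.5, -0.30 * h)
  add(0, 0, "phg_superior_edge")

  ## PHG crown arch to the medial CS mouth
  add(0.30 * w1, 0.5)
  add(0.70 * w1, 0.35)
  m1 <- c(w1, -0.8)
  add(m1[1], m1[2], "cs_medial_mouth")

  ## collateral sulcus: fundus at exactly `depth` from the mouth-chord
  ## midpoint, tilted by theta
  m2 <- c(w1 + wc, -0.8)
  mid <- (m1 + m2) / 2
  f <- mid + d * c(sin(th), -cos(th))
  bank <- function(a, b, sgn) {
    dir <- b - a
    n <- c(dir[2], -dir[1])
    n <- sgn * n / sqrt(sum(n^2))
    for (t in c(1 / 3, 2 / 3)) {
      p <- a + t * dir + bow * sin(pi * t) * n
      add(p[1], p[2])
    }
  }
  bank(m1, f, 1)               # medial bank bows into the gyral wall
  add(f[1], f[2], "cs_fundus")
  bank(f, m2, 1)               # lateral bank bows outward as well
  add(m2[1], m2[2], "cs_lateral_mouth")

  ## fusiform crown over the apex to the lateral terminus
  add(m2[1] + 0.20 * wf, 0.0)
  add(m2[1] + 0.50 * wf, ah, "fg_crown_apex")
  add(m2[1] + 0.80 * wf, 0.2 * ah)
  add(m2[1] + wf, -1.2, "lateral_terminus")

  list(points = do.call(rbind, pts), key = key)
}

#' Build the coronal contour of a phantom case at one slice
#'
#' Draws the case's pial contour (all seven key vertices tagged) at the
#' requested slice.  The phantom keeps the in-plane anatomy constant
#' along the anterior-posterior axis, so the collateral sulcus depth at
#' every slice, including the hippocampus-tip level, equals the case's
#' sampled depth.
#'
#' @param case a \code{\linkS4class{CasePhantom}}.
#' @param slice_distance_mm slice distance (mm anterior to the
#'   hippocampus tip); must lie within the case's stack range.
#' @return a \code{\linkS4class{SliceContour}}.
#' @export
buildSliceContour <- function(case, slice_distance_mm) {
  sh <- case@shape
  lo <- sh[["slice_thickness"]] - 1e-6
  hi <- sh[["stack_max"]] + 1e-6
  if (slice_distance_mm < lo || slice_distance_mm > hi)
    stopf("mtlseg_range",
          "slice %.2f mm outside the case's stack range [%.2f, %.2f]",
          slice_distance_mm, sh[["slice_thickness"]], sh[["stack_max"]])
  built <- .buildContourPoints(sh)
  SliceContour(case@caseId, slice_distance_mm, built$points, built$key)
}
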