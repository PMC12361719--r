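#' Rasterize an interval label map onto a voxel grid
#'
#' Paints each labeled arc-length interval as a band of the stated ribbon
#' thickness centered on the contour, on a common in-plane grid covering
#' all slices.  Every voxel is assigned to at most one label — the label
#' of the nearest arc-length sample within half the ribbon thickness —
#' so adjacent intervals never double-label a voxel.  Label codes are
#' fixed (ERC 1, BA35 2, BA36 3) and stable across runs.
#'
#' @param labelmap a \code{\linkS4class{LabelMap}}.
#' @param stack list of \code{\linkS4class{SliceContour}} objects
#'   covering the label map's slices.
#' @param resolution_mm in-plane voxel size (mm, > 0).
#' @param ribbon_mm ribbon (cortical band) thickness (mm), default 1.
#' @return an object of class \code{mtlseg_raster}: list with
#'   \code{array} (integer array nx x ny x nslices, 0 = background),
#'   \code{origin}, \code{resolution_mm}, \code{ribbon_mm},
#'   \code{slice_distances}, \code{codes}.
#' @export
rasterizeLabels <- function(labelmap, stack, resolution_mm,
                            ribbon_mm = 1) {
  if (!is.finite(resolution_mm) || resolution_mm <= 0)
    stopf("mtlseg_domain", "resolution must be > 0")
  if (resolution_mm > ribbon_mm)
    warnf("mtlseg_resolution",
          "resolution (%.2f mm) is coarser than the ribbon thickness (%.2f mm)",
          resolution_mm, ribbon_mm)
  dists <- vapply(stack, sliceDistance, numeric(1))
  iv <- labelmap@intervals
  slice_d <- sort(unique(iv$slice_distance_mm))

  pts_all <- do.call(rbind, lapply(stack, contourPoints))
  margin <- ribbon_mm / 2 + resolution_mm
  if (is.null(pts_all)) pts_all <- matrix(0, 1, 2)
  x0 <- floor((min(pts_all[, 1]) - margin) / resolution_mm) * resolution_mm
  y0 <- floor((min(pts_all[, 2]) - margin) / resolution_mm) * resolution_mm
  nx <- ceiling((max(pts_all[, 1]) + margin - x0) / resolution_mm)
  ny <- ceiling((max(pts_all[, 2]) + margin - y0) / resolution_mm)
  xc <- x0 + (seq_len(nx) - 0.5) * resolution_mm
  yc <- y0 + (seq_len(ny) - 0.5) * resolution_mm

  nsl <- max(length(slice_d), 1L)
  arr <- array(0L, dim = c(nx, ny, nsl))
  half <- ribbon_mm / 2
  step <- resolution_mm / 4

  for (k in seq_along(slice_d)) {
    d <- slice_d[k]
    ci <- which(abs(dists - d) < 1e-6)
    if (length(ci) == 0)
      stopf("mtlseg_pairing", "no contour for labeled slice %.2f mm", d)
    contour <- stack[[ci[1]]]
    sl <- iv[abs(iv$slice_distance_mm - d) < 1e-9, , drop = FALSE]
    best <- matrix(Inf, nx, ny)
    lab <- matrix(0L, nx, ny)
    for (j in seq_len(nrow(sl))) {
      svals <- seq(sl$s_start[j], sl$s_end[j], by = step)
      if (svals[length(svals)] < sl$s_end[j])
        svals <- c(svals, sl$s_end[j])
      pts <- pointAtArcLength(contour, svals)
      code <- .LABEL_CODES[[sl$label[j]]]
      ## bounding window of this interval, in voxel indices
      ix <- which(xc >= min(pts[, 1]) - half - resolution_mm &
                    xc <= max(pts[, 1]) + half + resolution_mm)
      iy <- which(yc >= min(pts[, 2]) - half - resolution_mm &
                    yc <= max(pts[, 2]) + half + resolution_mm)
      if (!length(ix) || !length(iy)) next
      dx2 <- outer(xc[ix], pts[, 1], "-")^2
      dy2 <- outer(yc[iy], pts[, 2], "-")^2
      for (a in seq_along(ix)) {
        dmin <- sqrt(apply(dy2 + matrix(dx2[a, ], nrow = length(iy),
                                        ncol = ncol(dy2), byrow = TRUE),
                           1, min))
        upd <- dmin <= half & dmin < best[ix[a], iy]
        if (any(upd)) {
          best[ix[a], iy[upd]] <- dmin[upd]
          lab[ix[a], iy[upd]] <- code
        }
      }
    }
    arr[, , k] <- lab
  }
  structure(list(array = arr, origin = c(x0, y0),
                 resolution_mm = resolution_mm, ribbon_mm = ribbon_mm,
                 slice_distances = slice_d, codes = .LABEL_CODES),
            class = "mtlseg_raster")
}

#' @export
print.mtlseg_raster <- function(x, ...) {
  cat(sprintf("mtlseg raster: %s voxels @ %.2f mm, %d slice(s)\n",
              paste(dim(x$array), collapse = " x "), x$resolution_mm,
              length(x$slice_distances)))
  tab <- table(factor(x$array[x$array > 0], levels = x$codes,
                      labels = names(x$codes)))
  if (sum(tab)) print(tab)
  invisible(x)
}

#' Fixed label colors of the protocol
#'
#' @return data.frame with columns index, label, r, g, b: green ERC,
#'   light blue BA35, dark blue BA36.
#' @export
labelColorTable <- function() {
  data.frame(index = unname(.LABEL_CODES), label = names(.LABEL_CODES),
             r = .LABEL_COLORS[, 1], g = .LABEL_COLORS[, 2],
             b = .LABEL_COLORS[, 3], row.names = NULL,
             stringsAsFactors = FALSE)
}
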