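## Reliability evaluation: Dice overlap, label measures, landmark
## perturbation, group comparison.

## total length of the union of intervals (2-column matrix start, end)
.mergeLength <- function(m) {
  if (nrow(m) == 0) return(0)
  m <- m[order(m[, 1]), , drop = FALSE]
  tot <- 0
  cur <- as.numeric(m[1, ])
  for (k in seq_len(nrow(m))[-1]) {
    if (m[k, 1] <= cur[2]) cur[2] <- max(cur[2], m[k, 2])
    else { tot <- tot + cur[2] - cur[1]; cur <- as.numeric(m[k, ]) }
  }
  unname(tot + cur[2] - cur[1])
}

## total length of the intersection of two interval unions
.intersectLength <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) tot <- tot + hi - lo
  }
  tot
}

.labelIntervalsOn <- function(map, label, d) {
  iv <- map@intervals
  sel <- iv$label == label & abs(iv$slice_distance_mm - d) < 1e-9
  as.matrix(iv[sel, c("s_start", "s_end"), drop = FALSE])
}

#' @describeIn dsi interval mode: the measure is total labeled arc
#'   length, accumulated over the union of slices of the two maps.
#' @export
setMethod("dsi", signature("LabelMap", "LabelMap"),
  function(a, b, label) {
    slices <- sort(unique(c(a@intervals$slice_distance_mm,
                            b@intervals$slice_distance_mm)))
    sizeA <- sizeB <- inter <- 0
    for (d in slices) {
      ia <- .labelIntervalsOn(a, label, d)
      ib <- .labelIntervalsOn(b, label, d)
      sizeA <- sizeA + .mergeLength(ia)
      sizeB <- sizeB + .mergeLength(ib)
      inter <- inter + .intersectLength(ia, ib)
    }
    if (sizeA + sizeB == 0)
      return(structure(1, bothEmpty = TRUE, sizeA = 0, sizeB = 0))
    structure(2 * inter / (sizeA + sizeB), sizeA = sizeA, sizeB = sizeB)
  })

#' @describeIn dsi raster mode: two integer label arrays of identical
#'   dimension; the measure is voxel counts.
#' @export
setMethod("dsi", signature("array", "array"),
  function(a, b, label) {
    if (!identical(dim(a), dim(b)))
      stopf("mtlseg_pairing", "raster dimensions differ")
    code <- if (is.character(label)) .LABEL_CODES[[label]] else label
    inA <- a == code
    inB <- b == code
    sizeA <- sum(inA); sizeB <- sum(inB)
    if (sizeA + sizeB == 0)
      return(structure(1, bothEmpty = TRUE, sizeA = 0, sizeB = 0))
    structure(2 * sum(inA & inB) / (sizeA + sizeB),
              sizeA = sizeA, sizeB = sizeB)
  })

#' Ribbon area / volume of one label
#'
#' Sum over slices of labeled interval length times the slice spacing
#' (ribbon area, mm^2); multiplied by a ribbon thickness it becomes a
#' volume proxy (mm^3).
#'
#' @param labelmap a \code{\linkS4class{LabelMap}}.
#' @param label label name.
#' @param slice_spacing_mm slice spacing (mm).
#' @param ribbon_mm optional ribbon thickness; if given, returns volume.
#' @return area (mm^2) or volume (mm^3).
#' @examples
#' lm <- LabelMap("c", data.frame(slice_distance_mm = 2.6, s_start = 0,
#'   s_end = 10, label = "ERC", segment = "primary"))
#' labelMeasure(lm, "ERC", 1.3)  # 13
#' @export
labelMeasure <- function(labelmap, label, slice_spacing_mm,
                         ribbon_mm = NULL) {
  iv <- labelmap@intervals
  iv <- iv[iv$label == label, , drop = FALSE]
  area <- sum(iv$s_end - iv$s_start) * slice_spacing_mm
  if (is.null(ribbon_mm)) area else area * ribbon_mm
}

#' Perturb a landmark set
#'
#' Jitters each landmark position by an independent Gaussian of SD
#' \code{sigma_mm}, then restores the ordering invariant by sorting the
#' jittered positions (reassigned in canonical medial-to-lateral order)
#' and clamping to the contour domain.  Stands in for re-tracing
#' variability of a human rater.  Draws from the current RNG stream.
#'
#' @param landmarks a \code{\linkS4class{LandmarkSet}}.
#' @param sigma_mm jitter SD (mm, >= 0).
#' @return a perturbed \code{\linkS4class{LandmarkSet}}.
#' @export
perturbLandmarks <- function(landmarks, sigma_mm) {
  if (!is.finite(sigma_mm) || sigma_mm < 0)
    stopf("mtlseg_domain", "sigma must be >= 0")
  s <- landmarks@positions
  if (sigma_mm > 0) {
    s <- s + stats::rnorm(length(s), 0, sigma_mm)
    s <- sort(s)
    names(s) <- .LANDMARKS
    s <- pmin(pmax(s, 0), landmarks@contourLength)
  }
  LandmarkSet(s, landmarks@csDepth, landmarks@sliceDistance,
              landmarks@contourLength)
}

#' Landmark-perturbation reliability experiment
#'
#' For each case of the cohort, segments once with the true landmark
#' sets and repeatedly with perturbed landmark sets at each jitter SD,
#' and summarizes the Dice Similarity Index per label.  At sigma = 0 the
#' engine is deterministic and every DSI is exactly 1; mean DSI is
#' expected to be non-increasing in sigma, and the summary reports
#' whether that monotonicity holds.  This is a methodological stand-in
#' for a second manual trace, not a replication of rater reliability on
#' real MRI.
#'
#' @param cohort an \code{\linkS4class{MTLCohort}} built with contours.
#' @param rule_table a \code{\linkS4class{RuleTable}}.
#' @param sigma_mm numeric vector of jitter SDs (mm).
#' @param n_reps perturbation repetitions per case and sigma.
#' @param seed RNG seed for the perturbations.
#' @return data.frame (sigma_mm, label, mean_dsi, sd_dsi, n) with
#'   attributes \code{per_case} (case-level DSIs) and \code{monotone}
#'   (named logical per label).
#' @export
reliabilityExperiment <- function(cohort, rule_table, sigma_mm = c(0, 0.5),
                                  n_reps = 5, seed = 1) {
  if (length(cohort@stacks) == 0)
    stopf("mtlseg_input", "cohort has no contour stacks")
  th <- rule_table@sliceThickness
  grid <- seq(rule_table@posteriorBound,
              max(rule_table@starts[.REGIONS]) + 1e-9, by = th)
  rows <- withSeed(seed, {
    acc <- list()
    for (cid in names(cohort@stacks)) {
      stack <- cohort@stacks[[cid]]
      dists <- vapply(stack, sliceDistance, numeric(1))
      lms <- lapply(grid, function(d) {
        i <- which(abs(dists - d) < 1e-6)
        if (!length(i))
          stopf("mtlseg_gap", "case %s missing slice %.1f mm", cid, d)
        deriveLandmarks(stack[[i[1]]])
      })
      ref <- .segmentFromLandmarks(cid, lms, rule_table)
      for (sg in sigma_mm) for (rep in seq_len(n_reps)) {
        plms <- lapply(lms, perturbLandmarks, sigma_mm = sg)
        alt <- .segmentFromLandmarks(cid, plms, rule_table)
        for (label in .REGIONS) {
          acc[[length(acc) + 1L]] <- data.frame(
            case_id = cid, sigma_mm = sg, rep = rep, label = label,
            dsi = as.numeric(dsi(ref, alt, label)),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, acc)
  })
  agg <- do.call(rbind, lapply(split(
    rows, list(rows$sigma_mm, rows$label), drop = TRUE), function(g)
      data.frame(sigma_mm = g$sigma_mm[1], label = g$label[1],
                 mean_dsi = mean(g$dsi),
                 sd_dsi = if (nrow(g) > 1) stats::sd(g$dsi) else 0,
                 n = nrow(g), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$label, agg$sigma_mm), ]
  rownames(agg) <- NULL
  mono <- vapply(split(agg, agg$label), function(g)
    all(diff(g$mean_dsi[order(g$sigma_mm)]) <= 1e-9), logical(1))
  attr(agg, "per_case") <- rows
  attr(agg, "monotone") <- mono
  agg
}

#' Descriptive group comparison of label measures
#'
#' Per-group n, median and SD plus the median difference.  The stratified
#' protocol checks were descriptive, so no inferential test is run by
#' default; \code{test = TRUE} adds a Wilcoxon rank-sum test.
#'
#' @param values numeric measurements (e.g. label volumes), one per case.
#' @param group two-level grouping (e.g. shallow vs deep CS).
#' @param test if TRUE, append a Wilcoxon rank-sum p-value.
#' @return list with \code{groups} (data.frame group, n, median, sd),
#'   \code{difference} (median difference, first minus second level) and
#'   optionally \code{p_value}.
#' @export
compareGroups <- function(values, group, test = FALSE) {
  group <- factor(group)
  if (nlevels(group) != 2)
    stopf("mtlseg_input", "grouping must have exactly two levels")
  if (any(table(group) < 2))
    stopf("mtlseg_input", "need at least 2 cases per group")
  g <- data.frame(
    group = levels(group),
    n = as.integer(table(group)),
    median = as.numeric(tapply(values, group, stats::median)),
    sd = as.numeric(tapply(values, group, stats::sd)),
    stringsAsFactors = FALSE)
  out <- list(groups = g, difference = g$median[1] - g$median[2])
  if (test)
    out$p_value <- stats::wilcox.test(values ~ group, exact = FALSE)$p.value
  out
}
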