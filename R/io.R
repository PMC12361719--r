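## Structured-text readers and writers: contour slice stacks and rule
## tables as YAML documents, border/label tables as TSV, ITK-SNAP label
## description files, optional NIfTI raster export.

#' Write a contour slice stack
#'
#' One YAML document per case: case metadata, then per slice the
#' distance, the vertex array and the key-vertex map.
#'
#' @param stack list of \code{\linkS4class{SliceContour}} for one case.
#' @param file output path.
#' @param hemisphere optional hemisphere tag ("L"/"R") stored as
#'   metadata.
#' @return invisibly, the file path.
#' @export
writeContourStack <- function(stack, file, hemisphere = NA) {
  doc <- list(
    format = "mtlseg-contours", version = 1L,
    case_id = caseId(stack[[1]]),
    hemisphere = if (is.na(hemisphere)) NULL else hemisphere,
    slices = lapply(stack, function(ct) list(
      slice_distance_mm = sliceDistance(ct),
      points = apply(contourPoints(ct), 1, function(r)
        list(as.numeric(r[1]), as.numeric(r[2])), simplify = FALSE),
      key_vertices = as.list(keyVertices(ct))
    ))
  )
  yaml::write_yaml(doc, file, precision = 12)
  invisible(file)
}

#' Read a contour slice stack
#'
#' Reads and validates a contour slice-stack file; every contour
#' invariant is checked and the first violation is reported with its
#' slice index.
#'
#' @param file path to a file written by \code{\link{writeContourStack}}.
#' @return list of \code{\linkS4class{SliceContour}}, with attribute
#'   \code{hemisphere} when present in the file.
#' @export
readContourStack <- function(file) {
  doc <- yaml::read_yaml(file)
  if (!identical(doc$format, "mtlseg-contours"))
    stopf("mtlseg_invalid_input", "%s: not a contour slice-stack file", file)
  stack <- vector("list", length(doc$slices))
  for (i in seq_along(doc$slices)) {
    sl <- doc$slices[[i]]
    pts <- do.call(rbind, lapply(sl$points, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    ct <- tryCatch(
      SliceContour(doc$case_id, sl$slice_distance_mm, pts,
                   unlist(sl$key_vertices)),
      error = function(e) stopf("mtlseg_invalid_input",
                                "slice %d: %s", i, conditionMessage(e)))
    stack[[i]] <- ct
  }
  if (!is.null(doc$hemisphere)) attr(stack, "hemisphere") <- doc$hemisphere
  stack
}

#' Write a rule table
#'
#' Serializes a \code{\linkS4class{RuleTable}} as a schema-versioned
#' YAML document.
#'
#' @param rule_table a \code{\linkS4class{RuleTable}}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeRuleTable <- function(rule_table, file) {
  df2list <- function(df) lapply(seq_len(nrow(df)), function(k) {
    row <- as.list(df[k, ])
    row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
  })
  doc <- list(
    format = "mtlseg-rules", version = 1L,
    slice_thickness_mm = rule_table@sliceThickness,
    anchor = rule_table@anchor,
    starts = as.list(rule_table@starts[.REGIONS]),
    levels = as.numeric(rule_table@levels),
    posterior_bound_mm = rule_table@posteriorBound,
    rules = df2list(rule_table@rules),
    flank = df2list(rule_table@flank),
    provenance = rule_table@provenance
  )
  yaml::write_yaml(doc, file, precision = 12)
  invisible(file)
}

#' Read a rule table
#' @param file path to a file written by \code{\link{writeRuleTable}}.
#' @return a validated \code{\linkS4class{RuleTable}}.
#' @export
readRuleTable <- function(file) {
  doc <- yaml::read_yaml(file)
  if (!identical(doc$format, "mtlseg-rules"))
    stopf("mtlseg_invalid_input", "%s: not a rule-table file", file)
  list2df <- function(lst, cols) {
    if (length(lst) == 0)
      return(as.data.frame(stats::setNames(
        rep(list(logical(0)), length(cols)), cols)))
    do.call(rbind, lapply(lst, function(row) {
      for (cn in cols) if (is.null(row[[cn]])) row[[cn]] <- NA
      as.data.frame(row[cols], stringsAsFactors = FALSE)
    }))
  }
  rules <- list2df(doc$rules, c("level", "region", "side", "landmark",
                                "offset_mm", "direction", "reference"))
  rules$offset_mm[is.na(rules$offset_mm)] <- 0
  flank <- list2df(doc$flank, c("level", "landmark", "offset_mm",
                                "direction"))
  ruleTable(doc$slice_thickness_mm, doc$anchor,
            unlist(doc$starts)[.REGIONS], as.numeric(doc$levels), rules,
            flank, doc$posterior_bound_mm, doc$provenance %||% list())
}

#' Write a label map as a tab-separated interval table
#' @param labelmap a \code{\linkS4class{LabelMap}}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeLabelMap <- function(labelmap, file) {
  iv <- cbind(case_id = labelmap@caseId, labelmap@intervals)
  utils::write.table(iv, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a label map interval table
#' @param file path to a file written by \code{\link{writeLabelMap}}.
#' @return a \code{\linkS4class{LabelMap}} (first case in the file).
#' @export
readLabelMap <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  LabelMap(df$case_id[1], df[, c("slice_distance_mm", "s_start", "s_end",
                                 "label", "segment")])
}

#' Write a ground-truth border table
#' @param truth data.frame of border annotations (as in
#'   \code{cohortTruth}).
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeBorderTable <- function(truth, file) {
  utils::write.table(truth, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a ground-truth border table
#' @param file path to a file written by \code{\link{writeBorderTable}}.
#' @return data.frame of border annotations.
#' @export
readBorderTable <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write an ITK-SNAP label description file
#'
#' The standard label description format (index, RGB, alpha, visibility,
#' mesh visibility, name) with the protocol's fixed colors, suitable for
#' loading alongside an exported NIfTI raster.
#'
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeLabelDescription <- function(file) {
  tab <- labelColorTable()
  lines <- c(
    "################################################",
    "# ITK-SnAP Label Description File",
    "# Fields: IDX -R- -G- -B- -A-- VIS MSH LABEL",
    "################################################",
    sprintf('%5d %5d %5d %5d %9.2f %3d %3d "%s"',
            0L, 0L, 0L, 0L, 0, 0L, 0L, "Clear Label"),
    sprintf('%5d %5d %5d %5d %9.2f %3d %3d "%s"',
            tab$index, tab$r, tab$g, tab$b, 1, 1L, 1L, tab$label)
  )
  writeLines(lines, file)
  invisible(file)
}

#' Export a raster label volume as NIfTI
#'
#' Requires the RNifti package; voxel dimensions are the in-plane
#' resolution and the slice spacing.
#'
#' @param raster an \code{mtlseg_raster} from
#'   \code{\link{rasterizeLabels}}.
#' @param file output path (.nii).
#' @param slice_spacing_mm through-plane voxel size (mm).
#' @return invisibly, the file path.
#' @export
writeNiftiLabels <- function(raster, file, slice_spacing_mm = 1.3) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("mtlseg_input", "NIfTI export requires the RNifti package")
  img <- RNifti::asNifti(raster$array,
                         pixdim = c(raster$resolution_mm,
                                    raster$resolution_mm,
                                    slice_spacing_mm))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Write a cohort to a directory
#'
#' One contour slice-stack file per case plus the ground-truth border
#' table — the on-disk form consumed by the measurement CLI.
#'
#' @param cohort an \code{\linkS4class{MTLCohort}} built with contours.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cohort@cases) {
    cid <- case@caseId
    if (!is.null(cohort@stacks[[cid]]))
      writeContourStack(cohort@stacks[[cid]],
                        file.path(dir, paste0(cid, "_contours.yaml")),
                        hemisphere = case@hemisphere)
  }
  writeBorderTable(cohort@truth, file.path(dir, "truth_borders.tsv"))
  invisible(dir)
}
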