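#' Configuration for the synthetic phantom cohort generator
#'
#' Assembles and validates the parameters of the phantom cohort: sample
#' size, seed, slice grid, the anterior-extent distributions of the three
#' cortical regions relative to the hippocampus tip, the axial positions
#' of the candidate anchor structures, the collateral-sulcus depth
#' dichotomy, and the true border-placement table with its between-case
#' noise.
#'
#' Extent distributions are location-scale with location = the configured
#' median and scale = the between-subject SD; the default extent
#' parameters are the measured medians/SDs of the region-to-hippocampus
#' distances (ERC 4.75/1.58, BA35 9.25/2.60, BA36 10.25/3.84 mm).  All
#' three extents share a latent per-case component
#' (\code{extent_shared_sd}) which the amygdala tip position tracks, so
#' that region-to-amygdala distances have slightly lower SDs than
#' region-to-hippocampus distances, reproducing the anchor-comparison
#' structure of the source measurements.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed RNG seed (integer).
#' @param slice_thickness_mm slice spacing of the synthetic stacks (mm);
#'   1.3 for the MRI grid, 0.5 for a histology-like grid.
#' @param fraction_deep_cs fraction of cases with a deep collateral
#'   sulcus (depth >= 7 mm at the hippocampus-tip level).
#' @param cs_assignment "bernoulli" (per-case draw, group sizes exact in
#'   expectation) or "stratified" (deterministic interleaving, exact
#'   counts for any prefix of the cohort).
#' @param fraction_disease fraction of cases flagged as carrying
#'   neurodegenerative disease (default 11/20; the flag has no effect on
#'   borders, giving a null generator for group comparisons).
#' @param extent_params data.frame with columns region, median, sd (mm).
#' @param extent_shared_sd SD of the latent extent component shared by
#'   all regions (must not exceed any region SD).
#' @param extent_dist "normal" (shifted normal matched to median and SD)
#'   or "lognormal" (skewed; shifted log-normal matched exactly to the
#'   same median and SD).
#' @param anchor_params data.frame with columns anchor, position, sd,
#'   orientation ("posterior" anchors are measured as extent - position,
#'   "anterior" anchors as position - extent).
#' @param amygdala_tracks_shared logical; if TRUE the amygdala tip
#'   position follows the latent shared extent component.
#' @param limen_sign "anterior" (default; limen distances negative for
#'   regions starting anterior of it) or "posterior": the sign convention
#'   for the limen insulae distances.
#' @param true_rules a \code{\linkS4class{RuleTable}} giving the true
#'   border placement; defaults to \code{\link{defaultRuleTable}()}.
#' @param border_sd_mm between-case Gaussian SD of true border positions
#'   around their rule positions (mm).
#' @param flank_window_mm width of the window behind the ERC anterior
#'   extent on which the medial BA35 flank is present (default 1 mm).
#' @param rater_sigma_mm default landmark jitter SD for perturbation
#'   studies (mm).
#' @return a validated config (list of class \code{mtlseg_cohort_config}).
#' @examples
#' cfg <- cohortConfig(n_cases = 2, seed = 7)
#' @export
cohortConfig <- function(n_cases,
                         seed,
                         slice_thickness_mm = 1.3,
                         fraction_deep_cs = 0.5,
                         cs_assignment = c("bernoulli", "stratified"),
                         fraction_disease = 11 / 20,
                         extent_params = data.frame(
                           region = c("ERC", "BA35", "BA36"),
                           median = c(4.75, 9.25, 10.25),
                           sd = c(1.58, 2.60, 3.84)),
                         extent_shared_sd = 1.0,
                         extent_dist = c("normal", "lognormal"),
                         anchor_params = data.frame(
                           anchor = c("hippocampus", "amygdala",
                                      "temporal_pole", "limen_insulae",
                                      "collateral_sulcus"),
                           position = c(0, 4, 26.5, 5.5, 19.5),
                           sd = c(0, 0.4, 2.0, 1.9, 4.0),
                           orientation = c("posterior", "posterior",
                                           "anterior", "anterior",
                                           "anterior")),
                         amygdala_tracks_shared = TRUE,
                         limen_sign = c("anterior", "posterior"),
                         true_rules = defaultRuleTable(),
                         border_sd_mm = 2.0,
                         flank_window_mm = 1.0,
                         rater_sigma_mm = 0.5) {
  cs_assignment <- match.arg(cs_assignment)
  extent_dist <- match.arg(extent_dist)
  limen_sign <- match.arg(limen_sign)
  if (limen_sign == "posterior")
    anchor_params$orientation[anchor_params$anchor == "limen_insulae"] <-
      "posterior"
  cfg <- list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    slice_thickness_mm = slice_thickness_mm,
    fraction_deep_cs = fraction_deep_cs,
    cs_assignment = cs_assignment,
    fraction_disease = fraction_disease,
    extent_params = extent_params,
    extent_shared_sd = extent_shared_sd,
    extent_dist = extent_dist,
    anchor_params = anchor_params,
    amygdala_tracks_shared = isTRUE(amygdala_tracks_shared),
    true_rules = true_rules,
    border_sd_mm = border_sd_mm,
    flank_window_mm = flank_window_mm,
    rater_sigma_mm = rater_sigma_mm
  )
  .validateCohortConfig(cfg)
  class(cfg) <- "mtlseg_cohort_config"
  cfg
}

.validateCohortConfig <- function(cfg) {
  if (cfg$n_cases < 1L)
    stopf("mtlseg_config", "n_cases must be >= 1")
  if (cfg$slice_thickness_mm <= 0)
    stopf("mtlseg_config", "slice_thickness_mm must be > 0")
  for (f in c("fraction_deep_cs", "fraction_disease"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("mtlseg_config", "%s must lie in [0, 1]", f)
  ep <- cfg$extent_params
  if (!all(.REGIONS %in% ep$region))
    stopf("mtlseg_config", "extent_params must cover ERC, BA35, BA36")
  if (any(ep$sd < 0) || any(cfg$anchor_params$sd < 0) ||
      cfg$border_sd_mm < 0 || cfg$extent_shared_sd < 0 ||
      cfg$rater_sigma_mm < 0)
    stopf("mtlseg_config", "all SDs must be >= 0")
  if (any(ep$median <= 0))
    stopf("mtlseg_config", "extent medians must be > 0")
  if (cfg$extent_shared_sd > min(ep$sd) + 1e-12)
    stopf("mtlseg_config",
          "extent_shared_sd must not exceed the smallest region SD")
  if (!is(cfg$true_rules, "RuleTable"))
    stopf("mtlseg_config", "true_rules must be a RuleTable")
  invisible(TRUE)
}

#' Zero-noise configuration generated from a rule table
#'
#' Builds a cohort configuration whose phantom truth reproduces a given
#' rule table exactly: region extents fixed at the table's start
#' distances, true borders placed at the rule positions with zero
#' between-case noise.  Anchor-position variability is kept at its
#' defaults (so anchor selection remains decidable) unless
#' \code{zero_anchor_sd = TRUE}.
#'
#' @param rule_table a \code{\linkS4class{RuleTable}}.
#' @param n_cases number of cases.
#' @param seed RNG seed.
#' @param zero_anchor_sd if TRUE, anchor positions are also noise-free.
#' @param border_sd_mm between-case border noise SD (mm), default 0.
#' @param ... further arguments passed to \code{\link{cohortConfig}}.
#' @return a cohort config.
#' @export
cohortConfigFromRules <- function(rule_table, n_cases, seed,
                                  zero_anchor_sd = FALSE,
                                  border_sd_mm = 0, ...) {
  st <- ruleStarts(rule_table)
  ap <- formals(cohortConfig)$anchor_params
  ap <- eval(ap)
  if (zero_anchor_sd) ap$sd <- 0
  cohortConfig(
    n_cases = n_cases, seed = seed,
    slice_thickness_mm = rule_table@sliceThickness,
    extent_params = data.frame(region = .REGIONS,
                               median = as.numeric(st[.REGIONS]),
                               sd = 0),
    extent_shared_sd = 0,
    anchor_params = ap,
    true_rules = rule_table,
    border_sd_mm = border_sd_mm,
    ...
  )
}

## Sample one region extent: location-scale on the configured median/SD.
## The shared component `c` is added outside.  For the lognormal option,
## sigma and mu are solved so that the median and SD match exactly.
.sampleExtent <- function(median, sd, dist) {
  if (sd <= 0) return(median)
  if (dist == "normal") return(median + sd * stats::rnorm(1))
  ## solve SD^2 = (exp(s2) - 1) * exp(2*mu + s2) with exp(mu) = median:
  ## SD^2 = median^2 * (exp(s2) - 1) * exp(s2)
  r <- sd^2 / median^2
  s2 <- log((1 + sqrt(1 + 4 * r)) / 2)
  stats::rlnorm(1, meanlog = log(median), sdlog = sqrt(s2))
}

.sampleCase <- function(cfg, i) {
  ep <- cfg$extent_params
  shared <- if (cfg$extent_shared_sd > 0)
    cfg$extent_shared_sd * stats::rnorm(1) else 0
  extents <- numeric(0)
  for (r in .REGIONS) {
    row <- ep[ep$region == r, ][1, ]
    indep_sd <- sqrt(max(row$sd^2 - cfg$extent_shared_sd^2, 0))
    ok <- FALSE
    for (tries in seq_len(100)) {
      x <- shared + .sampleExtent(row$median, indep_sd, cfg$extent_dist)
      if (x > 0) { ok <- TRUE; break }
    }
    if (!ok)
      stopf("mtlseg_config",
            "extent for %s resampled 100 times without a positive draw", r)
    extents[[r]] <- x
  }

  ap <- cfg$anchor_params
  anchors <- numeric(0)
  for (k in seq_len(nrow(ap))) {
    pos <- ap$position[k] + if (ap$sd[k] > 0) ap$sd[k] * stats::rnorm(1) else 0
    if (ap$anchor[k] == "amygdala" && cfg$amygdala_tracks_shared)
      pos <- pos + shared
    anchors[[ap$anchor[k]]] <- pos
  }

  disease <- stats::runif(1) < cfg$fraction_disease

  deep <- switch(cfg$cs_assignment,
    bernoulli = stats::runif(1) < cfg$fraction_deep_cs,
    stratified = floor(i * cfg$fraction_deep_cs) >
      floor((i - 1) * cfg$fraction_deep_cs))
  depth <- if (deep) stats::runif(1, 7.2, 11.0) else stats::runif(1, 3.0, 6.5)

  shape <- c(
    h_med = stats::runif(1, 13, 16),
    w_phg = stats::runif(1, 8, 12),
    w_cs = stats::runif(1, 5, 8),
    depth = depth,
    theta = stats::runif(1, -0.15, 0.15),
    w_fg = stats::runif(1, 10, 14),
    apex_h = stats::runif(1, 1, 3),
    bow = stats::runif(1, 0.2, 0.8),
    slice_thickness = cfg$slice_thickness_mm,
    stack_max = 0  # set below
  )
  ## the stack covers both the case's own anatomy (max extent + 2 mm)
  ## and the full protocol grid of the configured rule table
  th <- cfg$slice_thickness_mm
  span <- max(max(extents) + 2, max(ruleStarts(cfg$true_rules)))
  shape[["stack_max"]] <- th * ceiling(span / th - 1e-9)

  new("CasePhantom",
      caseId = sprintf("case%03d", i),
      hemisphere = if (stats::runif(1) < 0.65) "R" else "L",
      diseaseGroup = disease,
      csDepthClass = if (deep) "deep" else "shallow",
      csDepth = depth,
      extents = extents,
      anchors = anchors,
      shape = shape)
}

#' Place ground-truth cytoarchitectonic borders on one slice
#'
#' Resolves the true border positions on a slice from the configured rule
#' table (landmark position, plus offset in the rule's direction, plus
#' Gaussian between-case noise) and returns them as border annotations.
#' Only independent borders are annotated; borders that the protocol
#' shares between adjacent regions (e.g. BA36's medial border on
#' posterior slices) are implied.  The medial BA35 flank border is
#' emitted when the slice falls within the flank window behind the ERC
#' anterior extent.  Positions falling off the contour are clamped to the
#' terminus and counted.
#'
#' Noise is drawn from the current RNG stream; callers needing
#' reproducibility wrap the call in a seeded context (as
#' \code{\link{generateCohort}} does).
#'
#' @param case a \code{\linkS4class{CasePhantom}}.
#' @param landmarks the slice's \code{\linkS4class{LandmarkSet}}.
#' @param slice_distance_mm slice distance (mm).
#' @param rule_table the true \code{\linkS4class{RuleTable}}.
#' @param border_sd_mm between-case border noise SD (mm).
#' @param flank_window_mm flank window width (mm).
#' @return data.frame of annotations (region, side, segment, s,
#'   slice_distance_mm) with attribute \code{clamped} = number of clamped
#'   borders.
#' @export
placeTrueBorders <- function(case, landmarks, slice_distance_mm,
                             rule_table = defaultRuleTable(),
                             border_sd_mm = 0, flank_window_mm = 1.0) {
  d <- slice_distance_mm
  present <- .REGIONS[case@extents[.REGIONS] >= d - 1e-9]
  out <- list()
  clamped <- 0L
  L <- landmarks@contourLength
  pos <- landmarks@positions
  level <- sliceRuleLevel(d, rule_table, strict = FALSE)

  emit <- function(region, side, segment, s) {
    s2 <- min(max(s, 0), L)
    if (s2 != s) clamped <<- clamped + 1L
    out[[length(out) + 1L]] <<- data.frame(
      region = region, side = side, segment = segment, s = s2,
      slice_distance_mm = d, stringsAsFactors = FALSE)
  }
  place <- function(rr) {
    s <- pos[[rr$landmark]] +
      (if (identical(rr$direction, "medial")) -1 else 1) * rr$offset_mm
    if (border_sd_mm > 0) s <- s + border_sd_mm * stats::rnorm(1)
    s
  }

  for (region in intersect(.REGIONS, present)) {
    for (side in c("medial", "lateral")) {
      rr <- .ruleFor(rule_table, level, region, side)
      if (is.null(rr) || !is.na(rr$reference)) next  # shared border, implied
      emit(region, side, "primary", place(rr))
    }
  }

  ext_erc <- case@extents[["ERC"]]
  if ("ERC" %in% present && nrow(rule_table@flank) &&
      d > ext_erc - flank_window_mm - 1e-9 && d <= ext_erc + 1e-9) {
    f <- rule_table@flank[1, ]
    emit("BA35", "medial", "medial_flank", place(f))
  }

  res <- if (length(out)) do.call(rbind, out) else
    data.frame(region = character(), side = character(),
               segment = character(), s = numeric(),
               slice_distance_mm = numeric(), stringsAsFactors = FALSE)
  attr(res, "clamped") <- clamped
  res
}

#' Generate a synthetic phantom cohort
#'
#' Draws \code{n_cases} phantom cases under the configuration: anterior
#' extents and anchor positions, collateral-sulcus depth and class,
#' contour shape, per-slice contours spanning at least
#' [slice thickness, max extent + 2 mm], and ground-truth border
#' annotations placed by the configured rule table plus between-case
#' noise.  Each case is drawn from its own RNG substream, so the same
#' seed reproduces the cohort byte-for-byte and increasing
#' \code{n_cases} leaves earlier cases unchanged.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param contours if FALSE, skip building slice contours and truth
#'   borders (extent-only cohorts for large-n distribution checks; the
#'   per-case extents and anchors are identical either way).
#' @return an \code{\linkS4class{MTLCohort}}.
#' @examples
#' coh <- generateCohort(cohortConfig(n_cases = 2, seed = 7))
#' @export
generateCohort <- function(config, contours = TRUE) {
  stopifnot(inherits(config, "mtlseg_cohort_config"))
  cases <- vector("list", config$n_cases)
  stacks <- list()
  truth <- list()
  clamped <- 0L
  th <- config$slice_thickness_mm
  for (i in seq_len(config$n_cases)) {
    res <- withSeed(caseSeed(config$seed, i), {
      case <- .sampleCase(config, i)
      stack <- NULL
      tr <- NULL
      if (contours) {
        dists <- seq(th, case@shape[["stack_max"]] + 1e-9, by = th)
        stack <- lapply(dists, function(d) buildSliceContour(case, d))
        lm0 <- deriveLandmarks(stack[[1]])  # shape constant across slices
        ann <- lapply(dists, function(d) {
          lm <- LandmarkSet(lm0@positions, lm0@csDepth, d, lm0@contourLength)
          placeTrueBorders(case, lm, d, config$true_rules,
                           config$border_sd_mm, config$flank_window_mm)
        })
        cl <- sum(vapply(ann, function(a) attr(a, "clamped"), integer(1)))
        tr <- do.call(rbind, ann)
        tr <- if (nrow(tr)) cbind(case_id = case@caseId, tr) else
          data.frame(case_id = character(), region = character(),
                     side = character(), segment = character(),
                     s = numeric(), slice_distance_mm = numeric(),
                     stringsAsFactors = FALSE)
        attr(tr, "clamped") <- cl
      }
      list(case = case, stack = stack, truth = tr)
    })
    cases[[i]] <- res$case
    if (contours) {
      stacks[[res$case@caseId]] <- res$stack
      truth[[i]] <- res$truth
      clamped <- clamped + attr(res$truth, "clamped")
    }
  }
  truth_df <- if (contours && length(truth)) do.call(rbind, truth) else
    data.frame(case_id = character(), region = character(),
               side = character(), segment = character(), s = numeric(),
               slice_distance_mm = numeric(), stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  if (clamped > 0)
    warnf("mtlseg_border_clamped",
          "%d true border(s) clamped to the contour domain", clamped)
  new("MTLCohort", cases = cases, stacks = stacks, truth = truth_df,
      config = unclass(config), clamped = clamped)
}

#' Ground-truth label map of one phantom case
#'
#' Assembles the case's ground-truth border annotations into an interval
#' label map: shared borders are filled in from the adjacent region
#' (BA35's medial border is ERC's lateral border where ERC is present and
#' no independent BA35 medial border was annotated; likewise BA36/BA35),
#' and the medial BA35 flank becomes a BA35 interval between its
#' annotated medial border and the ERC medial border.  Intervals whose
#' noisy borders invert (start >= end) are dropped and counted in the
#' \code{dropped} attribute.
#'
#' @param cohort an \code{\linkS4class{MTLCohort}} built with contours.
#' @param case_id case identifier.
#' @param posterior_bound_mm if non-NULL, keep only slices at or anterior
#'   to this bound (use the rule table's bound to compare against engine
#'   output).
#' @return a \code{\linkS4class{LabelMap}}.
#' @export
truthLabelMap <- function(cohort, case_id, posterior_bound_mm = NULL) {
  tr <- cohort@truth
  tr <- tr[tr$case_id == case_id, , drop = FALSE]
  if (!is.null(posterior_bound_mm))
    tr <- tr[tr$slice_distance_mm >= posterior_bound_mm - 1e-9, ,
             drop = FALSE]
  rows <- list()
  dropped <- 0L
  for (d in sort(unique(tr$slice_distance_mm))) {
    sl <- tr[abs(tr$slice_distance_mm - d) < 1e-9, , drop = FALSE]
    get <- function(region, side, segment = "primary") {
      hit <- sl[sl$region == region & sl$side == side &
                  sl$segment == segment, , drop = FALSE]
      if (nrow(hit)) hit$s[1] else NA_real_
    }
    e_med <- get("ERC", "medial"); e_lat <- get("ERC", "lateral")
    b35_med <- get("BA35", "medial"); b35_lat <- get("BA35", "lateral")
    b36_med <- get("BA36", "medial"); b36_lat <- get("BA36", "lateral")
    f_med <- get("BA35", "medial", "medial_flank")
    if (is.na(b35_med) && !is.na(e_lat)) b35_med <- e_lat
    if (is.na(b36_med) && !is.na(b35_lat)) b36_med <- b35_lat
    push <- function(label, s0, s1, segment = "primary") {
      if (is.na(s0) || is.na(s1)) return()
      if (s0 >= s1) { dropped <<- dropped + 1L; return() }
      rows[[length(rows) + 1L]] <<- data.frame(
        slice_distance_mm = d, s_start = s0, s_end = s1, label = label,
        segment = segment, stringsAsFactors = FALSE)
    }
    push("BA35", f_med, e_med, "medial_flank")
    push("ERC", e_med, e_lat)
    push("BA35", b35_med, b35_lat)
    push("BA36", b36_med, b36_lat)
  }
  iv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice_distance_mm = numeric(), s_start = numeric(),
               s_end = numeric(), label = character(),
               segment = character(), stringsAsFactors = FALSE)
  lm <- LabelMap(case_id, iv)
  attr(lm, "dropped") <- dropped
  lm
}
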