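## Internal helpers: vocabulary constants, classed conditions, RNG scoping.

## Key vertices tagged on a coronal pial contour, in canonical
## medial -> lateral order.
.KEY_VERTICES <- c(
  "medial_terminus", "phg_superior_edge", "cs_medial_mouth",
  "cs_fundus", "cs_lateral_mouth", "fg_crown_apex", "lateral_terminus"
)

## Protocol landmarks (arc-length positions), canonical medial -> lateral
## order; this ordering is a class invariant of LandmarkSet.
.LANDMARKS <- c(
  "s_phg_superior_edge", "s_phg_crown_midpoint", "s_cs_medial_edge",
  "s_medial_bank_half", "s_cs_fundus", "s_lateral_bank_quarter",
  "s_fundus_fg_midpoint", "s_fg_crown_midpoint"
)

.REGIONS <- c("ERC", "BA35", "BA36")

.ANCHORS <- c("hippocampus", "amygdala", "temporal_pole",
              "limen_insulae", "collateral_sulcus")

## Integer label codes pinned for raster export (stable across runs);
## colors follow the protocol's convention: green ERC, light blue BA35,
## dark blue BA36.
.LABEL_CODES <- c(ERC = 1L, BA35 = 2L, BA36 = 3L)
.LABEL_COLORS <- rbind(
  ERC  = c(0L, 170L, 0L),
  BA35 = c(102L, 178L, 255L),
  BA36 = c(0L, 0L, 153L)
)

stopf <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "mtlseg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

warnf <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(
    class = c(class, "mtlseg_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a fixed RNG state without disturbing the caller's
## stream.  All package randomness goes through this so that results are
## reproducible across platforms (Mersenne-Twister / inversion sampling).
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## Deterministic per-case substream seed: changing n_cases must not alter
## earlier cases, so each case gets its own 31-bit seed derived from the
## cohort seed and the case index.
caseSeed <- function(seed, i) {
  v <- ((as.numeric(seed) %% 2147483647) * 69069 + i * 1234567) %% 2147483647
  as.integer(v)
}
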