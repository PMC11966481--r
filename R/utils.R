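#' Derive a stage-specific RNG seed from a master seed
#'
#' Each pipeline stage draws from its own RNG stream so that adding or
#' reordering stages never perturbs another stage's random numbers. The
#' stream seed is a deterministic hash of the master seed and the stage
#' name, kept inside the 32-bit integer range R requires.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name (e.g. `"simulate"`, `"reho"`).
#' @return A single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

#' Canonicalize a region name for cross-source matching
#'
#' Templates and cohort tables often originate from different tools with
#' different capitalization and separators; matching is done on a
#' lowercase, underscore-separated canonical form.
#'
#' @param x Character vector of region names.
#' @return Canonical names.
#' @export
canonical_region_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# tie-correction term sum(g^3 - g) over tied groups of one series
tie_correction <- function(x) {
  r <- rle(sort(x))
  g <- r$lengths
  sum(g^3 - g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
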