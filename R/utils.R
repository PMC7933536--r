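#' @keywords internal
"_PACKAGE"

#' Pixel resolution of the reference H&E whole-slide scans
#'
#' Spatial resolution, in micrometres per pixel, of the slide scanner output
#' that tumour annotations and compartment masks are natively expressed in.
#' Synthetic cohorts use a coarser working resolution (see [sim_config()]);
#' this constant is the default when importing real annotation data without a
#' stated resolution.
#' @export
HNE_SCAN_RESOLUTION_UM <- 0.12

# Round half away from zero (SPSS-style), used for report percentages.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run an expression with a local RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive per-component seeds from a master seed, kept inside 32-bit range.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
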