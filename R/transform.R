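#' Anscombe variance-stabilizing transform
#'
#' Maps Poisson-distributed counts `x` to `y = 2 * sqrt(x + 3/8)`, whose
#' variance is approximately 1 for Poisson means above about 4, so the
#' downstream denoiser — which assumes additive Gaussian noise — sees a
#' signal with (nearly) constant noise level.
#'
#' Both functions accept either a bare numeric vector or a coverage track;
#' tracks come back on the same bin grid with only the values changed.
#'
#' @param x non-negative counts: numeric vector or [binned_track()].
#' @return `anscombe()`: transformed values (>= `2 * sqrt(3/8)`), as a
#'   numeric vector or `stabilized_track`.
#' @export
#' @examples
#' anscombe(0:3)
#' inverse_anscombe(anscombe(0:3))
anscombe <- function(x) UseMethod("anscombe")

#' @export
anscombe.default <- function(x) {
  if (any(x < 0)) stop_misuse("Anscombe transform requires counts >= 0")
  2 * sqrt(x + 3 / 8)
}

#' @export
anscombe.binned_track <- function(x) {
  stabilized_track(x$chrom, x$bin_size, anscombe.default(x$values),
                   x$chrom_length)
}

#' @rdname anscombe
#'
#' @details `inverse_anscombe()` applies the exact algebraic inverse
#'   `x = (y/2)^2 - 3/8` (no bias correction), clipping results below 0 to
#'   0: denoised values near empty regions can fall slightly under the
#'   transform's minimum, and coverage cannot be negative. Results below
#'   1e-12 are snapped to 0 so that empty bins survive the round trip as
#'   exact zeros despite floating-point residue.
#'
#' @param y stabilized values: numeric vector, `stabilized_track`, or any
#'   coverage track on the Anscombe scale.
#' @return `inverse_anscombe()`: counts-scale values (>= 0), numeric vector
#'   or `denoised_track`.
#' @export
inverse_anscombe <- function(y) UseMethod("inverse_anscombe")

#' @export
inverse_anscombe.default <- function(y) {
  if (any(y < 0)) stop_misuse("inverse Anscombe requires values >= 0")
  x <- pmax((y / 2)^2 - 3 / 8, 0)
  x[x < 1e-12] <- 0
  x
}

#' @export
inverse_anscombe.coverage_track <- function(y) {
  denoised_track(y$chrom, y$bin_size, inverse_anscombe.default(y$values),
                 y$chrom_length)
}
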