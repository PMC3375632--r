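#' Per-chromosome binned coverage tracks
#'
#' A track is the pipeline's 1-D signal: one value per fixed-width bin along
#' a single chromosome. Three flavours share the same layout and differ only
#' in what the values mean:
#'
#' * `binned_track`: non-negative integer read counts `r_i` (the raw
#'   histogram),
#' * `stabilized_track`: real values on the Anscombe scale,
#' * `denoised_track`: real coverage heights after denoising and inverse
#'   transform.
#'
#' The number of bins is always `ceiling(chrom_length / bin_size)`; the last
#' bin may be truncated at the chromosome end.
#'
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param counts,values the per-bin signal, length `ceiling(chrom_length /
#'   bin_size)`.
#' @param chrom_length chromosome length in bp.
#' @return an object of class `binned_track`, `stabilized_track` or
#'   `denoised_track` (all inheriting from `coverage_track`).
#' @export
#' @examples
#' binned_track("chr1", 25, c(2L, 1L), 50)
binned_track <- function(chrom, bin_size, counts, chrom_length) {
  if (any(counts < 0)) stop_misuse("bin counts must be non-negative")
  if (any(counts != floor(counts))) stop_misuse("bin counts must be integers")
  new_track(chrom, bin_size, as.numeric(counts), chrom_length,
            "binned_track")
}

#' @rdname binned_track
#' @export
stabilized_track <- function(chrom, bin_size, values, chrom_length) {
  new_track(chrom, bin_size, values, chrom_length, "stabilized_track")
}

#' @rdname binned_track
#' @export
denoised_track <- function(chrom, bin_size, values, chrom_length) {
  if (any(values < 0)) stop_misuse("denoised heights must be non-negative")
  new_track(chrom, bin_size, values, chrom_length, "denoised_track")
}

new_track <- function(chrom, bin_size, values, chrom_length, class) {
  stopifnot(length(chrom) == 1, length(bin_size) == 1,
            length(chrom_length) == 1)
  if (bin_size <= 0) stop_misuse("bin_size must be > 0")
  if (chrom_length <= 0) stop_misuse("chrom_length must be > 0")
  m <- as.integer(ceiling(chrom_length / bin_size))
  if (length(values) != m) {
    stop_misuse(sprintf(
      "track for %s must have %d bins (chrom_length %s / bin_size %s), got %d",
      chrom, m, format(chrom_length), format(bin_size), length(values)))
  }
  structure(
    list(chrom = as.character(chrom), bin_size = as.numeric(bin_size),
         values = as.numeric(values),
         chrom_length = as.numeric(chrom_length)),
    class = c(class, "coverage_track"))
}

#' @rdname binned_track
#' @param x a coverage track.
#' @export
track_values <- function(x) {
  stopifnot(inherits(x, "coverage_track"))
  x$values
}

#' @rdname binned_track
#' @export
n_bins <- function(x) length(track_values(x))

#' @export
print.coverage_track <- function(x, ...) {
  v <- x$values
  cat(sprintf("<%s> %s: %d bins of %s bp (chrom length %s)\n",
              class(x)[1], x$chrom, length(v), format(x$bin_size),
              format(x$chrom_length)))
  cat(sprintf("  values: min %.4g, max %.4g, sum %.6g\n",
              min(v), max(v), sum(v)))
  invisible(x)
}

same_grid <- function(a, b) {
  a$chrom == b$chrom && a$bin_size == b$bin_size &&
    a$chrom_length == b$chrom_length && length(a$values) == length(b$values)
}
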