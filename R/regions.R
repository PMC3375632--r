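#' Call enriched regions from a denoised track
#'
#' Maximal runs of consecutive bins whose denoised height is at or above
#' the threshold become candidate regions; runs separated by at most
#' `merge_gap` sub-threshold bins are merged; candidates shorter than
#' `min_length` or with peak-to-threshold ratio below `min_peak_ratio` are
#' dropped. Region coordinates are 0-based half-open and snap to bin edges
#' (the end is clipped at the chromosome length).
#'
#' @param track a `denoised_track`.
#' @param height_threshold calling threshold on the denoised height scale
#'   (> 0), typically from [choose_threshold()].
#' @param min_peak_ratio minimum peak-to-threshold ratio (>= 1). Default 1,
#'   i.e. no ratio filter.
#' @param min_length minimum region length in bp. Default 0.
#' @param merge_gap maximum run gap to bridge, in bins. Default 0.
#' @return a data.frame with one row per region: `chrom`, `start`, `end`,
#'   `length` (bp), `peak_height`, `threshold`, `peak_ratio`; sorted by
#'   start, pairwise disjoint.
#' @export
#' @examples
#' tr <- denoised_track("chr1", 1000, c(0, 5, 6, 5, 0), 5000)
#' call_regions(tr, height_threshold = 4)
call_regions <- function(track, height_threshold, min_peak_ratio = 1,
                         min_length = 0, merge_gap = 0) {
  stopifnot(inherits(track, "denoised_track"))
  if (height_threshold <= 0) stop_misuse("height_threshold must be > 0")
  if (min_peak_ratio < 1) stop_misuse("min_peak_ratio must be >= 1")
  if (min_length < 0 || merge_gap < 0) {
    stop_misuse("min_length and merge_gap must be >= 0")
  }
  v <- track_values(track)
  above <- v >= height_threshold
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric(),
                      peak_height = numeric(), threshold = numeric(),
                      peak_ratio = numeric(), stringsAsFactors = FALSE)
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  # bridge sub-threshold gaps of at most merge_gap bins
  if (length(run_start) > 1 && merge_gap > 0) {
    gap <- run_start[-1] - run_end[-length(run_end)] - 1
    new_group <- c(TRUE, gap > merge_gap)
    grp <- cumsum(new_group)
    run_start <- tapply(run_start, grp, min)
    run_end <- tapply(run_end, grp, max)
  }
  bs <- track$bin_size
  start <- (run_start - 1) * bs
  end <- pmin(run_end * bs, track$chrom_length)
  peak <- vapply(seq_along(run_start), function(k) {
    max(v[run_start[k]:run_end[k]])
  }, numeric(1))
  out <- data.frame(chrom = track$chrom, start = start, end = end,
                    length = end - start, peak_height = peak,
                    threshold = height_threshold,
                    peak_ratio = peak / height_threshold,
                    stringsAsFactors = FALSE)
  out <- out[out$peak_ratio >= min_peak_ratio & out$length >= min_length, ]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

regions_to_granges <- function(regions) {
  if (nrow(regions) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1,
                              end = regions$end))
}

#' Overlap ratio between two region sets
#'
#' Fraction of `detected` regions that intersect (by at least 1 bp) at
#' least one `reference` region — the headline consistency measure when
#' benchmarking one caller's regions against another's. `mode =
#' "symmetric"` averages the two directions.
#'
#' @param detected,reference region data.frames (as from [call_regions()]
#'   or [read_regions_bed()]); each set should be non-overlapping within
#'   itself, any row order.
#' @param mode `"detected_in_reference"` (default) or `"symmetric"`.
#' @return a fraction in `[0, 1]`; `NA` if `detected` is empty (0/0).
#' @export
overlap_ratio <- function(detected, reference,
                          mode = c("detected_in_reference", "symmetric")) {
  mode <- match.arg(mode)
  frac_hit <- function(a, b) {
    if (nrow(a) == 0) return(NA_real_)
    if (nrow(b) == 0) return(0)
    # disjoint chromosome sets are a valid comparison (overlap 0), but
    # make findOverlaps warn about missing common seqlevels
    hits <- suppressWarnings(
      GenomicRanges::countOverlaps(regions_to_granges(a),
                                   regions_to_granges(b)))
    mean(hits > 0)
  }
  d <- frac_hit(detected, reference)
  if (mode == "detected_in_reference") return(d)
  mean(c(d, frac_hit(reference, detected)))
}

#' Region-length summary
#'
#' Counts regions at or above each length cutoff, plus the maximum length —
#' the standard summary for long-domain callers, where the interesting
#' regions are the multi-kilobase ones.
#'
#' @param regions region data.frame.
#' @param length_cutoffs numeric vector of cutoffs in bp.
#' @return list with `counts` (named integer vector, one per cutoff) and
#'   `max_length` (0 for an empty set).
#' @export
#' @examples
#' r <- data.frame(chrom = "chr1", start = 0, end = c(4000, 12000, 3000))
#' r$length <- r$end - r$start
#' region_length_summary(r, c(4000, 10000))
region_length_summary <- function(regions,
                                  length_cutoffs = c(4000, 10000)) {
  counts <- vapply(length_cutoffs, function(cutoff) {
    sum(regions$length >= cutoff)
  }, integer(1))
  names(counts) <- paste0("ge_", format(length_cutoffs, scientific = FALSE,
                                        trim = TRUE), "bp")
  list(counts = counts,
       max_length = if (nrow(regions)) max(regions$length) else 0)
}

#' Write called regions as BED6
#'
#' Name is a sequential region id, score is the peak-to-threshold ratio
#' scaled as `min(1000, round(100 * ratio))`, strand is ".". Rows are
#' written sorted by chromosome then start, so output is deterministic.
#'
#' @param regions region data.frame from [call_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions)) {
    regions <- regions[order(regions$chrom, regions$start), ]
    score <- if (!is.null(regions$peak_ratio)) {
      pmin(1000, round(100 * regions$peak_ratio))
    } else {
      rep(0, nrow(regions))
    }
    lines <- sprintf("%s\t%s\t%s\tregion_%d\t%d\t.", regions$chrom,
                     format(regions$start, scientific = FALSE, trim = TRUE),
                     format(regions$end, scientific = FALSE, trim = TRUE),
                     seq_len(nrow(regions)), score)
  } else {
    lines <- character()
  }
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_misuse("cannot write regions BED to ", path)
  invisible(path)
}

#' Read a BED3+ file as a region data.frame
#'
#' @param path BED file with at least chrom, start, end columns.
#' @return data.frame with `chrom`, `start`, `end`, `length` (and `name`,
#'   `score` when present).
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop_misuse("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric(),
                      stringsAsFactors = FALSE))
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_misuse("malformed BED record at line ", lineno[which(nf < 3)[1]],
                " of ", path, ": fewer than 3 columns")
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    stop_misuse("malformed BED record at line ", lineno[which(bad)[1]],
                " of ", path, ": bad coordinates")
  }
  out <- data.frame(chrom = vapply(fields, `[[`, "", 1), start = start,
                    end = end, length = end - start,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 5)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  }
  out
}
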