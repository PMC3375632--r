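#' Configuration for the synthetic read generator
#'
#' Describes a single synthetic chromosome: homogeneous Poisson background
#' at `background_rate` reads/bp, with planted enriched segments whose rate
#' is multiplied by `fold`. This mirrors the noise model the pipeline
#' assumes (spike noise with Poisson statistics) plus the long enriched
#' domains it is designed to recover; it deliberately omits fragment-length
#' strand shift, mappability and GC bias.
#'
#' @param chrom_length chromosome length in bp.
#' @param background_rate background read density, reads per bp.
#' @param segments data.frame with columns `start`, `end` (0-based
#'   half-open, bp) and `fold` (> 1); may have zero rows. Segments must be
#'   non-overlapping and inside the chromosome.
#' @param bin_size bin width the dataset is meant to be analysed at; truth
#'   segments are expected to sit on this grid in the standard fixtures.
#' @param seed integer seed making the dataset reproducible.
#' @param chrom chromosome name.
#' @return an object of class `synthetic_config`.
#' @export
#' @examples
#' synthetic_config(1e6, 0.02,
#'                  data.frame(start = 2e5, end = 2.2e5, fold = 8))
synthetic_config <- function(chrom_length, background_rate = 0.02,
                             segments = data.frame(start = numeric(),
                                                   end = numeric(),
                                                   fold = numeric()),
                             bin_size = 1000, seed = 1,
                             chrom = "chrSim") {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "fold") %in% names(segments)) ||
              nrow(segments) == 0)
  if (chrom_length <= 0) stop_misuse("chrom_length must be > 0")
  if (background_rate <= 0) stop_misuse("background_rate must be > 0")
  if (nrow(segments)) {
    segments <- segments[order(segments$start), ]
    if (any(segments$start < 0) || any(segments$end > chrom_length) ||
        any(segments$start >= segments$end)) {
      stop_misuse("segments must satisfy 0 <= start < end <= chrom_length")
    }
    if (any(segments$fold <= 1)) stop_misuse("segment fold must be > 1")
    if (nrow(segments) > 1 &&
        any(segments$start[-1] < segments$end[-nrow(segments)])) {
      stop_misuse("segments must be non-overlapping")
    }
  }
  structure(list(chrom_length = chrom_length,
                 background_rate = background_rate,
                 segments = segments, bin_size = bin_size,
                 seed = as.integer(seed), chrom = as.character(chrom)),
            class = "synthetic_config")
}

#' Generate synthetic reads with ground truth
#'
#' Draws reads from an inhomogeneous Poisson process: rate
#' `background_rate` outside the planted segments and
#' `fold * background_rate` inside. Per piece the read count is Poisson
#' with mean rate x width and positions are uniform. Strands are assigned
#' at random (the pipeline ignores them). Deterministic under the config
#' seed; reads are returned sorted by position.
#'
#' @param config a [synthetic_config()].
#' @return list with `reads` (data.frame chrom/pos/strand) and `truth`
#'   (data.frame chrom/start/end/length/fold — the planted segments).
#' @export
#' @examples
#' cfg <- synthetic_config(1e5, 0.02, seed = 7)
#' gen <- generate_reads(cfg)
#' nrow(gen$reads)
generate_reads <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  seg <- config$segments
  # piecewise-constant rate: background pieces interleaved with segments
  bounds <- sort(unique(c(0, seg$start, seg$end, config$chrom_length)))
  piece_start <- bounds[-length(bounds)]
  piece_end <- bounds[-1]
  in_seg <- vapply(piece_start, function(s) {
    k <- which(seg$start <= s & s < seg$end)
    if (length(k)) seg$fold[k[1]] else 1
  }, numeric(1))
  rate <- config$background_rate * in_seg
  out <- with_seed(config$seed, {
    pos <- numeric(0)
    for (k in seq_along(piece_start)) {
      w <- piece_end[k] - piece_start[k]
      n <- stats::rpois(1, rate[k] * w)
      if (n > 0) {
        pos <- c(pos, piece_start[k] + floor(stats::runif(n) * w))
      }
    }
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    list(pos = pos, strand = strand)
  })
  ord <- order(out$pos)
  reads <- data.frame(chrom = rep(config$chrom, length(out$pos)),
                      pos = as.integer(out$pos[ord]),
                      strand = out$strand[ord], stringsAsFactors = FALSE)
  truth <- if (nrow(seg)) {
    data.frame(chrom = config$chrom, start = seg$start, end = seg$end,
               length = seg$end - seg$start, fold = seg$fold,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               length = numeric(), fold = numeric(),
               stringsAsFactors = FALSE)
  }
  list(reads = reads, truth = truth)
}

#' Standard recovery fixture: planted domains on a long chromosome
#'
#' The package's reference test condition: `n_segments` enriched segments
#' with lengths drawn uniformly between `min_seg` and `max_seg` (snapped to
#' bin edges), evenly spaced along the chromosome, at a common fold
#' enrichment over a uniform background. Defaults describe a 10 Mb
#' chromosome, 0.02 reads/bp background (about 200k background reads),
#' fold 8, 1 kb bins.
#'
#' @param seed integer seed (drives both segment layout and reads).
#' @param chrom_length,background_rate,bin_size,fold,n_segments,min_seg,max_seg
#'   study-condition parameters; see description.
#' @return a [synthetic_config()].
#' @export
synthetic_fixture_config <- function(seed = 1, chrom_length = 1e7,
                                     background_rate = 0.02,
                                     bin_size = 1000, fold = 8,
                                     n_segments = 10, min_seg = 5000,
                                     max_seg = 50000) {
  lens <- with_seed(derive_seed(seed, "fixture-layout"), {
    round(stats::runif(n_segments, min_seg, max_seg) / bin_size) * bin_size
  })
  lens <- pmax(lens, bin_size)
  # evenly spaced anchors, segment placed at the anchor's bin edge
  anchor <- floor(chrom_length * (seq_len(n_segments) - 0.5) /
                    n_segments / bin_size) * bin_size
  segments <- data.frame(start = anchor, end = anchor + lens, fold = fold)
  synthetic_config(chrom_length, background_rate, segments, bin_size,
                   seed = seed)
}

#' Score detected regions against planted truth
#'
#' A truth segment counts as recovered when a single detected region covers
#' at least half of it; a detected region counts as a true positive when at
#' least half of its length lies inside truth segments. Boundary error is
#' the mean absolute distance between matched region edges (each recovered
#' truth segment paired with its maximal-overlap detected region, both
#' edges contributing).
#'
#' @param detected region data.frame (as from [call_regions()]).
#' @param truth truth data.frame (as from [generate_reads()]).
#' @param boundary_tol optional tolerance in bp; when given, the returned
#'   `frac_within_tol` is the fraction of matched edges within it.
#' @return list with `recall`, `precision`, `mean_boundary_error` (bp; NA
#'   when nothing matched), `n_detected`, `n_truth`, and optionally
#'   `frac_within_tol`.
#' @export
evaluate_recovery <- function(detected, truth, boundary_tol = NULL) {
  n_det <- nrow(detected)
  n_tru <- nrow(truth)
  if (n_tru == 0) {
    return(list(recall = NA_real_,
                precision = if (n_det) 0 else NA_real_,
                mean_boundary_error = NA_real_, n_detected = n_det,
                n_truth = 0))
  }
  if (n_det == 0) {
    return(list(recall = 0, precision = NA_real_,
                mean_boundary_error = NA_real_, n_detected = 0,
                n_truth = n_tru))
  }
  dg <- regions_to_granges(detected)
  tg <- regions_to_granges(truth)
  hits <- GenomicRanges::findOverlaps(dg, tg)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(dg)[S4Vectors::queryHits(hits)],
    IRanges::ranges(tg)[S4Vectors::subjectHits(hits)]))
  # recall: best single-region coverage of each truth segment
  best_ov <- tapply(ov, S4Vectors::subjectHits(hits), max)
  covered <- rep(0, n_tru)
  covered[as.integer(names(best_ov))] <- best_ov
  recovered <- covered >= 0.5 * truth$length
  # precision: total truth overlap per detected region
  det_ov <- tapply(ov, S4Vectors::queryHits(hits), sum)
  inside <- rep(0, n_det)
  inside[as.integer(names(det_ov))] <- det_ov
  precision <- mean(inside >= 0.5 * detected$length)
  # boundary error over matched pairs
  edge_err <- numeric(0)
  for (k in which(recovered)) {
    cand <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == k]
    cand_ov <- ov[S4Vectors::subjectHits(hits) == k]
    j <- cand[which.max(cand_ov)]
    edge_err <- c(edge_err,
                  abs(detected$start[j] - truth$start[k]),
                  abs(detected$end[j] - truth$end[k]))
  }
  out <- list(recall = mean(recovered), precision = precision,
              mean_boundary_error = if (length(edge_err)) mean(edge_err)
                                    else NA_real_,
              n_detected = n_det, n_truth = n_tru)
  if (!is.null(boundary_tol)) {
    out$frac_within_tol <- if (length(edge_err)) {
      mean(edge_err <= boundary_tol)
    } else {
      NA_real_
    }
  }
  out
}
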