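#' Assemble a full run configuration
#'
#' Bundles every tunable of the detection pipeline, with two presets
#' matching the two analysis regimes the method is used in:
#'
#' * `"narrow"`: 25 bp bins, no length filter, peak-to-threshold ratio
#'   filter 6.5 — the fine-grained regime for comparing against narrow-peak
#'   callers.
#' * `"broad"`: 1,000 bp bins, 4,000 bp minimum length, no ratio filter —
#'   the long-domain regime where region length is the operative filter.
#'
#' Explicit arguments always override the preset.
#'
#' @param input path(s) to mapped-read files.
#' @param chrom_sizes path to a chrom.sizes file, or a named vector.
#' @param out_dir output directory for [run_detect()].
#' @param preset `"broad"` (default) or `"narrow"`.
#' @param format input format, `"bed"` or `"tab"`.
#' @param bin_size,min_length,min_peak_ratio,merge_gap region-calling
#'   parameters; preset defaults when `NULL`.
#' @param search_radius,patch_length,sigma denoiser parameters
#'   ([nlm_params()]).
#' @param B null-ensemble size. Default 20.
#' @param target_fdr target FDR. Default 0.01.
#' @param extend fragment extension in bp (0 = none).
#' @param placement null read-placement model.
#' @param seed master seed.
#' @return an object of class `run_config` (a list of all settings).
#' @export
run_config <- function(input = NULL, chrom_sizes = NULL, out_dir = ".",
                       preset = c("broad", "narrow"), format = "bed",
                       bin_size = NULL, min_length = NULL,
                       min_peak_ratio = NULL, merge_gap = 0,
                       search_radius = 10, patch_length = 15, sigma = 10,
                       B = 20, target_fdr = 0.01, extend = 0,
                       placement = "multinomial", seed = 1) {
  preset <- match.arg(preset)
  defaults <- if (preset == "broad") {
    list(bin_size = 1000, min_length = 4000, min_peak_ratio = 1)
  } else {
    list(bin_size = 25, min_length = 0, min_peak_ratio = 6.5)
  }
  cfg <- list(input = input, chrom_sizes = chrom_sizes, out_dir = out_dir,
              preset = preset, format = format,
              bin_size = bin_size %||% defaults$bin_size,
              min_length = min_length %||% defaults$min_length,
              min_peak_ratio = min_peak_ratio %||% defaults$min_peak_ratio,
              merge_gap = merge_gap,
              params = nlm_params(search_radius, patch_length, sigma),
              B = B, target_fdr = target_fdr, extend = extend,
              placement = placement, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Detect enriched regions (in-memory pipeline)
#'
#' Runs the complete per-chromosome pipeline on already-loaded reads: bin,
#' denoise (Anscombe + non-local means + inverse), build the random-
#' placement null ensemble, convert the target FDR into a height threshold,
#' and call regions. Chromosomes are processed independently with seed
#' streams keyed by chromosome name, so results do not depend on
#' processing order. Chromosomes with no reads yield no regions.
#'
#' @param reads data.frame of mapped reads (chrom/pos/strand).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size bin width in bp.
#' @param params [nlm_params()].
#' @param B null-ensemble size (>= 2).
#' @param target_fdr target FDR in (0, 1).
#' @param min_peak_ratio,min_length,merge_gap region filters, see
#'   [call_regions()].
#' @param seed master seed.
#' @param placement null read-placement model.
#' @param extend fragment extension in bp.
#' @param keep_tracks also return the denoised tracks and FDR curves
#'   (memory permitting).
#' @return list with `regions` (one data.frame across chromosomes),
#'   `thresholds` (per-chromosome data.frame: n_reads, p_cut, fdr,
#'   height_threshold, met, n_regions), and when `keep_tracks` the
#'   `tracks`, `binned` and `curves` lists.
#' @export
#' @examples
#' cfg <- synthetic_config(2e5, 0.05,
#'                         data.frame(start = 5e4, end = 7e4, fold = 8),
#'                         bin_size = 1000, seed = 3)
#' gen <- generate_reads(cfg)
#' res <- detect_regions(gen$reads, c(chrSim = 2e5), bin_size = 1000,
#'                       B = 5, seed = 3)
#' res$regions
detect_regions <- function(reads, chrom_sizes, bin_size = 1000,
                           params = nlm_params(), B = 20,
                           target_fdr = 0.01, min_peak_ratio = 1,
                           min_length = 0, merge_gap = 0, seed = 1,
                           placement = "multinomial", extend = 0,
                           keep_tracks = FALSE) {
  binned <- bin_reads(reads, chrom_sizes, bin_size, extend = extend)
  region_list <- list()
  thr_rows <- list()
  tracks <- list()
  curves <- list()
  for (chr in names(binned)) {
    tr <- binned[[chr]]
    n_reads <- sum(tr$values)
    if (n_reads == 0) {
      thr_rows[[chr]] <- data.frame(chrom = chr, n_reads = 0, p_cut = NA,
                                    fdr = NA, height_threshold = NA,
                                    met = NA, n_regions = 0)
      next
    }
    den <- denoise_track(tr, params)
    ens <- build_null_ensemble(tr, B = B, params = params,
                               seed = derive_seed(seed, chr),
                               placement = placement)
    sel <- choose_threshold(ens, den, target_fdr)
    regs <- if (sel$height_threshold > 0) {
      call_regions(den, sel$height_threshold,
                   min_peak_ratio = min_peak_ratio,
                   min_length = min_length, merge_gap = merge_gap)
    } else {
      call_regions(den, .Machine$double.eps)[0, ]
    }
    region_list[[chr]] <- regs
    thr_rows[[chr]] <- data.frame(chrom = chr, n_reads = n_reads,
                                  p_cut = sel$p_cut, fdr = sel$fdr,
                                  height_threshold = sel$height_threshold,
                                  met = sel$met, n_regions = nrow(regs))
    if (keep_tracks) {
      tracks[[chr]] <- den
      curves[[chr]] <- sel$curve
    }
  }
  regions <- if (length(region_list)) {
    out <- do.call(rbind, region_list)
    out <- out[order(out$chrom, out$start), ]
    rownames(out) <- NULL
    out
  } else {
    call_regions(denoised_track("none", 1, 1, 1), 0.5)[0, ]
  }
  res <- list(regions = regions,
              thresholds = do.call(rbind, c(thr_rows,
                                            make.row.names = FALSE)))
  if (keep_tracks) {
    res$tracks <- tracks
    res$binned <- binned
    res$curves <- curves
  }
  res
}

#' Run the detection pipeline on files
#'
#' File-level front end for [detect_regions()]: reads alignments and
#' chromosome sizes, runs the pipeline, and writes to `out_dir`:
#'
#' * `regions.bed` — called regions (BED6, score = scaled peak ratio),
#' * `denoised.bedGraph` — the denoised coverage,
#' * `fdr_curves.tsv` — the per-chromosome FDR curve
#'   (chrom, p_cut, fdr, height_threshold),
#' * `report.json` — all parameters, the seed, and per-chromosome
#'   thresholds and region counts, sufficient to reproduce the run.
#'
#' @param config a [run_config()].
#' @return the run report (a list), invisibly.
#' @export
run_detect <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input)) stop_misuse("config$input is required")
  sizes <- if (is.character(config$chrom_sizes)) {
    read_chrom_sizes(config$chrom_sizes)
  } else {
    config$chrom_sizes
  }
  if (is.null(sizes)) stop_misuse("config$chrom_sizes is required")
  reads_list <- lapply(config$input, read_alignments,
                       format = config$format)
  reads <- do.call(rbind, reads_list)
  res <- detect_regions(reads, sizes, bin_size = config$bin_size,
                        params = config$params, B = config$B,
                        target_fdr = config$target_fdr,
                        min_peak_ratio = config$min_peak_ratio,
                        min_length = config$min_length,
                        merge_gap = config$merge_gap, seed = config$seed,
                        placement = config$placement,
                        extend = config$extend, keep_tracks = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_regions_bed(res$regions, file.path(config$out_dir, "regions.bed"))
  write_bedgraph(res$tracks, file.path(config$out_dir,
                                       "denoised.bedGraph"))
  curve_df <- do.call(rbind, lapply(names(res$curves), function(chr) {
    cbind(chrom = chr, res$curves[[chr]])
  }))
  if (is.null(curve_df)) {
    curve_df <- data.frame(chrom = character(), p_cut = numeric(),
                           fdr = numeric(), height_threshold = numeric())
  }
  utils::write.table(curve_df,
                     file.path(config$out_dir, "fdr_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    parameters = list(
      preset = config$preset, format = config$format,
      bin_size = config$bin_size, min_length = config$min_length,
      min_peak_ratio = config$min_peak_ratio,
      merge_gap = config$merge_gap,
      search_radius = config$params$search_radius,
      patch_length = config$params$patch_length,
      sigma = config$params$sigma, B = config$B,
      target_fdr = config$target_fdr, extend = config$extend,
      placement = config$placement, seed = config$seed),
    input = config$input,
    n_reads_total = nrow(reads),
    chromosomes = res$thresholds,
    n_regions_total = nrow(res$regions))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(report)
}

#' Compare two region BED files
#'
#' Parses both files and reports the overlap ratio in both directions plus
#' region counts — the consistency check used when benchmarking against
#' another caller's output.
#'
#' @param detected_path,reference_path BED3+ file paths.
#' @param quiet suppress the printed summary.
#' @return list with `n_detected`, `n_reference`,
#'   `overlap_detected_in_reference`, `overlap_reference_in_detected`
#'   (fractions in `[0, 1]`).
#' @export
run_compare <- function(detected_path, reference_path, quiet = FALSE) {
  detected <- read_regions_bed(detected_path)
  reference <- read_regions_bed(reference_path)
  out <- list(
    n_detected = nrow(detected),
    n_reference = nrow(reference),
    overlap_detected_in_reference = overlap_ratio(detected, reference),
    overlap_reference_in_detected = overlap_ratio(reference, detected))
  if (!quiet) {
    cat(sprintf("detected regions:  %d\n", out$n_detected))
    cat(sprintf("reference regions: %d\n", out$n_reference))
    cat(sprintf("detected overlapping reference: %.2f%%\n",
                100 * out$overlap_detected_in_reference))
    cat(sprintf("reference overlapping detected: %.2f%%\n",
                100 * out$overlap_reference_in_detected))
  }
  invisible(out)
}
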