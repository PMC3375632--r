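# Build a null_ensemble around an explicit B x M matrix of denoised
# heights, for hand-enumerable FDR examples.
make_ensemble <- function(values, bin_size = 1000,
                          chrom_length = ncol(values) * 1000,
                          chrom = "chrT") {
  structure(list(B = nrow(values), chrom = chrom, bin_size = bin_size,
                 chrom_length = chrom_length, n_reads = sum(values),
                 values = values),
            class = "null_ensemble")
}

make_denoised <- function(values, bin_size = 1000, chrom = "chrT") {
  nlmdomains::denoised_track(chrom, bin_size, values,
                             length(values) * bin_size)
}

write_tmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Small region data.frame from parallel vectors.
make_regions <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, length = end - start,
             stringsAsFactors = FALSE)
}
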