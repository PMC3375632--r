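#' Read mapped-read positions from BED or tab-delimited files
#'
#' Supports two plain-text layouts for mapped reads:
#'
#' * `"bed"`: UCSC BED with at least 3 columns; the 0-based start column is
#'   used as the read position and column 6, when present, as the strand.
#' * `"tab"`: minimal mapper-style output with columns chrom, position
#'   (0-based), strand.
#'
#' Header lines starting with `track`, `browser` or `#` are skipped. Any
#' malformed record aborts with an error naming its line number.
#'
#' @param path input file path.
#' @param format `"bed"` or `"tab"`.
#' @return a data.frame with columns `chrom` (character), `pos` (0-based
#'   integer bp) and `strand` (`"+"` or `"-"`; `"+"` when the input has no
#'   strand column).
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t125\t.\t0\t+", f)
#' read_alignments(f, "bed")
read_alignments <- function(path, format = c("bed", "tab")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_misuse("input file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad_line <- function(i, why) {
    stop_misuse(sprintf("malformed %s record at line %d of %s: %s",
                        format, lineno[i], path, why))
  }
  nf <- lengths(fields)
  if (format == "bed") {
    if (any(nf < 3)) bad_line(which(nf < 3)[1], "fewer than 3 columns")
    chrom <- vapply(fields, `[[`, "", 1)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
    if (anyNA(start) || anyNA(end)) {
      bad_line(which(is.na(start) | is.na(end))[1],
               "non-numeric start or end")
    }
    if (any(start < 0)) bad_line(which(start < 0)[1], "negative start")
    if (any(start > end)) bad_line(which(start > end)[1], "start > end")
    strand <- rep("+", length(chrom))
    has6 <- nf >= 6
    if (any(has6)) {
      s6 <- vapply(fields[has6], `[[`, "", 6)
      strand[has6] <- ifelse(s6 == "-", "-", "+")
    }
    pos <- start
  } else {
    if (any(nf < 3)) bad_line(which(nf < 3)[1], "fewer than 3 columns")
    chrom <- vapply(fields, `[[`, "", 1)
    pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
    strand <- vapply(fields, `[[`, "", 3)
    if (anyNA(pos)) bad_line(which(is.na(pos))[1], "non-numeric position")
    if (any(pos < 0)) bad_line(which(pos < 0)[1], "negative position")
    ok <- strand %in% c("+", "-")
    if (!all(ok)) bad_line(which(!ok)[1], "strand is not '+' or '-'")
  }
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a UCSC chrom.sizes table
#'
#' @param path two-column tab-delimited file: chromosome name, length in bp.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_misuse("chrom.sizes file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    stop_misuse("malformed chrom.sizes record at line ",
                which(lengths(fields) < 2)[1], " of ", path)
  }
  nm <- vapply(fields, `[[`, "", 1)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  if (anyNA(len) || any(len <= 0)) {
    stop_misuse("chromosome lengths must be positive numbers in ", path)
  }
  if (anyDuplicated(nm)) {
    stop_misuse("duplicated chromosome name in ", path, ": ",
                nm[duplicated(nm)][1])
  }
  stats::setNames(len, nm)
}

#' Bin mapped reads into fixed-width count histograms
#'
#' Each read increments the bin containing its 5' leftmost position,
#' `floor(pos / bin_size)`. Duplicate reads are retained and strand is
#' ignored; the optional `extend` shifts each read to the midpoint of an
#' assumed fragment of that length (0 disables any extension, the default
#' model).
#'
#' @param reads data.frame as returned by [read_alignments()].
#' @param chrom_sizes named vector from [read_chrom_sizes()].
#' @param bin_size bin width in bp.
#' @param extend assumed fragment length in bp; reads are shifted by
#'   `floor(extend / 2)` along their strand before binning. Default 0.
#' @return named list of [binned_track()] objects, one per chromosome in
#'   `chrom_sizes` (chromosomes without reads get all-zero tracks).
#' @export
#' @examples
#' reads <- data.frame(chrom = "chr1", pos = c(0L, 10L, 30L), strand = "+")
#' bin_reads(reads, c(chr1 = 50), bin_size = 25)
bin_reads <- function(reads, chrom_sizes, bin_size, extend = 0) {
  stopifnot(is.data.frame(reads),
            all(c("chrom", "pos", "strand") %in% names(reads)))
  if (bin_size <= 0) stop_misuse("bin_size must be > 0")
  if (extend < 0) stop_misuse("extend must be >= 0")
  unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop_misuse("reads on chromosome(s) absent from chrom_sizes: ",
                paste(unknown, collapse = ", "))
  }
  pos <- reads$pos
  if (extend > 0) {
    shift <- floor(extend / 2)
    pos <- pos + ifelse(reads$strand == "-", -shift, shift)
    pos <- pmin(pmax(pos, 0), chrom_sizes[reads$chrom] - 1)
  }
  bad <- pos < 0 | pos >= chrom_sizes[reads$chrom]
  if (any(bad)) {
    i <- which(bad)[1]
    stop_misuse(sprintf(
      "read position %d outside chromosome %s (length %s)",
      reads$pos[i], reads$chrom[i], format(chrom_sizes[reads$chrom[i]])))
  }
  tracks <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    m <- as.integer(ceiling(len / bin_size))
    p <- pos[reads$chrom == chr]
    counts <- tabulate(as.integer(p %/% bin_size) + 1L, nbins = m)
    binned_track(chr, bin_size, counts, len)
  })
  stats::setNames(tracks, names(chrom_sizes))
}

#' Write coverage tracks as bedGraph
#'
#' Emits one record per non-zero bin, 0-based half-open, with the last bin
#' truncated at the chromosome end.
#'
#' @param tracks a single coverage track or a list of them.
#' @param path output path.
#' @param track_line add a UCSC `track type=bedGraph` header line.
#' @param name track name used in the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path, track_line = FALSE,
                           name = "coverage") {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  lines <- character()
  if (track_line) {
    lines <- sprintf("track type=bedGraph name=\"%s\"", name)
  }
  for (tr in tracks) {
    stopifnot(inherits(tr, "coverage_track"))
    v <- tr$values
    nz <- which(v != 0)
    if (!length(nz)) next
    start <- (nz - 1) * tr$bin_size
    end <- pmin(nz * tr$bin_size, tr$chrom_length)
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s", tr$chrom,
                              format(start, scientific = FALSE, trim = TRUE),
                              format(end, scientific = FALSE, trim = TRUE),
                              format(v[nz], digits = 15,
                                     scientific = FALSE, trim = TRUE)))
  }
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_misuse("cannot write bedGraph to ", path)
  invisible(path)
}

#' Parse a bedGraph file
#'
#' Companion reader for [write_bedgraph()], mainly for audit and
#' round-tripping.
#'
#' @param path bedGraph file path.
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop_misuse("bedGraph file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    stop_misuse("malformed bedGraph record at line ",
                which(keep)[which(lengths(fields) < 4)[1]], " of ", path)
  }
  data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end = as.numeric(vapply(fields, `[[`, "", 3)),
    value = as.numeric(vapply(fields, `[[`, "", 4)),
    stringsAsFactors = FALSE)
}

#' Write mapped reads as BED
#'
#' Each read becomes a 1-bp BED6 interval at its 5' position; used by the
#' synthetic generator's `simulate` command so generated datasets can be fed
#' back through the standard input path.
#'
#' @param reads data.frame with chrom, pos, strand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  lines <- sprintf("%s\t%d\t%d\tread_%d\t0\t%s", reads$chrom, reads$pos,
                   reads$pos + 1L, seq_len(nrow(reads)), reads$strand)
  writeLines(lines, path)
  invisible(path)
}
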