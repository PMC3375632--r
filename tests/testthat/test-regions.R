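test_that("run detection follows the hand-traced example", {
  tr <- denoised_track("chr1", 1000, c(0, 5, 6, 5, 0), 5000)
  regs <- call_regions(tr, height_threshold = 4)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start, 1000)
  expect_equal(regs$end, 4000)
  expect_equal(regs$length, 3000)
  expect_equal(regs$peak_height, 6)
  expect_equal(regs$peak_ratio, 1.5)
})

test_that("a threshold above the global maximum calls nothing", {
  tr <- denoised_track("chr1", 1000, c(0, 5, 6, 5, 0), 5000)
  expect_equal(nrow(call_regions(tr, 7)), 0)
  expect_error(call_regions(tr, 0), "> 0")
})

test_that("merge_gap bridges short sub-threshold gaps", {
  tr <- denoised_track("chr1", 1000, c(5, 5, 1, 5, 5), 5000)
  split <- call_regions(tr, 4, merge_gap = 0)
  expect_equal(nrow(split), 2)
  merged <- call_regions(tr, 4, merge_gap = 1)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(0, 5000))
  # gap of 2 bins survives merge_gap 1
  tr2 <- denoised_track("chr1", 1000, c(5, 1, 1, 5, 5), 5000)
  expect_equal(nrow(call_regions(tr2, 4, merge_gap = 1)), 2)
})

test_that("length and peak-ratio filters drop candidates", {
  tr <- denoised_track("chr1", 1000, c(5, 0, 9, 9, 9, 0, 26), 7000)
  all3 <- call_regions(tr, 4)
  expect_equal(nrow(all3), 3)
  expect_true(all(all3$peak_ratio >= 1))
  expect_equal(nrow(call_regions(tr, 4, min_length = 2000)), 1)
  expect_equal(call_regions(tr, 4, min_peak_ratio = 2)$peak_height,
               c(9, 26))
})

test_that("called regions are disjoint, sorted, and shrink as the threshold rises", {
  set.seed(3)
  v <- pmax(0, rpois(300, 2) + rep(c(0, 12, 0, 8, 0), each = 60))
  tr <- denoised_track("chr5", 1000, v, 3e5)
  lo <- call_regions(tr, 5)
  expect_true(all(diff(lo$start) > 0))
  expect_true(all(lo$start[-1] >= lo$end[-nrow(lo)]))
  hi <- call_regions(tr, 9)
  expect_lte(sum(hi$length), sum(lo$length))
  # every hi region is contained in some lo region (super-level sets nest)
  for (k in seq_len(nrow(hi))) {
    expect_true(any(lo$start <= hi$start[k] & hi$end[k] <= lo$end))
  }
  # union of called bins is exactly the super-threshold bin set
  bins <- unlist(lapply(seq_len(nrow(lo)), function(k) {
    (lo$start[k] / 1000 + 1):(lo$end[k] / 1000)
  }))
  expect_equal(sort(bins), which(v >= 5))
})

test_that("overlap ratio counts detected regions hitting the reference", {
  a <- make_regions(c(0, 5000), c(1000, 6000))
  expect_equal(overlap_ratio(a, a), 1)
  b <- make_regions(c(2000, 7000), c(3000, 8000))
  expect_equal(overlap_ratio(a, b), 0)
  c2 <- make_regions(c(900, 20000), c(1100, 21000))
  expect_equal(overlap_ratio(c2, a), 0.5)
  # direction matters; the symmetric mode averages the two
  expect_equal(overlap_ratio(a, c2), 0.5)
  expect_equal(overlap_ratio(c2, a, mode = "symmetric"), 0.5)
  # order within a set is irrelevant
  expect_equal(overlap_ratio(c2[2:1, ], a), 0.5)
  expect_true(is.na(overlap_ratio(a[0, ], a)))
  # bookended (touching, 0 bp shared) intervals do not count as overlap
  d <- make_regions(1000, 2000)
  expect_equal(overlap_ratio(d, make_regions(0, 1000)), 0)
})

test_that("length summary counts regions per cutoff", {
  r <- make_regions(rep(0, 3), c(4000, 12000, 3000))
  s <- region_length_summary(r, c(4000, 10000))
  expect_equal(unname(s$counts), c(2L, 1L))
  expect_equal(s$max_length, 12000)
  empty <- region_length_summary(r[0, ], c(4000, 10000))
  expect_equal(unname(empty$counts), c(0L, 0L))
  expect_equal(empty$max_length, 0)
  one <- region_length_summary(make_regions(0, 5000), c(4000, 10000))
  expect_equal(unname(one$counts), c(1L, 0L))
})

test_that("region BED output applies the score scaling and round-trips", {
  regs <- data.frame(chrom = "chr1", start = 1000, end = 4000,
                     length = 3000, peak_height = 6, threshold = 4,
                     peak_ratio = 1.5)
  f <- tempfile(fileext = ".bed")
  write_regions_bed(regs, f)
  expect_equal(readLines(f), "chr1\t1000\t4000\tregion_1\t150\t.")
  back <- read_regions_bed(f)
  expect_equal(back$start, 1000)
  expect_equal(back$end, 4000)
  expect_equal(back$score, 150)

  write_regions_bed(regs[0, ], f)
  expect_equal(length(readLines(f)), 0)
  expect_equal(nrow(read_regions_bed(f)), 0)

  bad <- write_tmp("chr1\t5000\t4000")
  expect_error(read_regions_bed(bad), "line 1")
})
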