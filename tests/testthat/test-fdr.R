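test_that("null simulation conserves reads and is seed-deterministic", {
  zero <- simulate_null_track(0, 1e5, 1000, seed = 1)
  expect_equal(sum(track_values(zero)), 0)

  tr <- simulate_null_track(10000, 1e5, 1000, seed = 1)
  v <- track_values(tr)
  expect_equal(sum(v), 10000)
  expect_equal(length(v), 100)
  expect_lt(max(abs(v - 100)), 50) # binomial concentration at this depth

  again <- simulate_null_track(10000, 1e5, 1000, seed = 1)
  expect_identical(track_values(again), v)
  other <- simulate_null_track(10000, 1e5, 1000, seed = 2)
  expect_false(identical(track_values(other), v))
})

test_that("independent-Poisson placement matches the rate in expectation", {
  tr <- simulate_null_track(50000, 1e6, 1000, seed = 3,
                            placement = "poisson")
  v <- track_values(tr)
  expect_equal(length(v), 1000)
  expect_lt(abs(mean(v) - 50), 1) # mean 50 per bin, se ~0.22
})

test_that("the ensemble shares the observed grid and is reproducible", {
  obs <- simulate_null_track(2000, 5e4, 1000, seed = 7, chrom = "chr9")
  ens <- build_null_ensemble(obs, B = 5, seed = 11)
  expect_equal(dim(ens$values), c(5, 50))
  expect_equal(ens$chrom, "chr9")
  expect_equal(ens$n_reads, 2000)
  ens2 <- build_null_ensemble(obs, B = 5, seed = 11)
  expect_identical(ens$values, ens2$values)
  expect_error(build_null_ensemble(obs, B = 1), "B must be >= 2")

  none <- binned_track("chr9", 1000, rep(0L, 50), 5e4)
  ens0 <- build_null_ensemble(none, B = 3, seed = 1)
  expect_true(all(ens0$values == 0))
})

test_that("per-bin p-values count null exceedances", {
  ens <- make_ensemble(matrix(c(1, 2, 3, 4,    # bin 1: obs 2.5 -> 2/4
                                5, 5, 5, 5,    # bin 2: obs 10  -> 0
                                5, 5, 5, 5),   # bin 3: obs 1   -> 1
                              nrow = 4))
  obs <- make_denoised(c(2.5, 10, 1))
  expect_equal(per_bin_pvalues(obs, ens), c(0.5, 0, 1))
  wrong_grid <- make_denoised(c(1, 2))
  expect_error(per_bin_pvalues(wrong_grid, ens), "grid")
})

test_that("FDR estimate matches a hand enumeration on a 5-bin toy", {
  # explicit B = 3 ensemble; expected values recomputed in-test by
  # enumerating every indicator in the leave-one-out definition
  vals <- matrix(c(1, 2, 3, 4, 5,
                   2, 1, 5, 3, 4,
                   3, 3, 1, 5, 2), nrow = 3, byrow = TRUE)
  ens <- make_ensemble(vals, bin_size = 1000)
  obs <- make_denoised(c(10, 0, 3, 10, 0))
  p <- per_bin_pvalues(obs, ens)
  expect_equal(p, c(0, 1, 1 / 3, 0, 1))
  B <- 3
  pstar <- matrix(0, B, 5)
  for (b in 1:B) {
    for (i in 1:5) {
      pstar[b, i] <- sum(vals[-b, i] > vals[b, i]) / (B - 1)
    }
  }
  for (pc in c(0, 1 / 3, 0.5, 2 / 3, 1)) {
    d_b <- vapply(1:B, function(b) sum(pstar[b, ] <= pc), numeric(1))
    denom <- sum(p <= pc)
    want <- if (denom == 0) 0 else min(1, mean(d_b) / denom)
    expect_equal(estimate_fdr(ens, p, pc), want)
  }
})

test_that("FDR respects conventions: 1 at full cutoff, 0 on empty calls", {
  set.seed(12)
  ens <- make_ensemble(matrix(runif(4 * 20, 1, 2), nrow = 4))
  obs_hi <- make_denoised(rep(10, 20))   # everything called
  p_hi <- per_bin_pvalues(obs_hi, ens)
  expect_identical(estimate_fdr(ens, p_hi, 1), 1)
  obs_lo <- make_denoised(rep(0, 20))    # nothing called at p_cut 0
  p_lo <- per_bin_pvalues(obs_lo, ens)
  expect_equal(sum(p_lo == 0), 0)
  expect_equal(estimate_fdr(ens, p_lo, 0), 0)
  expect_error(estimate_fdr(ens, p_hi, 1.5), "p_cut")
})

test_that("FDR numerator and denominator grow with the cutoff", {
  set.seed(19)
  obs <- simulate_null_track(5000, 1e5, 1000, seed = 21)
  ens <- build_null_ensemble(obs, B = 10, seed = 22)
  p <- per_bin_pvalues(denoise_track(obs), ens)
  curve <- fdr_curve(ens, p)
  denom <- vapply(curve$p_cut, function(pc) sum(p <= pc), numeric(1))
  expect_true(all(diff(denom) >= 0))
  expect_true(all(curve$fdr >= 0 & curve$fdr <= 1))
  expect_true(all(diff(curve$height_threshold) <= 0))
  expect_identical(curve$fdr[nrow(curve)], 1)
})

test_that("threshold selection keeps the largest achievable cutoff", {
  # planted signal far above a tight null: every achievable cutoff up to
  # 1/2 estimates FDR 0.5 on this toy, so p_cut = 1/2 is kept
  vals <- matrix(rep(c(1, 1.1, 0.9, 1.05), times = 6), nrow = 4)
  ens <- make_ensemble(vals)
  obs <- make_denoised(c(10, 10, 10, 1, 1, 1))
  sel <- choose_threshold(ens, obs, target_fdr = 0.5)
  expect_true(sel$met)
  expect_gte(sel$p_cut, 1 / 4)
  expect_equal(nrow(sel$curve), 5)
  expect_error(choose_threshold(ens, obs, 0), "target_fdr")
})

test_that("an unreachable target takes the flagged degenerate path", {
  set.seed(29)
  obs <- simulate_null_track(3000, 1e5, 1000, seed = 31)
  ens <- build_null_ensemble(obs, B = 5, seed = 32)
  den <- denoise_track(obs)
  sel <- choose_threshold(ens, den, target_fdr = 1e-6)
  expect_false(sel$met)
  expect_equal(sel$p_cut, 0)
  expect_equal(sel$height_threshold, max(ens$values))
})

test_that("a null-drawn observed track yields roughly uniform p-values", {
  obs <- simulate_null_track(20000, 5e5, 1000, seed = 41)
  ens <- build_null_ensemble(obs, B = 25, seed = 42)
  p <- per_bin_pvalues(denoise_track(obs), ens)
  sp <- sort(p)
  m <- length(sp)
  ks <- max(abs(sp - (seq_len(m) - 1) / m), abs(sp - seq_len(m) / m))
  expect_lt(ks, 0.15) # small-scale check; the full condition runs at B = 50
})
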