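test_that("patch distance is zero for identical windows and symmetric", {
  s <- c(1, 1, 1, 9, 1, 1, 1)
  expect_equal(patch_sq_distance(s, 4, 4, 3), 0)
  expect_equal(patch_sq_distance(s, 2, 6, 3), 0) # both windows (1,1,1)
  set.seed(5)
  x <- rnorm(30)
  for (k in 1:20) {
    ij <- sample.int(30, 2)
    expect_equal(patch_sq_distance(x, ij[1], ij[2], 5),
                 patch_sq_distance(x, ij[2], ij[1], 5))
  }
  expect_error(patch_sq_distance(s, 0, 3, 3), "out of range")
  expect_error(patch_sq_distance(s, 1, 8, 3), "out of range")
})

test_that("patch distance expands to the sum of squared differences", {
  # windows (0,0,0) at bin 2 and (0,2,0) at bin 5: one difference of 2
  s <- c(0, 0, 0, 0, 2, 0, 0)
  expect_equal(patch_sq_distance(s, 2, 5, 3), 4)
  # truncated edge window rescaled by L / n_compared
  s2 <- c(3, 0, 0, 0, 0)
  # i = 1, j = 4, L = 3: valid offsets t in {0, 1} -> diffs (3-0, 0-0)
  expect_equal(patch_sq_distance(s2, 1, 4, 3), 9 * 3 / 2)
})

test_that("nlm_params validates and centres even patches", {
  p <- nlm_params()
  expect_equal(c(p$search_radius, p$patch_length, p$sigma), c(10, 15, 10))
  expect_equal(nlm_params(patch_length = 4)$patch_length, 5)
  expect_error(nlm_params(search_radius = -1), "non-negative")
  expect_error(nlm_params(sigma = 0), "sigma")
})

test_that("constant signals are exact fixed points", {
  x <- rep(3.7, 40)
  out <- nlmeans_denoise(x, nlm_params(search_radius = 6,
                                       patch_length = 5, sigma = 2))
  expect_equal(out, x)
})

test_that("the large-sigma limit is the plain search-window mean", {
  set.seed(8)
  x <- rnorm(25)
  R <- 4
  out <- nlmeans_denoise(x, nlm_params(search_radius = R,
                                       patch_length = 5, sigma = 1e8))
  expected <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - R):min(length(x), i + R)])
  }, numeric(1))
  expect_equal(out, expected, tolerance = 1e-9)
})

test_that("vectorized denoiser matches the naive reference", {
  set.seed(17)
  for (rep in 1:10) {
    m <- sample(5:120, 1)
    x <- rpois(m, 4) + rnorm(m, sd = 0.3)
    R <- sample(0:12, 1)
    L <- sample(1:17, 1)
    sigma <- runif(1, 0.5, 15)
    expect_equal(nlmeans_denoise(x, nlm_params(R, L, sigma)),
                 naive_nlmeans(x, R, L, sigma), tolerance = 1e-12)
  }
})

test_that("weight matrix is row-stochastic and reproduces the denoiser", {
  set.seed(23)
  x <- c(rpois(30, 3), rpois(10, 30), rpois(30, 3))
  p <- nlm_params(search_radius = 8, patch_length = 7, sigma = 4)
  w <- nlmeans_weights(x, p)
  expect_true(all(w >= 0))
  expect_equal(rowSums(w), rep(1, length(x)), tolerance = 1e-12)
  expect_equal(as.numeric(w %*% x), nlmeans_denoise(x, p),
               tolerance = 1e-12)
})

test_that("output stays within the search-window value range", {
  set.seed(31)
  x <- rpois(200, 5) + c(rep(0, 90), rep(40, 20), rep(0, 90))
  R <- 10
  out <- nlmeans_denoise(x, nlm_params(R, 15, 10))
  win_min <- vapply(seq_along(x), function(i) {
    min(x[max(1, i - R):min(length(x), i + R)])
  }, numeric(1))
  win_max <- vapply(seq_along(x), function(i) {
    max(x[max(1, i - R):min(length(x), i + R)])
  }, numeric(1))
  expect_true(all(out >= win_min - 1e-12))
  expect_true(all(out <= win_max + 1e-12))
})

test_that("shifting a padded signal shifts the output", {
  set.seed(37)
  core <- rpois(40, 6)
  pad <- 30
  x1 <- c(rep(0, pad), core, rep(0, pad))
  x2 <- c(rep(0, pad + 5), core, rep(0, pad - 5))
  p <- nlm_params(search_radius = 5, patch_length = 5, sigma = 3)
  o1 <- nlmeans_denoise(x1, p)
  o2 <- nlmeans_denoise(x2, p)
  keep <- (pad + 1):(pad + 40)
  expect_equal(o1[keep], o2[keep + 5], tolerance = 1e-12)
})

test_that("an isolated spike is flattened, neighbours raised, bounds kept", {
  x <- rep(0, 41)
  x[21] <- 40
  p <- nlm_params(10, 15, 10)
  tr <- binned_track("chr1", 25, x, 41 * 25)
  out <- track_values(denoise_track(tr, p))
  expect_lt(out[21], 40)
  expect_true(all(out[c(20, 22)] > 0))
  expect_true(all(out >= 0 & out <= 40))
})

test_that("identical repeated segments denoise identically", {
  # two copies of the same enriched segment, placed so that neither the
  # search windows nor the patches of the compared bins touch a boundary:
  # the weight formula is translation-symmetric, so the profiles match
  x <- rep(1, 80)
  x[21:25] <- 20
  x[51:55] <- 20
  out <- nlmeans_denoise(x, nlm_params(10, 5, 5))
  expect_equal(out[16:30], out[46:60], tolerance = 1e-12)
})

test_that("all-zero tracks denoise to all zero", {
  tr <- binned_track("chr1", 1000, rep(0L, 50), 50000)
  expect_equal(track_values(denoise_track(tr)), rep(0, 50))
})

test_that("denoising reduces RMSE against a piecewise-constant truth", {
  p <- nlm_params(10, 15, 10)
  truth <- rep(c(3, 30, 3, 30, 3), times = c(150, 60, 120, 60, 150))
  wins <- 0
  n_trials <- 30
  for (s in seq_len(n_trials)) {
    set.seed(1000 + s)
    noisy <- rpois(length(truth), truth)
    tr <- binned_track("chr1", 1000, noisy, length(truth) * 1000)
    den <- track_values(denoise_track(tr, p))
    if (sqrt(mean((den - truth)^2)) < sqrt(mean((noisy - truth)^2))) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, n_trials - 1)
})
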