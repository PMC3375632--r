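#' Parameters for the 1-D non-local-means denoiser
#'
#' @param search_radius half-range of the search window, in bins: weights
#'   for bin `i` are computed over `j` in `[i - R, i + R]`. Default 10.
#' @param patch_length full length of the similarity patch, in bins; even
#'   values are incremented to the next odd value so patches stay centred.
#'   Default 15.
#' @param sigma weight decay scale, on the Anscombe scale when used through
#'   [denoise_track()]. Default 10.
#' @return an object of class `nlm_params`.
#' @export
#' @examples
#' nlm_params()
#' nlm_params(search_radius = 5, patch_length = 5, sigma = 3)
nlm_params <- function(search_radius = 10, patch_length = 15, sigma = 10) {
  stopifnot(length(search_radius) == 1, length(patch_length) == 1,
            length(sigma) == 1)
  if (search_radius < 0 || search_radius != floor(search_radius)) {
    stop_misuse("search_radius must be a non-negative integer")
  }
  if (patch_length < 1 || patch_length != floor(patch_length)) {
    stop_misuse("patch_length must be a positive integer")
  }
  if (patch_length %% 2 == 0) patch_length <- patch_length + 1
  if (sigma <= 0) stop_misuse("sigma must be > 0")
  structure(list(search_radius = as.integer(search_radius),
                 patch_length = as.integer(patch_length),
                 sigma = as.numeric(sigma)),
            class = "nlm_params")
}

#' @export
print.nlm_params <- function(x, ...) {
  cat(sprintf("<nlm_params> search radius R = %d bins, patch L = %d bins, sigma = %g\n",
              x$search_radius, x$patch_length, x$sigma))
  invisible(x)
}

#' Squared distance between two signal patches
#'
#' The similarity measure underlying the non-local-means weights: the
#' squared Euclidean distance between the length-`L` windows centred at bins
#' `i` and `j`. At signal boundaries the windows are truncated to the
#' positions where both are defined, and the sum is rescaled by
#' `L / n_compared` so truncated comparisons stay on the same scale as full
#' ones (for two full interior windows this is exactly the plain sum of
#' squared differences).
#'
#' @param signal numeric vector.
#' @param i,j 1-based bin indices.
#' @param L patch length in bins (even values are bumped to the next odd).
#' @return non-negative scalar; symmetric in `i`, `j`; 0 when `i == j`.
#' @export
#' @examples
#' patch_sq_distance(c(1, 1, 1, 9, 1, 1, 1), 2, 6, L = 3) # identical patches
patch_sq_distance <- function(signal, i, j, L) {
  m <- length(signal)
  if (i < 1 || i > m || j < 1 || j > m) {
    stop_misuse("patch centre index out of range")
  }
  if (L %% 2 == 0) L <- L + 1
  h <- (L - 1) / 2
  t <- (-h):h
  ok <- i + t >= 1 & i + t <= m & j + t >= 1 & j + t <= m
  d <- signal[i + t[ok]] - signal[j + t[ok]]
  sum(d^2) * L / sum(ok)
}

#' Denoise a 1-D signal with non-local means
#'
#' Replaces each value by a weighted average of the values in its search
#' window, `NL(x_i) = sum_j w(i, j) x_j`, with weights
#' `w(i, j) = exp(-||N(x_i) - N(x_j)||^2 / (2 sigma^2)) / Z(i)`
#' decaying in the squared distance between the local patches around `i`
#' and `j` ([patch_sq_distance()]) and `Z(i)` normalizing each row to 1.
#' Bins whose neighbourhood resembles many others (flat background, or one
#' of several similar enriched regions) are averaged strongly; isolated
#' structure is preserved.
#'
#' Runs in O(M * R) vectorized passes (O(M * R * L) work) and O(M) extra
#' space per chromosome.
#'
#' @param signal numeric vector of length >= 1.
#' @param params an [nlm_params()] object.
#' @return numeric vector, same length as `signal`; each value lies within
#'   the range of `signal` over its search window.
#' @export
#' @examples
#' x <- c(0, 0, 0, 8, 0, 0, 0)
#' nlmeans_denoise(x, nlm_params(search_radius = 3, patch_length = 3, sigma = 2))
nlmeans_denoise <- function(signal, params = nlm_params()) {
  stopifnot(inherits(params, "nlm_params"))
  m <- length(signal)
  if (m < 1) stop_misuse("signal must have length >= 1")
  h <- (params$patch_length - 1) / 2
  L <- params$patch_length
  two_s2 <- 2 * params$sigma^2
  num <- signal          # d = 0: self weight exp(0) = 1
  den <- rep(1, m)
  for (d in seq_len(min(params$search_radius, m - 1))) {
    nd <- m - d
    e <- (signal[seq_len(nd)] - signal[(1 + d):m])^2
    cs <- c(0, cumsum(e))
    idx <- seq_len(nd)
    lo <- pmax(1L, idx - h)
    hi <- pmin(nd, idx + h)
    dist <- L * (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    w <- exp(-dist / two_s2)
    # distance is symmetric: the same weight links (i, i+d) and (i+d, i)
    num[idx] <- num[idx] + w * signal[idx + d]
    den[idx] <- den[idx] + w
    num[idx + d] <- num[idx + d] + w * signal[idx]
    den[idx + d] <- den[idx + d] + w
  }
  num / den
}

#' Explicit non-local-means weight matrix
#'
#' Materializes the full `M x M` matrix of normalized weights `w(i, j)` used
#' by [nlmeans_denoise()] (zero outside the search window). Quadratic in
#' memory, so intended for audit and testing on short signals: each row is a
#' probability vector, and `weights %*% signal` reproduces the denoiser
#' output.
#'
#' @inheritParams nlmeans_denoise
#' @return numeric matrix with rows summing to 1.
#' @export
nlmeans_weights <- function(signal, params = nlm_params()) {
  stopifnot(inherits(params, "nlm_params"))
  m <- length(signal)
  if (m < 1) stop_misuse("signal must have length >= 1")
  two_s2 <- 2 * params$sigma^2
  w <- matrix(0, m, m)
  for (i in seq_len(m)) {
    js <- max(1, i - params$search_radius):min(m, i + params$search_radius)
    d <- vapply(js, function(j) {
      patch_sq_distance(signal, i, j, params$patch_length)
    }, numeric(1))
    w[i, js] <- exp(-d / two_s2)
  }
  sweep(w, 1, rowSums(w), "/")
}

#' Denoise a binned count track
#'
#' The full per-chromosome denoising stage: Anscombe transform, non-local
#' means on the stabilized signal, inverse transform (clipped at 0). Bins
#' are never mixed across chromosomes.
#'
#' @param track a [binned_track()].
#' @param params an [nlm_params()] object.
#' @return a `denoised_track` on the same bin grid.
#' @export
denoise_track <- function(track, params = nlm_params()) {
  stopifnot(inherits(track, "binned_track"))
  y <- anscombe(track)
  z <- nlmeans_denoise(y$values, params)
  inverse_anscombe(stabilized_track(track$chrom, track$bin_size, z,
                                    track$chrom_length))
}
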