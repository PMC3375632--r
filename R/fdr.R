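#' Simulate one random-placement null track
#'
#' Draws `n_reads` positions uniformly over the chromosome and bins them,
#' emulating a dataset with the same sequencing depth but no binding signal.
#' The default `"multinomial"` placement keeps the total read count exact,
#' with per-bin counts Binomial(n, bin/chrom) ~ Poisson; `"poisson"` draws
#' each bin independently as Poisson(n * bin_width / chrom_length), so the
#' total is only equal in expectation.
#'
#' @param n_reads number of reads to place.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin width in bp.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param placement `"multinomial"` (default) or `"poisson"`.
#' @param chrom chromosome name carried on the returned track.
#' @return a [binned_track()].
#' @export
#' @examples
#' simulate_null_track(1000, 1e5, 1000, seed = 1)
simulate_null_track <- function(n_reads, chrom_length, bin_size,
                                seed = NULL,
                                placement = c("multinomial", "poisson"),
                                chrom = "chrNull") {
  placement <- match.arg(placement)
  if (n_reads < 0) stop_misuse("n_reads must be >= 0")
  m <- as.integer(ceiling(chrom_length / bin_size))
  counts <- with_seed(seed, {
    if (placement == "multinomial") {
      pos <- floor(stats::runif(n_reads) * chrom_length)
      pos <- pmin(pos, chrom_length - 1)
      tabulate(as.integer(pos %/% bin_size) + 1L, nbins = m)
    } else {
      widths <- c(rep(bin_size, m - 1),
                  chrom_length - (m - 1) * bin_size)
      stats::rpois(m, n_reads * widths / chrom_length)
    }
  })
  binned_track(chrom, bin_size, counts, chrom_length)
}

#' Build the empirical null ensemble for one chromosome
#'
#' Runs `B` rounds of the null model: re-place the observed number of reads
#' at random, bin, and push through the identical denoising stage
#' ([denoise_track()]). The resulting `B x M` matrix of denoised null
#' heights is the reference distribution for per-bin p-values and FDR
#' estimation. Each round gets its own child seed derived from `seed` and
#' the chromosome name, so ensembles are reproducible and independent of
#' chromosome processing order.
#'
#' @param observed the observed [binned_track()] (raw counts, not denoised).
#' @param B number of simulation rounds (>= 2). Default 20.
#' @param params [nlm_params()] used for the observed data.
#' @param seed master integer seed, or `NULL`.
#' @param placement read-placement model, see [simulate_null_track()].
#' @return an object of class `null_ensemble`: list with `B`, `chrom`,
#'   `bin_size`, `chrom_length`, `n_reads`, and `values` (a `B x M` matrix
#'   of denoised null heights).
#' @export
build_null_ensemble <- function(observed, B = 20, params = nlm_params(),
                                seed = NULL,
                                placement = c("multinomial", "poisson")) {
  stopifnot(inherits(observed, "binned_track"))
  placement <- match.arg(placement)
  if (B < 2) stop_misuse("B must be >= 2 (leave-one-out FDR needs it)")
  n <- sum(observed$values)
  m <- n_bins(observed)
  vals <- matrix(0, nrow = B, ncol = m)
  for (b in seq_len(B)) {
    sb <- if (is.null(seed)) NULL else derive_seed(seed, observed$chrom, b)
    tr <- simulate_null_track(n, observed$chrom_length, observed$bin_size,
                              seed = sb, placement = placement,
                              chrom = observed$chrom)
    vals[b, ] <- track_values(denoise_track(tr, params))
  }
  structure(list(B = as.integer(B), chrom = observed$chrom,
                 bin_size = observed$bin_size,
                 chrom_length = observed$chrom_length,
                 n_reads = n, values = vals),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s: B = %d rounds x %d bins (%s reads/round)\n",
              x$chrom, x$B, ncol(x$values), format(x$n_reads)))
  invisible(x)
}

ensemble_grid_matches <- function(ensemble, track) {
  ensemble$chrom == track$chrom && ensemble$bin_size == track$bin_size &&
    ensemble$chrom_length == track$chrom_length &&
    ncol(ensemble$values) == n_bins(track)
}

#' Per-bin empirical p-values against the null ensemble
#'
#' For bin `i`, `p_i` is the fraction of null rounds whose denoised height
#' strictly exceeds the observed denoised height:
#' `p_i = (1/B) * #\{b : r_i < r*_ib\}`. Small `p_i` means the observed
#' height is unusually large under random read placement. Values lie on the
#' grid `{0, 1/B, ..., 1}`.
#'
#' @param observed a `denoised_track` on the ensemble's bin grid.
#' @param ensemble a [build_null_ensemble()] result.
#' @return numeric vector of length M.
#' @export
per_bin_pvalues <- function(observed, ensemble) {
  stopifnot(inherits(observed, "denoised_track"),
            inherits(ensemble, "null_ensemble"))
  if (!ensemble_grid_matches(ensemble, observed)) {
    stop_misuse("observed track and null ensemble are on different bin grids")
  }
  obs <- track_values(observed)
  colMeans(ensemble$values > matrix(obs, nrow = ensemble$B,
                                    ncol = length(obs), byrow = TRUE))
}

# Leave-one-out null p-values: p*_ib = fraction of the other B - 1 rounds
# whose height at bin i strictly exceeds round b's. B x M matrix.
null_pvalue_matrix <- function(ensemble) {
  B <- ensemble$B
  apply(ensemble$values, 2,
        function(v) (B - rank(v, ties.method = "max")) / (B - 1))
}

#' Estimate the FDR at a p-value cutoff
#'
#' Treats each null round in turn as if it were the observed data and
#' scores it against the remaining rounds: `p*_ib` is the leave-one-out
#' p-value of round `b` at bin `i`, and `d_b = #\{i : p*_ib <= p_cut\}`
#' counts the bins a pure-noise dataset would call at this cutoff. The
#' estimate is
#' `FDR(p_cut) = mean_b(d_b) / #\{i : p_i <= p_cut\}`,
#' clipped to `[0, 1]`, with the convention that an empty denominator (no
#' observed bin passes) gives 0. The non-strict `<=` is used on both sides
#' so numerator and denominator are monotone in `p_cut`.
#'
#' @param ensemble a [build_null_ensemble()] result.
#' @param observed_p per-bin p-values from [per_bin_pvalues()].
#' @param p_cut cutoff in `[0, 1]`.
#' @param .pstar optional precomputed leave-one-out p-value matrix (used by
#'   [fdr_curve()] to avoid recomputation across a grid of cutoffs).
#' @return estimated FDR in `[0, 1]`.
#' @export
estimate_fdr <- function(ensemble, observed_p, p_cut, .pstar = NULL) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (length(p_cut) != 1 || is.na(p_cut) || p_cut < 0 || p_cut > 1) {
    stop_misuse("p_cut must be a single value in [0, 1]")
  }
  if (length(observed_p) != ncol(ensemble$values)) {
    stop_misuse("observed_p length does not match the ensemble grid")
  }
  pstar <- .pstar %||% null_pvalue_matrix(ensemble)
  d_b <- rowSums(pstar <= p_cut)
  denom <- sum(observed_p <= p_cut)
  if (denom == 0) return(0)
  min(1, mean(d_b) / denom)
}

#' FDR as a function of the achievable p-value cutoffs
#'
#' Evaluates [estimate_fdr()] on the full achievable grid
#' `p_cut = k / B, k = 0..B`, together with the height threshold each
#' cutoff induces: the `(1 - p_cut)` empirical quantile (inverse ECDF with
#' averaging at discontinuities, `stats::quantile` type 2) of the pooled
#' `B x M` null denoised heights. `p_cut = 0` maps to the pooled maximum.
#'
#' @inheritParams estimate_fdr
#' @return data.frame with columns `p_cut`, `fdr`, `height_threshold`.
#' @export
fdr_curve <- function(ensemble, observed_p) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  pstar <- null_pvalue_matrix(ensemble)
  grid <- seq(0, ensemble$B) / ensemble$B
  fdr <- vapply(grid, function(pc) {
    estimate_fdr(ensemble, observed_p, pc, .pstar = pstar)
  }, numeric(1))
  pooled <- as.numeric(ensemble$values)
  height <- stats::quantile(pooled, probs = 1 - grid, type = 2,
                            names = FALSE)
  data.frame(p_cut = grid, fdr = fdr, height_threshold = height)
}

#' Convert a target FDR into a height threshold
#'
#' Scans the achievable cutoff grid in increasing order and keeps the
#' largest `p_cut` whose estimated FDR stays at or below `target_fdr`; the
#' region-calling threshold is the pooled-null height quantile that cutoff
#' induces (see [fdr_curve()]). If no cutoff meets the target — which
#' happens whenever even the most stringent achievable cutoff `p_cut = 0`
#' estimates too many null calls per observed call — the degenerate path is
#' taken: `p_cut = 0`, threshold equal to the pooled-null maximum, and
#' `met = FALSE` flags the condition.
#'
#' @param ensemble a [build_null_ensemble()] result.
#' @param observed the observed `denoised_track`.
#' @param target_fdr target false discovery rate in (0, 1).
#' @return list with `p_cut`, `height_threshold`, `fdr` (the estimate at
#'   the chosen cutoff), `met` (logical), and `curve` (the full
#'   [fdr_curve()] data.frame).
#' @export
choose_threshold <- function(ensemble, observed, target_fdr) {
  if (length(target_fdr) != 1 || target_fdr <= 0 || target_fdr >= 1) {
    stop_misuse("target_fdr must be a single value in (0, 1)")
  }
  p <- per_bin_pvalues(observed, ensemble)
  curve <- fdr_curve(ensemble, p)
  ok <- which(curve$fdr <= target_fdr)
  if (length(ok)) {
    pick <- ok[length(ok)] # grid is increasing; keep the largest cutoff
    list(p_cut = curve$p_cut[pick],
         height_threshold = curve$height_threshold[pick],
         fdr = curve$fdr[pick], met = TRUE, curve = curve)
  } else {
    list(p_cut = 0, height_threshold = max(ensemble$values),
         fdr = curve$fdr[1], met = FALSE, curve = curve)
  }
}
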