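---
title: "Detecting broad ChIP-seq enrichment domains with nlmdomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting broad ChIP-seq enrichment domains with nlmdomains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlmdomains)
```

## The problem

RNA polymerase II, and broad histone marks such as H3K36me3 or H3K27me3, do
not produce the sharp, few-hundred-bp pileups that transcription-factor
ChIP-seq does. PolII elongates along the whole transcribed gene body, so its
enrichment forms contiguous domains that routinely span thousands to
hundreds of thousands of base pairs. Narrow-peak callers tuned for point
binding fragment these domains into islands or miss the moderate but
sustained enrichment altogether. `nlmdomains` treats the problem as 1-D
signal recovery: the binned read histogram is a noisy piecewise signal, and
the task is to denoise it and decide, with error control, which stretches
are above what random read placement would produce.

## The model and the pipeline

Per chromosome, reads are counted into fixed-width bins by their 5'-most
position, giving counts $r_i$, $i = 1, \dots, M$. Sequencing noise
(non-specific antibody capture, PCR artefacts, mapping errors) is modelled
as Poisson spike noise around the local mean coverage. The pipeline is:

1. **Variance stabilization.** The Anscombe transform
   $y = 2\sqrt{x + 3/8}$ maps Poisson counts to approximately
   unit-variance, near-Gaussian values; its exact algebraic inverse is
   $x = (y/2)^2 - 3/8$. This matters because the denoiser in step 2 is
   optimal for additive Gaussian noise, not Poisson noise.

2. **Non-local-means denoising.** Each stabilized value is replaced by a
   weighted average over its search window,
   $\mathrm{NL}(x_i) = \sum_j w(i,j)\, x_j$ with
   $w(i,j) \propto \exp\!\big(-\|N(x_i) - N(x_j)\|^2 / (2\sigma^2)\big)$,
   where $N(x_i)$ is the length-$L$ patch centred at bin $i$, and the
   weights over each window are normalized to sum to 1. The premise fits
   ChIP-seq well: many genomic positions share similar local coverage
   shapes (flat background, domain interiors, domain edges), so averaging
   positions with similar neighbourhoods suppresses noise without blurring
   structure the way a fixed-kernel smoother would.

3. **Inverse transform.** Back to the coverage scale, clipped at 0
   (values below $10^{-12}$ are snapped to 0 so empty bins stay exactly
   empty despite floating-point residue).

4. **Empirical-null FDR.** $B$ simulated datasets re-place the same number
   of reads uniformly at random on the chromosome and are processed by the
   identical transform–denoise–invert chain. Per-bin p-values compare the
   observed denoised height to the $B$ null heights; the FDR of a p-value
   cutoff is estimated leave-one-out, by letting each null round play the
   role of observed data against the remaining $B - 1$ rounds. The chosen
   cutoff is mapped to a height threshold via the $(1 - p_\mathrm{cut})$
   quantile of the pooled $B \times M$ null heights.

5. **Region calling.** Maximal runs of bins at or above the threshold
   become regions, optionally merged across short sub-threshold gaps, and
   filtered by minimum length and by the ratio of peak height to
   threshold.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `bin_size` | bin width (bp) | 1000 (broad), 25 (narrow) | the two standard analysis regimes |
| `search_radius` (R) | search half-range (bins) | 10 | window $[i-R, i+R]$ |
| `patch_length` (L) | similarity patch (bins) | 15 | even values bumped to odd so patches are centred |
| `sigma` | weight decay scale | 10 | on the Anscombe scale, since denoising runs there |
| `B` | null simulation rounds | 20 | see below |
| `target_fdr` | FDR target | 0.01 | |
| `min_length` | region length filter (bp) | 4000 (broad), 0 (narrow) | |
| `min_peak_ratio` | peak/threshold filter | 1 (broad), 6.5 (narrow) | |
| `merge_gap` | gap bridging (bins) | 0 | off by default |

Three of these deserve comment.

**R vs L.** The denoiser needs a patch size, a search range and a weight
scale. We fix R as the search half-range and L as the full patch length,
with defaults R = 10 bins, L = 15 bins, sigma = 10. A patch longer than the
search diameter is unusual in image denoising but reasonable here: at 1 kb
bins a 15-bin patch spans 15 kb, enough local context to distinguish
domain interiors, edges and background, while the +/-10-bin search keeps
the method local enough to be fast and to respect chromosome-scale
non-stationarity. Both are plain arguments and can be swapped if a user
prefers the opposite reading.

**sigma.** Interpreted on the stabilized scale, where noise variance is
~1. `sigma = 10` therefore averages aggressively across patches whose
mean-square difference is small relative to $2\sigma^2 = 200$; flat
background is smoothed hard, while patches that differ by a domain edge
(squared differences of tens to hundreds per element) are effectively
excluded.

**B.** Each round costs one full simulate-and-denoise pass, and the
achievable p-value grid is $\{k/B\}$, so B trades resolution against time.
The default B = 20 gives a coarse grid: at a strict target like FDR 0.01
the selection usually degenerates to $p_\mathrm{cut} = 0$, i.e. the
threshold becomes the pooled-null maximum — the most stringent achievable
rule — and the result is flagged (`met = FALSE` in the threshold table).
This is the intended behaviour, not an error: the caller is conservative
when B is small, and raising B refines the grid.

## Boundary and tie policies

* Patches and search windows truncate at chromosome ends. The patch
  distance is `L * mean(squared differences over compared positions)`, so
  an interior comparison is the plain sum over L positions and a truncated
  one is rescaled to the same magnitude rather than looking artificially
  similar.
* The self-weight $w(i,i)$ is included as computed (distance 0, maximal
  unnormalized weight 1), with no special-casing.
* The per-bin p-value uses a strict comparison (null strictly above
  observed), while the FDR numerator and denominator both use non-strict
  `<=` against the cutoff; this makes both counts monotone in
  $p_\mathrm{cut}$ and makes FDR exactly 1 at $p_\mathrm{cut} = 1$.
* Null read placement is uniform-multinomial: the per-round total exactly
  matches the observed read count and per-bin counts are approximately
  Poisson. An independent-Poisson mode (`placement = "poisson"`, per-bin
  mean proportional to bin width) is available; it preserves the total
  only in expectation.
* The height-threshold quantile uses the inverse empirical CDF with
  averaging at discontinuities (`stats::quantile`, type 2), so
  $p_\mathrm{cut} = 0$ maps to the pooled-null maximum.
* Super-threshold comparison in region calling is `>=` (ties included).
* Each chromosome gets its own ensemble, p-values and threshold, since
  read depth differs by chromosome; per-round child seeds are derived from
  the master seed and the chromosome name, so results are independent of
  chromosome processing order and reproducible from the run report alone.

## Filter defaults per regime

The two presets mirror the two ways the method is used. The fine regime
(25 bp bins) is for comparing against narrow-peak callers; there the
peak-to-threshold ratio (default 6.5) is the operative filter and no
length filter is applied. The broad regime (1 kb bins) targets multi-kb
domains; there the length filter (>= 4 kb, i.e. four bins) is operative
and the ratio filter is off (1), since long moderate domains — exactly the
signal of interest — need not tower over the threshold.

## What the synthetic generator emulates

`generate_reads()` draws reads from an inhomogeneous Poisson process:
uniform background at `background_rate` reads/bp, multiplied by `fold`
inside planted segments. The standard recovery fixture
(`synthetic_fixture_config()`) places 10 segments of 5–50 kb (snapped to
bin edges) evenly along a 10 Mb chromosome at fold 8 over a 0.02 reads/bp
background — roughly 200k background reads, i.e. 20 reads per 1 kb bin,
a realistic depth for a broad-mark library scaled to one chromosome.

The generator deliberately omits several features of real data: no
fragment-length strand shift (reads are positions, not sequences), no
mappability gaps or GC bias, no copy-number variation, and background that
is globally homogeneous rather than locally autocorrelated. Passing the
recovery tests therefore demonstrates that the statistical machinery is
implemented correctly and controls errors under its own model; it does not
by itself certify performance on real libraries, where background
heterogeneity is the main additional difficulty.

## Numerical and testing choices

Problem sizes in the test-suite were chosen to exercise the study
conditions at desk scale: recovery runs use the 10 Mb fixture across 10
seeds and specificity runs use 20 pure-noise seeds, with B = 20; p-value
calibration uses a 2 Mb null-drawn track at B = 50, where the
Kolmogorov–Smirnov distance of the per-bin p-values from uniform stays
below 0.1. The optimized O(MRL) denoiser is checked elementwise (1e-12)
against a naive double-loop reference on random signals, and the explicit
weight matrix is checked to be row-stochastic and to reproduce the
optimized output.

## Known limitations

* Parameters are fixed per run; domains much shorter or longer than the
  scale implied by (R, L, `bin_size`) are better served by re-running at a
  different bin size (a multiscale extension is the natural next step).
* The null is simulation-only; input-control tracks are not used, so
  systematic background (open chromatin, CNVs) can inflate calls on real
  data.
* With small B the threshold quantizes to the pooled-null maximum (see
  above), which is conservative.
* Region boundaries snap to bin edges; sub-bin resolution is out of
  scope.

## A minimal run

```{r example}
cfg <- synthetic_config(5e5, background_rate = 0.05,
                        data.frame(start = 2e5, end = 2.4e5, fold = 8),
                        bin_size = 1000, seed = 3)
gen <- generate_reads(cfg)
res <- detect_regions(gen$reads, c(chrSim = 5e5), bin_size = 1000,
                      B = 10, target_fdr = 0.01, min_length = 4000,
                      seed = 3)
res$regions
evaluate_recovery(res$regions, gen$truth)
```
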