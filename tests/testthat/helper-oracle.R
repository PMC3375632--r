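# Independent naive non-local-means reference: explicit double loop over
# positions and patch offsets, written directly from the weight formula.
# Deliberately shares no code with the package implementation.
naive_nlmeans <- function(x, R, L, sigma) {
  if (L %% 2 == 0) L <- L + 1
  h <- (L - 1) / 2
  m <- length(x)
  out <- numeric(m)
  for (i in seq_len(m)) {
    js <- max(1, i - R):min(m, i + R)
    w <- numeric(length(js))
    for (k in seq_along(js)) {
      j <- js[k]
      ss <- 0
      cnt <- 0
      for (t in -h:h) {
        if (i + t >= 1 && i + t <= m && j + t >= 1 && j + t <= m) {
          ss <- ss + (x[i + t] - x[j + t])^2
          cnt <- cnt + 1
        }
      }
      w[k] <- exp(-(L * ss / cnt) / (2 * sigma^2))
    }
    out[i] <- sum(w * x[js]) / sum(w)
  }
  out
}
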