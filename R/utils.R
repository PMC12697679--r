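# Internal helpers shared across modules.

# Deterministically derive a 32-bit seed from a master seed and a string key
# (e.g. a tree-node path).  Used so per-node randomness is reproducible
# independent of traversal order.
derive_seed <- function(master, key) {
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + as.numeric(master)) %% 2147483647)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Equal-frequency partition of a pooled sample.  Values are sorted and cut
# into `n_bins` contiguous chunks whose sizes differ by at most one; interior
# edges are midpoints between the order statistics flanking each cut, outer
# edges are -Inf/+Inf sentinels.  `positive` flags the draws whose per-bin
# proportion becomes the bin value, so sum(count * fraction) equals the
# overall positive count exactly.
eqfreq_histogram <- function(x, positive, n_bins) {
  n <- length(x)
  if (n_bins > n) {
    stop("n_bins (", n_bins, ") exceeds the number of samples (", n, ")")
  }
  ord <- order(x)
  xs <- x[ord]
  ps <- positive[ord]
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_bins] + 1L)
  mids <- (xs[ends[-n_bins]] + xs[ends[-n_bins] + 1L]) / 2
  frac <- vapply(seq_len(n_bins),
                 function(b) mean(ps[starts[b]:ends[b]]), numeric(1))
  structure(list(edges = c(-Inf, mids, Inf),
                 bin_fraction = frac,
                 bin_count = sizes,
                 n_synthetic = n),
            class = "calibration_histogram")
}

#' @export
print.calibration_histogram <- function(x, ...) {
  cat("Equal-frequency calibration histogram:",
      length(x$bin_fraction), "bins over", x$n_synthetic, "samples\n")
  cat("  bin fractions:", format(range(x$bin_fraction), digits = 3),
      "(min, max)\n")
  invisible(x)
}

# Locate scores in a calibration histogram: half-open bins [lo, hi); the
# -Inf/+Inf sentinel edges clamp out-of-range scores into the first/last bin.
histogram_lookup <- function(hist, scores) {
  idx <- findInterval(scores, hist$edges, left.open = FALSE)
  idx[idx < 1L] <- 1L
  nb <- length(hist$bin_fraction)
  idx[idx > nb] <- nb
  hist$bin_fraction[idx]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
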