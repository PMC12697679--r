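# Score-level operators: log-likelihood ratios from logits, sliding-window
# bookkeeping for long proteins, normalized entropy, robust outlier removal
# and min-max normalization/orientation.

#' Log-likelihood ratio from a logit vector
#'
#' Computes a variant LLR from a model's per-position logit vector.  In
#' \code{eq2} mode the wild-type entry is subtracted from the whole vector, a
#' log-softmax is applied, and the mutant entry of the normalized vector is
#' returned.  In \code{naive_diff} mode the raw logit difference
#' \code{values[mut] - values[wt]} is returned.  Because the log-softmax is
#' shift invariant, \code{eq2} equals the mutant entry of the log-softmax of
#' the unshifted logits; the two modes generally differ, but
#' log-softmax-then-subtract collapses to \code{naive_diff} exactly.
#'
#' @param values numeric logit vector (one entry per amino-acid token).
#' @param wt_index,mut_index 1-based indices of the wild-type and mutant
#'   tokens.
#' @param mode \code{"eq2"} (default) or \code{"naive_diff"}.
#' @return a single numeric LLR.
#' @export
llr_from_logits <- function(values, wt_index, mut_index, mode = c("eq2", "naive_diff")) {
  mode <- match.arg(mode)
  if (length(values) < 2) stop("logit vector needs at least two entries")
  if (!all(is.finite(values))) stop("non-finite logits")
  if (wt_index == mut_index) stop("wt_index and mut_index must differ")
  stopifnot(wt_index >= 1, mut_index >= 1,
            wt_index <= length(values), mut_index <= length(values))
  if (mode == "naive_diff") {
    return(values[mut_index] - values[wt_index])
  }
  shifted <- values - values[wt_index]
  shifted[mut_index] - logsumexp(shifted)
}

#' Sliding-window plan for scoring long sequences
#'
#' Models with a bounded input context score long proteins through
#' overlapping windows.  Each window of \code{window} residues scores its
#' central \code{window - 2*overlap} positions; the first and last windows
#' additionally score their terminal \code{overlap} regions so the scored
#' ranges are pairwise disjoint and tile the whole sequence.
#'
#' @param seq_len sequence length (>= 1).
#' @param window window size in residues (default 1022).
#' @param overlap overlap between consecutive windows (default 250);
#'   must satisfy \code{window > 2*overlap}.
#' @return a data frame with 0-based half-open columns \code{window_start},
#'   \code{window_end}, \code{scored_start}, \code{scored_end}.
#' @export
plan_windows <- function(seq_len, window = 1022, overlap = 250) {
  if (window <= 2 * overlap) stop("window must exceed 2*overlap")
  if (seq_len < 1) stop("seq_len must be >= 1")
  if (seq_len <= window) {
    return(data.frame(window_start = 0L, window_end = as.integer(seq_len),
                      scored_start = 0L, scored_end = as.integer(seq_len)))
  }
  core <- window - 2L * overlap
  rows <- list()
  scored_from <- 0L
  k <- 0L
  repeat {
    ws <- k * core
    if (ws + window >= seq_len) {
      ws <- seq_len - window
      rows[[length(rows) + 1L]] <- c(ws, seq_len, scored_from, seq_len)
      break
    }
    se <- ws + window - overlap
    rows[[length(rows) + 1L]] <- c(ws, ws + window, scored_from, se)
    scored_from <- se
    k <- k + 1L
  }
  m <- do.call(rbind, rows)
  data.frame(window_start = as.integer(m[, 1]), window_end = as.integer(m[, 2]),
             scored_start = as.integer(m[, 3]), scored_end = as.integer(m[, 4]))
}

#' Normalized entropy of a probability vector
#'
#' Returns \code{1 - H(p)/log(N)} (with \code{0*log(0) := 0}), so 1 means a
#' one-hot (fully confident) prediction and 0 a uniform one.  Set
#' \code{complement = TRUE} for the flipped quantity \code{H(p)/log(N)}
#' (1 = complete uncertainty).
#'
#' @param p non-negative probability vector of length >= 2, summing to ~1.
#' @param complement return \code{H/log N} instead of \code{1 - H/log N}.
#' @return numeric in [0, 1].
#' @export
normalized_entropy <- function(p, complement = FALSE) {
  if (length(p) < 2) stop("probability vector needs at least two entries")
  if (any(p < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  nz <- p[p > 0]
  h <- -sum(nz * log(nz)) / log(length(p))
  if (complement) h else 1 - h
}

#' Robust outlier mask via the modified z-score
#'
#' Flags extreme outliers using \code{z_i = 0.6745 * |x_i - median| / MAD};
#' values with \code{z_i > threshold} (strict) are marked for removal.  The
#' filter is applied to the pooled dataset without class separation.  When
#' the MAD is zero the z-score is undefined and nothing is removed (with a
#' warning).
#'
#' @param values numeric vector.
#' @param threshold modified z-score cutoff (default 4.25).
#' @return logical keep-mask of the same length (TRUE = keep).
#' @export
modified_zscore_filter <- function(values, threshold = 4.25) {
  if (length(values) < 1) stop("no values")
  med <- stats::median(values)
  mad0 <- stats::median(abs(values - med))
  if (mad0 == 0) {
    warning("MAD is zero; modified z-scores undefined, nothing removed")
    return(rep(TRUE, length(values)))
  }
  z <- 0.6745 * abs(values - med) / mad0
  z <= threshold
}

#' Percentile tail outlier mask
#'
#' Removes values strictly above the \code{1 - tail_frac} quantile or
#' strictly below the \code{tail_frac} quantile (linear-interpolation
#' empirical quantiles).
#'
#' @param values numeric vector of length >= 10.
#' @param tail_frac tail mass per side, in (0, 0.5); default 0.001
#'   (the most extreme 0.2\% of values in total).
#' @return logical keep-mask (TRUE = keep).
#' @export
percentile_filter <- function(values, tail_frac = 0.001) {
  if (tail_frac <= 0 || tail_frac >= 0.5) stop("tail_frac must be in (0, 0.5)")
  if (length(values) < 10) stop("need at least 10 values")
  q <- stats::quantile(values, c(tail_frac, 1 - tail_frac), names = FALSE,
                       type = 7)
  values >= q[1] & values <= q[2]
}

#' Modified min-max normalization with pathogenic-high orientation
#'
#' Maps raw predictor scores to [0, 1] on a common orientation.  Scores
#' already bounded in [0, 1] are not rescaled, only flipped
#' (\code{s -> 1 - s}) when the pathogenic mean is below the benign mean.
#' Otherwise the 0.1-percentile tails are set aside, the inliers are min-max
#' normalized, orientation is fixed by flipping if needed, and the reinstated
#' outliers are clamped to 1 on the above-range tail and 0 on the below-range
#' tail after orientation.  The transform is monotone up to the deliberate
#' flip, so AUROC is preserved.
#'
#' @param scores numeric vector of raw scores.
#' @param labels binary labels (1 pathogenic, 0 benign); both classes
#'   required to determine orientation.
#' @param tail_frac tail mass per side for outlier removal (default 0.001).
#' @return numeric vector of oriented scores in [0, 1].
#' @export
minmax_normalize_orient <- function(scores, labels, tail_frac = 0.001) {
  labels <- as.integer(labels)
  if (length(unique(labels[!is.na(labels)])) < 2) {
    stop("both classes required to orient scores")
  }
  flip_needed <- function(s) {
    mean(s[labels == 1L], na.rm = TRUE) < mean(s[labels == 0L], na.rm = TRUE)
  }
  if (all(scores >= 0 & scores <= 1)) {
    return(if (flip_needed(scores)) 1 - scores else scores)
  }
  keep <- percentile_filter(scores, tail_frac)
  lo <- min(scores[keep])
  hi <- max(scores[keep])
  if (hi == lo) stop("degenerate score range after outlier removal")
  s <- (scores - lo) / (hi - lo)
  if (flip_needed(s)) s <- 1 - s
  pmin(pmax(s, 0), 1)
}
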