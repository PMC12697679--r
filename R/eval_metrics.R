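# Discrimination and calibration metrics: AUROC (global and per-protein),
# Youden thresholds, reliability histograms with expected and maximal
# calibration error, and bootstrap machinery.

#' Rank-based AUROC
#'
#' Area under the ROC curve with midrank tie handling; higher scores are
#' assumed to indicate pathogenicity (the caller orients).
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 pathogenic, 0 benign).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  n1 <- as.numeric(sum(labels == 1L)); n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0 || n0 == 0) stop("AUROC undefined with a single class")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean per-protein AUROC
#'
#' AUROC computed independently within each qualifying protein and averaged.
#' Proteins lacking either class, or with fewer than \code{min_variants}
#' labeled variants, are excluded.
#'
#' @param table labeled \code{variant_table}.
#' @param score_col column holding the score to rank by (default
#'   \code{"score"}).
#' @param min_variants minimum labeled variants per protein (default 1).
#' @param min_pos,min_neg minimum variants per class per protein (default 1).
#' @param weighted weight each protein by its variant count instead of the
#'   unweighted mean (default FALSE).
#' @return mean per-protein AUROC.
#' @export
per_protein_auroc <- function(table, score_col = "score", min_variants = 1,
                              min_pos = 1, min_neg = 1, weighted = FALSE) {
  ok <- !is.na(table$label) & !is.na(table[[score_col]])
  tab <- table[ok, , drop = FALSE]
  per <- lapply(split(seq_len(nrow(tab)), tab$protein_id), function(rows) {
    lab <- tab$label[rows]
    if (length(rows) < min_variants || sum(lab == 1L) < min_pos ||
        sum(lab == 0L) < min_neg) {
      return(NULL)
    }
    c(auc = auroc(tab[[score_col]][rows], lab), n = length(rows))
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0) stop("no qualifying protein")
  m <- do.call(rbind, per)
  if (weighted) {
    sum(m[, "auc"] * m[, "n"]) / sum(m[, "n"])
  } else {
    mean(m[, "auc"])
  }
}

# J = TPR - FPR over all cuts (classify pathogenic when score >= threshold).
# Candidates are midpoints between consecutive distinct scores plus -Inf and
# +Inf; smallest qualifying threshold on ties.
youden_scan <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  ord <- order(scores)
  s <- scores[ord]; l <- labels[ord]
  last <- cumsum(rle(s)$lengths)  # last index of each distinct value
  u <- s[last]
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  cum_pos <- c(0, cumsum(l == 1L)[last])
  cum_neg <- c(0, cumsum(l == 0L)[last])
  # candidate i sits above the first (i-1) distinct values
  tpr <- (n1 - cum_pos) / n1
  fpr <- (n0 - cum_neg) / n0
  j <- tpr - fpr
  best <- which.max(j)  # ties: smallest threshold (which.max takes first)
  list(threshold = cand[best], J = j[best])
}

#' Youden J-statistic threshold
#'
#' Scans every candidate cut (midpoints between consecutive distinct sorted
#' scores plus the infinite cuts) for the threshold maximizing
#' TPR - FPR, classifying pathogenic when score >= threshold.  The threshold
#' standard deviation is estimated over non-parametric bootstrap resamples.
#'
#' @param scores numeric scores (higher = pathogenic).
#' @param labels binary labels.
#' @param bootstrap bootstrap iterations for the threshold sd (default
#'   1000; 0 skips the bootstrap).
#' @param seed RNG seed.
#' @return list with \code{threshold}, \code{sd} and \code{J}.
#' @export
youden_threshold <- function(scores, labels, bootstrap = 1000, seed = 1) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  if (length(unique(labels)) < 2) stop("both classes required")
  point <- youden_scan(scores, labels)
  sd_thr <- NA_real_
  if (bootstrap > 0) {
    set.seed(seed)
    n <- length(scores)
    thr <- vapply(seq_len(bootstrap), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) {
          return(youden_scan(scores[idx], labels[idx])$threshold)
        }
      }
    }, numeric(1))
    thr <- thr[is.finite(thr)]
    sd_thr <- stats::sd(thr)
  }
  list(threshold = point$threshold, sd = sd_thr, J = point$J)
}

#' Reliability histogram with expected and maximal calibration error
#'
#' Discretizes predicted probabilities into \code{n_bins} equal-width bins on
#' [0, 1] (half-open, final bin closed at 1) and compares per-bin mean
#' confidence with the empirical pathogenic frequency.  ECE is the
#' count-weighted mean absolute gap; MCE is the maximal gap over bins with
#' more than \code{mce_min_count} samples (NA when no bin qualifies).
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels binary labels.
#' @param n_bins equal-width bins (default 10).
#' @param mce_min_count bin-count floor for the MCE (default 50, strict >).
#' @return object of class \code{reliability_report}: list with the per-bin
#'   table (\code{bins}) and scalars \code{ece}, \code{mce}.
#' @export
reliability_histogram <- function(probs, labels, n_bins = 10,
                                  mce_min_count = 50) {
  ok <- !is.na(probs) & !is.na(labels)
  probs <- probs[ok]; labels <- as.integer(labels[ok])
  if (any(probs < 0 | probs > 1)) stop("probabilities outside [0, 1]")
  idx <- pmin(floor(probs * n_bins) + 1L, n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1)
  count <- tabulate(idx, nbins = n_bins)
  conf <- vapply(seq_len(n_bins), function(b) {
    if (count[b] > 0) mean(probs[idx == b]) else NA_real_
  }, numeric(1))
  freq <- vapply(seq_len(n_bins), function(b) {
    if (count[b] > 0) mean(labels[idx == b]) else NA_real_
  }, numeric(1))
  gap <- abs(conf - freq)
  ece <- sum(count * ifelse(is.na(gap), 0, gap)) / sum(count)
  qual <- count > mce_min_count
  mce <- if (any(qual)) max(gap[qual]) else NA_real_
  structure(list(bins = data.frame(bin_lo = edges[-(n_bins + 1)],
                                   bin_hi = edges[-1],
                                   count = count,
                                   mean_confidence = conf,
                                   pathogenic_frequency = freq),
                 ece = ece, mce = mce, n = sum(count)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Reliability report over", x$n, "predictions:\n")
  cat(sprintf("  ECE = %.4f   MCE = %s\n", x$ece,
              if (is.na(x$mce)) "undefined" else sprintf("%.4f", x$mce)))
  print(x$bins)
  invisible(x)
}

#' Expected calibration error
#' @inheritParams reliability_histogram
#' @return ECE in [0, 1].
#' @export
ece <- function(probs, labels, n_bins = 10) {
  reliability_histogram(probs, labels, n_bins = n_bins)$ece
}

#' Bootstrap evaluation of a table-level metric
#'
#' Resamples variant records with replacement, recomputes the metric on each
#' resample, and reports the mean and standard deviation.  A resample on
#' which the metric fails (e.g. a single class) is redrawn, up to a retry
#' cap.
#'
#' @param metric_fn function taking a resampled table and returning a
#'   numeric scalar.
#' @param table a \code{variant_table} (any data frame of records).
#' @param iters bootstrap iterations.
#' @param seed RNG seed.
#' @param max_retries redraw cap per iteration (default 10).
#' @return list with \code{mean}, \code{sd} and the vector \code{values}.
#' @export
bootstrap_eval <- function(metric_fn, table, iters = 100, seed = 1,
                           max_retries = 10) {
  if (iters < 1) stop("iters must be >= 1")
  set.seed(seed)
  n <- nrow(table)
  values <- vapply(seq_len(iters), function(i) {
    for (try in seq_len(max_retries)) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric_fn(table[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (!is.null(v)) return(v)
    }
    stop("metric failed on ", max_retries, " consecutive resamples")
  }, numeric(1))
  list(mean = mean(values), sd = stats::sd(values), values = values)
}
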