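# Label-shift and class-conditional feature-distribution-shift analysis:
# conditional Jensen-Shannon divergence, label shift, mutual information at
# residue vs protein level, Fisher/BH significance, bin-stability checks.

#' Class-conditional Jensen-Shannon divergence between attribute subgroups
#'
#' For a binary residue attribute M, quantifies how much the feature
#' distribution differs between the M and not-M subgroups at fixed label:
#' for each label l the feature is discretized into \code{bins} equal-width
#' histograms on [0, 1], a smoothing factor \code{eps} is added to every bin,
#' the histograms are renormalized, and the squared Jensen-Shannon distance
#' (natural log) between P(X|M,l) and P(X|not-M,l) is computed.  The returned
#' divergence is the sum over the two labels, bounded by 2*log(2).
#'
#' Features not already bounded in [0, 1] (e.g. raw LLRs) are min-max mapped
#' before histogramming.
#'
#' @param feature numeric feature vector (entropy, score, ...).
#' @param mask logical attribute indicator (TRUE = subgroup M).
#' @param labels binary labels (1 pathogenic, 0 benign).
#' @param bins number of equal-width bins (default 100).
#' @param eps smoothing mass added to every bin (default exp(-12)).
#' @return non-negative numeric divergence.
#' @export
conditional_jsd <- function(feature, mask, labels, bins = 100,
                            eps = exp(-12)) {
  ok <- !is.na(feature) & !is.na(mask) & !is.na(labels)
  feature <- feature[ok]; mask <- as.logical(mask[ok]); labels <- as.integer(labels[ok])
  rng <- range(feature)
  if (rng[1] < 0 || rng[2] > 1) {
    if (rng[2] == rng[1]) {
      feature <- rep(0.5, length(feature))
    } else {
      feature <- (feature - rng[1]) / (rng[2] - rng[1])
    }
  }
  total <- 0
  for (l in c(0L, 1L)) {
    for (m in c(TRUE, FALSE)) {
      if (!any(mask == m & labels == l)) {
        stop("empty subgroup-label cell: mask=", m, ", label=", l)
      }
    }
    p <- smoothed_hist(feature[mask & labels == l], bins, eps)
    q <- smoothed_hist(feature[!mask & labels == l], bins, eps)
    total <- total + jsd_squared(p, q)
  }
  total
}

smoothed_hist <- function(x, bins, eps) {
  idx <- pmin(floor(x * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins) + eps
  counts / sum(counts)
}

# Squared Jensen-Shannon distance between two probability vectors, natural
# log; equals the JS divergence 0.5*KL(p||m) + 0.5*KL(q||m).
jsd_squared <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Label (prior) shift of a variant subgroup
#'
#' Absolute difference between the pooled pathogenic ratio and the ratio
#' observed within the subgroup selected by \code{mask}.
#'
#' @param labels binary labels.
#' @param mask logical subgroup indicator.
#' @return numeric in [0, 1].
#' @export
label_shift <- function(labels, mask) {
  ok <- !is.na(labels) & !is.na(mask)
  labels <- as.integer(labels[ok]); mask <- as.logical(mask[ok])
  if (!any(mask)) stop("empty subgroup")
  abs(mean(labels) - mean(labels[mask]))
}

#' Mutual information between a grouping and the pathogenic label
#'
#' Plug-in (maximum-likelihood) mutual information in nats between a
#' categorical group assignment and the binary label, with uncertainty from
#' non-parametric bootstrap resampling of rows.
#'
#' @param labels binary labels.
#' @param groups categorical group assignment (same length).
#' @param bootstrap number of bootstrap iterations (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{mi} (point estimate), \code{mean} and \code{sd}
#'   over bootstrap replicates.
#' @export
mutual_information <- function(labels, groups, bootstrap = 1000, seed = 1) {
  ok <- !is.na(labels) & !is.na(groups)
  labels <- as.integer(labels[ok])
  groups <- as.integer(factor(groups[ok]))
  if (length(unique(groups)) < 2) stop("need at least two groups")
  point <- plugin_mi(labels, groups)
  set.seed(seed)
  n <- length(labels)
  reps <- vapply(seq_len(bootstrap), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    plugin_mi(labels[idx], groups[idx])
  }, numeric(1))
  list(mi = point, mean = mean(reps), sd = stats::sd(reps))
}

plugin_mi <- function(labels, groups) {
  tab <- table(groups, labels)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy)
  py <- colSums(pxy)
  expected <- outer(px, py)
  sum(ifelse(pxy > 0, pxy * log(pxy / expected), 0))
}

#' Protein-level attribute enrichment groups
#'
#' Assigns each protein (and therefore each of its variant records) to one of
#' \code{n_bins} groups by the fraction of its variants carrying the
#' attribute, using equal-width cut points over the observed fraction range.
#' The grouping is constant within a protein.
#'
#' @param table a \code{variant_table}.
#' @param attribute attribute column name.
#' @param n_bins number of enrichment groups (default 3).
#' @return integer group per record (1..n_bins).
#' @export
protein_level_groups <- function(table, attribute, n_bins = 3) {
  a <- table[[attribute]]
  frac <- tapply(a, table$protein_id, function(v) mean(v, na.rm = TRUE))
  frac[is.nan(frac)] <- 0
  rng <- range(frac)
  if (rng[2] == rng[1]) {
    grp <- stats::setNames(rep(1L, length(frac)), names(frac))
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    grp <- stats::setNames(
      pmin(findInterval(frac, edges, rightmost.closed = TRUE), n_bins),
      names(frac))
  }
  as.integer(grp[table$protein_id])
}

#' Fisher exact tests with Benjamini-Hochberg correction
#'
#' Two-sided Fisher's exact test per 2x2 table, with step-up BH adjustment
#' across the whole list.
#'
#' @param tables list of 2x2 integer matrices (non-negative counts).
#' @return data frame with columns \code{odds_ratio}, \code{p},
#'   \code{p_adj}, one row per input table.
#' @export
fisher_bh <- function(tables) {
  res <- lapply(tables, function(tab) {
    tab <- as.matrix(tab)
    if (!all(tab >= 0) || any(tab != round(tab))) {
      stop("counts must be non-negative integers")
    }
    if (sum(tab) == 0) stop("all-zero contingency table")
    ft <- stats::fisher.test(tab)
    c(odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  m <- do.call(rbind, res)
  data.frame(odds_ratio = m[, "odds_ratio"], p = m[, "p"],
             p_adj = stats::p.adjust(m[, "p"], method = "BH"))
}

#' Rank stability of divergences across histogram bin sizes
#'
#' Kendall's tau between attribute divergence rankings computed at different
#' bin resolutions; high tau indicates the attribute ordering is robust to
#' the binning choice.
#'
#' @param divergences_by_binsize named list: bin size -> named numeric vector
#'   of per-attribute divergences (identical attribute sets).
#' @return symmetric matrix of pairwise Kendall's tau.
#' @export
kendall_tau_stability <- function(divergences_by_binsize) {
  if (length(divergences_by_binsize) < 2) stop("need at least two bin sizes")
  attrs <- sort(names(divergences_by_binsize[[1]]))
  for (v in divergences_by_binsize) {
    if (!identical(sort(names(v)), attrs)) {
      stop("attribute sets differ across bin sizes")
    }
  }
  k <- length(divergences_by_binsize)
  out <- matrix(1, k, k,
                dimnames = list(names(divergences_by_binsize),
                                names(divergences_by_binsize)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      tau <- stats::cor(divergences_by_binsize[[i]][attrs],
                        divergences_by_binsize[[j]][attrs],
                        method = "kendall")
      out[i, j] <- out[j, i] <- tau
    }
  }
  out
}

#' Shift scan across residue attributes
#'
#' For each attribute: subgroup sizes, label shift, class-conditional JSD of
#' the score distribution, Fisher odds ratio and BH-adjusted p-value for the
#' label-attribute association.
#'
#' @param table a labeled, scored \code{variant_table}.
#' @param attributes attribute names (default: all declared attributes).
#' @param bins histogram bins for the divergence (default 100).
#' @return data frame, one row per attribute, with columns \code{attribute},
#'   \code{n_M}, \code{n_notM}, \code{label_shift}, \code{divergence},
#'   \code{odds_ratio}, \code{p}, \code{p_adj}.
#' @export
shift_scan <- function(table, attributes = attribute_names(table),
                       bins = 100) {
  rows <- lapply(attributes, function(a) {
    mask <- table[[a]]
    ok <- !is.na(mask) & !is.na(table$label)
    mask_ok <- mask[ok]; lab <- table$label[ok]; sc <- table$score[ok]
    # attributes never observed on both sides (e.g. fully missing) are
    # reported with NA statistics rather than aborting the scan
    if (!any(mask_ok) || all(mask_ok)) {
      return(data.frame(attribute = a, n_M = sum(mask_ok),
                        n_notM = sum(!mask_ok), label_shift = NA_real_,
                        divergence = NA_real_, odds_ratio = NA_real_,
                        p = NA_real_))
    }
    div <- tryCatch(conditional_jsd(sc, mask_ok, lab, bins = bins),
                    error = function(e) NA_real_)
    tab <- matrix(c(sum(mask_ok & lab == 1L), sum(mask_ok & lab == 0L),
                    sum(!mask_ok & lab == 1L), sum(!mask_ok & lab == 0L)),
                  nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    data.frame(attribute = a, n_M = sum(mask_ok), n_notM = sum(!mask_ok),
               label_shift = label_shift(lab, mask_ok), divergence = div,
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
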