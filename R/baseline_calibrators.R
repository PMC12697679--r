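# Comparison calibrators: balanced logistic rescaling (global and
# per-subgroup), direct equal-frequency histogram binning of raw scores, and
# the hybrid synthetic-plus-raw binning variant.

#' Logistic rescaling parameters
#' @param c1 scale coefficient.
#' @param c2 intercept.
#' @return object of class \code{logistic_params}.
#' @export
logistic_params <- function(c1, c2) {
  if (!is.finite(c1) || !is.finite(c2)) stop("coefficients must be finite")
  structure(list(c1 = c1, c2 = c2), class = "logistic_params")
}

#' Fit a balanced logistic rescaling of raw scores
#'
#' Removes 0.1-percentile tail outliers, draws a balanced subsample
#' (\code{n_per_class} per class, without replacement, majority class
#' down-sampled), and fits an unpenalized maximum-likelihood logistic
#' regression of the label on the score.  The calibrated score is
#' \code{sigmoid(c1 * x + c2)}.
#'
#' @param scores numeric raw scores.
#' @param labels binary labels.
#' @param n_per_class balanced sample size per class; default: the smaller
#'   class size after outlier removal.
#' @param seed RNG seed for the balanced sampling.
#' @param tail_frac percentile tail per side removed first (default 0.001).
#' @return a \code{logistic_params} object.
#' @export
logistic_calibrate <- function(scores, labels, n_per_class = NULL, seed = 1,
                               tail_frac = 0.001) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  keep <- percentile_filter(scores, tail_frac)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  if (is.null(n_per_class)) n_per_class <- min(n1, n0)
  if (n_per_class > min(n1, n0)) {
    stop("fewer than n_per_class samples in one class after outlier removal")
  }
  set.seed(seed)
  idx <- c(sample(which(labels == 1L), n_per_class),
           sample(which(labels == 0L), n_per_class))
  fit <- stats::glm(labels[idx] ~ scores[idx], family = stats::binomial())
  logistic_params(c1 = unname(stats::coef(fit)[2]),
                  c2 = unname(stats::coef(fit)[1]))
}

#' Apply a logistic rescaling
#' @param params a \code{logistic_params} object.
#' @param x raw scores.
#' @return calibrated scores in (0, 1).
#' @export
apply_logistic <- function(params, x) {
  stats::plogis(params$c1 * x + params$c2)
}

# Subgroup assignment for the three calibration schemes; NA means "no
# subgroup" (global fallback at apply time).
subgroup_assign <- function(table, scheme) {
  switch(scheme,
         ppi_split = ifelse(is.na(table$ppi), NA_character_,
                            ifelse(table$ppi, "ppi", "non_ppi")),
         fold_split = ifelse(is.na(table$disordered), NA_character_,
                             ifelse(table$disordered, "disordered", "ordered")),
         joint = {
           d <- table$disordered
           p <- table$ppi
           out <- rep(NA_character_, nrow(table))
           out[!is.na(d) & d] <- "disordered"
           ord <- !is.na(d) & !d
           out[ord & !is.na(p) & p] <- "ordered_ppi"
           out[ord & !is.na(p) & !p] <- "ordered_non_ppi"
           out
         },
         stop("unknown scheme: ", scheme))
}

#' Per-subgroup balanced logistic calibration
#'
#' Fits an independent logistic rescaling per residue subgroup under one of
#' three schemes: \code{ppi_split} (interface vs non-interface),
#' \code{fold_split} (disordered vs ordered), or \code{joint} (disordered,
#' plus ordered residues further split by interface status; disordered
#' residues are not subdivided).  A subgroup without \code{n_per_class}
#' samples in each class falls back to the global fit with a warning, as do
#' variants with missing subgroup annotations at apply time.
#'
#' @param table labeled, scored \code{variant_table} with the scheme's
#'   attribute columns.
#' @param scheme one of \code{"ppi_split"}, \code{"fold_split"},
#'   \code{"joint"}.
#' @param n_per_class balanced sample size per class per subgroup.
#' @param seed RNG seed.
#' @return object of class \code{subgroup_logistic}.
#' @export
subgroup_logistic_calibrate <- function(table,
                                        scheme = c("fold_split", "ppi_split", "joint"),
                                        n_per_class = 500, seed = 1) {
  scheme <- match.arg(scheme)
  global <- logistic_calibrate(table$score, table$label,
                               n_per_class = n_per_class, seed = seed)
  groups <- subgroup_assign(table, scheme)
  fits <- list()
  for (g in sort(unique(groups[!is.na(groups)]))) {
    sel <- which(groups == g & !is.na(table$label))
    fit <- tryCatch(
      logistic_calibrate(table$score[sel], table$label[sel],
                         n_per_class = n_per_class,
                         seed = derive_seed(seed, g)),
      error = function(e) {
        warning("subgroup '", g, "' too small for a balanced fit (",
                conditionMessage(e), "); falling back to the global fit")
        global
      })
    fits[[g]] <- fit
  }
  structure(list(scheme = scheme, global = global, subgroups = fits),
            class = "subgroup_logistic")
}

#' Apply a per-subgroup logistic calibration to a variant table
#'
#' @param object a \code{subgroup_logistic} fit.
#' @param newdata a \code{variant_table}.
#' @param ... unused.
#' @return data frame with columns \code{probability} and \code{subgroup}
#'   (\code{"global"} for fallback rows).
#' @export
predict.subgroup_logistic <- function(object, newdata, ...) {
  groups <- subgroup_assign(newdata, object$scheme)
  prob <- numeric(nrow(newdata))
  out_group <- ifelse(is.na(groups) | !(groups %in% names(object$subgroups)),
                      "global", groups)
  for (g in unique(out_group)) {
    rows <- which(out_group == g)
    params <- if (g == "global") object$global else object$subgroups[[g]]
    prob[rows] <- apply_logistic(params, newdata$score[rows])
  }
  data.frame(probability = prob, subgroup = out_group,
             stringsAsFactors = FALSE)
}

#' Direct equal-frequency binning calibration
#'
#' Partitions raw labeled scores into equal-frequency bins and assigns each
#' bin its empirical pathogenic fraction.  The baseline against which
#' mixture-based synthetic binning is compared.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param n_bins number of bins.
#' @return a \code{calibration_histogram}.
#' @export
direct_binning_calibrate <- function(scores, labels, n_bins) {
  ok <- !is.na(scores) & !is.na(labels)
  eqfreq_histogram(scores[ok], as.integer(labels[ok]) == 1L, n_bins)
}

#' Hybrid synthetic-plus-raw binning calibration
#'
#' Pools synthetic mixture draws (pathogenic membership known by source)
#' with raw labeled scores, and bins the pool equal-frequency; each bin's
#' fraction counts synthetic draws by source and raw scores by label.
#' Reduces to \code{\link{build_histogram}} output with zero raw scores and
#' to \code{\link{direct_binning_calibrate}} with zero synthetic draws.
#'
#' @param synthetic_scores synthetic draws.
#' @param synthetic_pathogenic logical: drawn from the pathogenic mixture.
#' @param raw_scores,raw_labels raw labeled scores.
#' @param n_bins number of bins.
#' @return a \code{calibration_histogram}.
#' @export
hybrid_binning_calibrate <- function(synthetic_scores, synthetic_pathogenic,
                                     raw_scores, raw_labels, n_bins) {
  if (length(synthetic_scores) + length(raw_scores) == 0) {
    stop("both sources empty")
  }
  x <- c(synthetic_scores, raw_scores)
  pos <- c(as.logical(synthetic_pathogenic), as.integer(raw_labels) == 1L)
  eqfreq_histogram(x, pos, n_bins)
}
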