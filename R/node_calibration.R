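# Per-node distribution modelling and score-to-probability mapping: the
# pathogenic-fraction estimate, the two class-conditional mixtures, the
# equal-frequency calibration histogram, model fitting, traversal-based
# prediction, and ensemble prediction.

#' Estimate a node's pathogenic fraction from a label subsample
#'
#' Mean of \code{n_p} labels sampled without replacement (all labels when the
#' node is smaller).  The sampled indices are returned so mixture fitting can
#' reuse the same variants and keep the total labeled footprint small.
#'
#' @param node_labels binary label vector of the node's members.
#' @param n_p subsample size (default 500, sized so a 95\% CI on a Bernoulli
#'   fraction has half-width below 0.05 with margin).
#' @param seed RNG seed.
#' @return list with \code{fraction} and the sampled \code{idx}.
#' @export
estimate_fraction <- function(node_labels, n_p = 500, seed = 1) {
  lab <- node_labels[!is.na(node_labels)]
  if (length(lab) < 1) stop("node has no labels")
  set.seed(seed)
  idx <- if (length(lab) <= n_p) seq_along(lab) else sample.int(length(lab), n_p)
  list(fraction = mean(lab[idx]), idx = idx)
}

#' Fit per-class Gaussian mixtures for a node
#'
#' Fits one K-component mixture each for the benign and pathogenic score
#' subsets, on \code{n_gmm} sampled scores per class.  Indices in
#' \code{reuse_idx} (typically the fraction-estimation sample) are used
#' first and topped up at random to \code{n_gmm} per class.
#'
#' @param node_scores,node_labels scores and binary labels of the node's
#'   members (pooled outlier removal is assumed already applied).
#' @param n_gmm training scores per class (default 400).
#' @param K components per mixture (default 2).
#' @param seed RNG seed.
#' @param reuse_idx indices (into the node's members) to reuse first.
#' @return list with \code{gmm_benign} and \code{gmm_pathogenic}.
#' @export
fit_node_gmms <- function(node_scores, node_labels, n_gmm = 400, K = 2,
                          seed = 1, reuse_idx = NULL) {
  out <- list()
  for (cls in c(0L, 1L)) {
    cls_idx <- which(node_labels == cls)
    if (length(cls_idx) < n_gmm) {
      stop("class ", cls, " has ", length(cls_idx),
           " scores, fewer than n_gmm = ", n_gmm)
    }
    set.seed(derive_seed(seed, paste0("gmm", cls)))
    take <- intersect(reuse_idx, cls_idx)
    if (length(take) < n_gmm) {
      pool <- setdiff(cls_idx, take)
      take <- c(take, sample(pool, n_gmm - length(take)))
    } else if (length(take) > n_gmm) {
      take <- take[seq_len(n_gmm)]
    }
    fit <- fit_gmm1d(node_scores[take], K = K,
                     seed = derive_seed(seed, paste0("em", cls)))
    out[[if (cls == 0L) "gmm_benign" else "gmm_pathogenic"]] <- fit
  }
  out
}

#' Build a node's calibration histogram from its fitted mixtures
#'
#' Draws \code{round(n_sample * fraction)} scores from the pathogenic mixture
#' and the remainder from the benign mixture, partitions the pooled draw into
#' \code{n_bins} equal-frequency bins (counts differing by at most one for
#' distinct values), and records per bin the proportion of pathogenic-sourced
#' draws.  Outer bin edges are -Inf/+Inf sentinels so any score maps to a
#' bin.
#'
#' @param gmm_benign,gmm_pathogenic fitted \code{gmm_params}.
#' @param fraction pathogenic fraction in [0, 1].
#' @param n_sample total synthetic draws (default 40000).
#' @param n_bins equal-frequency bins (default 50).
#' @param seed RNG seed.
#' @return a \code{calibration_histogram}.
#' @export
build_histogram <- function(gmm_benign, gmm_pathogenic, fraction,
                            n_sample = 40000, n_bins = 50, seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (n_bins > n_sample) stop("n_bins exceeds the synthetic sample size")
  set.seed(seed)
  n_path <- round(n_sample * fraction)
  draws <- c(rgmm(gmm_pathogenic, n_path), rgmm(gmm_benign, n_sample - n_path))
  src <- c(rep(TRUE, n_path), rep(FALSE, n_sample - n_path))
  eqfreq_histogram(draws, src, n_bins)
}

#' Fit a residue-aware calibration model
#'
#' The full fitting pipeline: pooled modified z-score outlier removal, greedy
#' tree construction, threshold pruning, then per surviving node a
#' pathogenic-fraction estimate, two class-conditional mixtures, and an
#' equal-frequency calibration histogram.  Every surviving node is
#' calibrated, so inference-time traversal always terminates at a node with
#' a histogram.  Deterministic given the configuration's master seed.
#'
#' @param table labeled, scored \code{variant_table}.
#' @param cfg a \code{\link{tree_config}}.
#' @return object of class \code{calib_model}.
#' @export
fit_racoon <- function(table, cfg = tree_config()) {
  if (!("label" %in% names(table)) || all(is.na(table$label))) {
    stop("table carries no labels")
  }
  table <- table[!is.na(table$label) & !is.na(table$score), , drop = FALSE]
  keep <- modified_zscore_filter(table$score, cfg$z_threshold)
  if (any(!keep)) {
    message(sum(!keep), " extreme score outliers removed (modified z-score > ",
            cfg$z_threshold, ")")
    table <- table[keep, , drop = FALSE]
  }
  rownames(table) <- NULL
  tree <- build_tree(table, cfg)
  tree <- prune_tree(tree, cfg)
  for (id in names(tree$nodes)) {
    node <- tree$nodes[[id]]
    node_seed <- derive_seed(cfg$seed, id)
    scores <- table$score[node$members]
    labels <- table$label[node$members]
    est <- estimate_fraction(labels, n_p = cfg$n_frac, seed = node_seed)
    gmms <- fit_node_gmms(scores, labels, n_gmm = cfg$n_gmm, K = cfg$K,
                          seed = node_seed, reuse_idx = est$idx)
    node$fraction <- est$fraction
    node$gmm_benign <- gmms$gmm_benign
    node$gmm_pathogenic <- gmms$gmm_pathogenic
    node$histogram <- build_histogram(gmms$gmm_benign, gmms$gmm_pathogenic,
                                      est$fraction, n_sample = cfg$n_sample,
                                      n_bins = cfg$n_bins,
                                      seed = derive_seed(cfg$seed,
                                                         paste0(id, "#hist")))
    tree$nodes[[id]] <- node
  }
  attrs <- c(cfg$root_attr, cfg$partition_attrs)
  structure(list(version = paste0("racoon ",
                                  as.character(utils::packageVersion("racoon"))),
                 config = cfg, tree = tree, attribute_names = attrs,
                 fitted_at = format(Sys.time(), tz = "UTC")),
            class = "calib_model")
}

#' @export
print.calib_model <- function(x, ...) {
  cat(x$version, "calibration model\n")
  cat("  nodes:", length(x$tree$nodes), " attributes:",
      paste(x$attribute_names, collapse = ", "), "\n")
  invisible(x)
}

#' Map one variant through a fitted model
#'
#' Traverses the calibration tree by the variant's tri-state attributes
#' (stopping at a leaf, at a pruned child, or when the next split's
#' attribute is missing), then locates the score in the stopping node's
#' histogram (half-open bins; sentinel edges clamp out-of-range scores).
#'
#' @param model a fitted \code{calib_model}.
#' @param attrs named logical vector or list of the variant's attributes
#'   (NA = missing annotation).
#' @param score the variant's raw score (LLR).
#' @return list with \code{probability} and the stopping \code{node} id.
#' @export
map_variant <- function(model, attrs, score) {
  id <- traverse_tree(model$tree, as.list(attrs))
  node <- model$tree$nodes[[id]]
  if (is.null(node$histogram)) stop("node ", id, " is not calibrated")
  list(probability = histogram_lookup(node$histogram, score), node = id)
}

#' Predict calibrated probabilities for a variant table
#'
#' @param object a fitted \code{calib_model}.
#' @param newdata a \code{variant_table} with the model's attribute columns.
#' @param ... unused.
#' @return data frame with columns \code{probability} and \code{node}, one
#'   row per variant.
#' @export
predict.calib_model <- function(object, newdata, ...) {
  attrs <- object$attribute_names
  present <- intersect(attrs, names(newdata))
  n <- nrow(newdata)
  node_id <- character(n)
  # group rows by attribute pattern so each pattern is traversed once
  key <- do.call(paste, c(lapply(present, function(a) {
    v <- newdata[[a]]
    ifelse(is.na(v), "NA", as.character(v))
  }), sep = "|"))
  if (n == 0) {
    return(data.frame(probability = numeric(0), node = character(0)))
  }
  for (k in unique(key)) {
    rows <- which(key == k)
    av <- lapply(present, function(a) newdata[[a]][rows[1]])
    names(av) <- present
    node_id[rows] <- traverse_tree(object$tree, av)
  }
  prob <- numeric(n)
  for (id in unique(node_id)) {
    rows <- which(node_id == id)
    hist <- object$tree$nodes[[id]]$histogram
    if (is.null(hist)) stop("node ", id, " is not calibrated")
    prob[rows] <- histogram_lookup(hist, newdata$score[rows])
  }
  data.frame(probability = prob, node = node_id,
             stringsAsFactors = FALSE)
}

#' Ensemble prediction over randomly initialized models
#'
#' Computes per-model calibrated probabilities for one variant, keeps the
#' central \code{keep} values (trimming equally from both tails of the
#' sorted probabilities), and summarizes them by median and standard
#' deviation.
#'
#' @param models list of fitted \code{calib_model} objects.
#' @param attrs named tri-state attribute vector for the variant.
#' @param score the variant's raw score.
#' @param keep number of central models to keep (default 75).
#' @return list with \code{median} and \code{sd}.
#' @export
ensemble_predict <- function(models, attrs, score, keep = 75) {
  if (keep > length(models)) stop("keep exceeds the number of models")
  probs <- vapply(models, function(m) map_variant(m, attrs, score)$probability,
                  numeric(1))
  probs <- sort(probs)
  drop_low <- (length(probs) - keep) %/% 2
  central <- probs[(drop_low + 1):(drop_low + keep)]
  list(median = stats::median(central), sd = stats::sd(central))
}

#' Seen-vs-unseen evaluation (data-leakage check)
#'
#' Verifies that the calibration mapping cannot memorize individual labeled
#' examples.  Records are assigned to their terminal tree node; within each
#' node the classes are balanced to the smaller class and split into equal
#' train and test halves; per-node mixtures are fitted on the train half
#' only (pathogenic fraction 0.5 by construction) and converted to
#' histograms; pooled AUROC is then compared between the train (seen) and
#' test (unseen) halves, which have identical size and label composition.
#'
#' @param table labeled, scored \code{variant_table}.
#' @param cfg a \code{\link{tree_config}}.
#' @param min_per_class nodes with fewer balanced pairs than this are left
#'   out of the comparison (default 50).
#' @return list with \code{auroc_seen}, \code{auroc_unseen},
#'   \code{n_seen}, \code{n_unseen}.
#' @export
no_leakage_eval <- function(table, cfg = tree_config(), min_per_class = 50) {
  table <- table[!is.na(table$label) & !is.na(table$score), , drop = FALSE]
  keep <- modified_zscore_filter(table$score, cfg$z_threshold)
  table <- table[keep, , drop = FALSE]
  rownames(table) <- NULL
  tree <- prune_tree(build_tree(table, cfg), cfg)
  # terminal node per record under inference-time traversal
  attrs <- c(cfg$root_attr, cfg$partition_attrs)
  fake_model <- structure(list(tree = tree, attribute_names = attrs),
                          class = "calib_model")
  node_of <- character(nrow(table))
  key <- do.call(paste, c(lapply(attrs, function(a) {
    v <- table[[a]]
    ifelse(is.na(v), "NA", as.character(v))
  }), sep = "|"))
  for (k in unique(key)) {
    rows <- which(key == k)
    av <- lapply(attrs, function(a) table[[a]][rows[1]])
    names(av) <- attrs
    node_of[rows] <- traverse_tree(tree, av)
  }
  seen_prob <- numeric(0); seen_lab <- integer(0)
  unseen_prob <- numeric(0); unseen_lab <- integer(0)
  for (id in unique(node_of)) {
    rows <- which(node_of == id)
    pos <- rows[table$label[rows] == 1L]
    neg <- rows[table$label[rows] == 0L]
    m <- min(length(pos), length(neg))
    half <- m %/% 2
    if (half < min_per_class) next
    set.seed(derive_seed(cfg$seed, paste0(id, "#leak")))
    pos <- sample(pos, 2 * half)
    neg <- sample(neg, 2 * half)
    train <- c(pos[seq_len(half)], neg[seq_len(half)])
    test <- c(pos[(half + 1):(2 * half)], neg[(half + 1):(2 * half)])
    gb <- fit_gmm1d(table$score[intersect(train, neg)], K = cfg$K,
                    seed = derive_seed(cfg$seed, paste0(id, "#lb")))
    gp <- fit_gmm1d(table$score[intersect(train, pos)], K = cfg$K,
                    seed = derive_seed(cfg$seed, paste0(id, "#lp")))
    hist <- build_histogram(gb, gp, 0.5, n_sample = cfg$n_sample,
                            n_bins = cfg$n_bins,
                            seed = derive_seed(cfg$seed, paste0(id, "#lh")))
    seen_prob <- c(seen_prob, histogram_lookup(hist, table$score[train]))
    seen_lab <- c(seen_lab, table$label[train])
    unseen_prob <- c(unseen_prob, histogram_lookup(hist, table$score[test]))
    unseen_lab <- c(unseen_lab, table$label[test])
  }
  if (length(seen_lab) == 0) stop("no node large enough for the comparison")
  list(auroc_seen = auroc(seen_prob, seen_lab),
       auroc_unseen = auroc(unseen_prob, unseen_lab),
       n_seen = length(seen_lab), n_unseen = length(unseen_lab))
}
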