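# Attribute-partitioned calibration tree: greedy construction ordered by
# class-conditional divergence, threshold-based pruning, and the set of
# nodes at which inference-time traversal can terminate.

#' Calibration tree configuration
#'
#' Hyperparameters of the calibration tree and per-node models.  Defaults:
#' partition attributes disordered / sulfur_binding / ppi; root split on
#' long_protein; pruning thresholds 1600 total, 400 pathogenic, 400 benign
#' variants per leaf; 500 labels for pathogenic-fraction estimation; 400
#' training scores per class for two-component mixtures; 40,000 synthetic
#' draws into 50 equal-frequency bins; pooled modified z-score outlier cutoff
#' 4.25.
#'
#' @param partition_attrs ordered attribute names used for greedy splits.
#' @param root_attr attribute for the fixed root split (protein length class).
#' @param min_total,min_pos,min_neg pruning thresholds per leaf.
#' @param divergence_feature feature whose class-conditional divergence
#'   orders the splits: \code{"score"} (the LLR itself, default) or
#'   \code{"entropy"} (requires an \code{entropy} column).
#' @param jsd_subset per-class per-side subsample size for divergence
#'   estimation during tree construction.
#' @param n_frac labels sampled to estimate each node's pathogenic fraction.
#' @param n_gmm training scores per class for the per-node mixtures.
#' @param K mixture components per class.
#' @param n_sample synthetic draws per calibration histogram.
#' @param n_bins equal-frequency bins per histogram.
#' @param z_threshold pooled modified z-score outlier cutoff.
#' @param seed master seed; per-node seeds are derived deterministically
#'   from it and the node path.
#' @return object of class \code{tree_config}.
#' @export
tree_config <- function(partition_attrs = c("disordered", "sulfur_binding", "ppi"),
                        root_attr = "long_protein",
                        min_total = 1600, min_pos = 400, min_neg = 400,
                        divergence_feature = c("score", "entropy"),
                        jsd_subset = 400, n_frac = 500, n_gmm = 400, K = 2,
                        n_sample = 40000, n_bins = 50, z_threshold = 4.25,
                        seed = 1) {
  divergence_feature <- match.arg(divergence_feature)
  if (min_total <= 0 || min_pos <= 0 || min_neg <= 0) {
    stop("pruning thresholds must be positive")
  }
  if (root_attr %in% partition_attrs) {
    stop("root_attr must not appear in partition_attrs")
  }
  structure(list(partition_attrs = partition_attrs, root_attr = root_attr,
                 min_total = min_total, min_pos = min_pos, min_neg = min_neg,
                 divergence_feature = divergence_feature,
                 jsd_subset = jsd_subset, n_frac = n_frac, n_gmm = n_gmm,
                 K = K, n_sample = n_sample, n_bins = n_bins,
                 z_threshold = z_threshold, seed = seed),
            class = "tree_config")
}

new_tree_node <- function(id, parent, depth, path, members, available,
                          labels) {
  lab <- labels[members]
  list(id = id, parent = parent, depth = depth, path = path,
       members = members, available = available,
       split_attr = NA_character_,
       children = c("true" = NA_character_, "false" = NA_character_),
       n_total = length(members),
       n_pathogenic = sum(lab == 1L, na.rm = TRUE),
       n_benign = sum(lab == 0L, na.rm = TRUE),
       fraction = NULL, gmm_benign = NULL, gmm_pathogenic = NULL,
       histogram = NULL)
}

#' Build the calibration tree
#'
#' Splits the data at the root by the length class, then greedily: each node
#' is split on the remaining partition attribute with the largest
#' class-conditional Jensen-Shannon divergence of the configured feature
#' within the node (estimated on a seeded per-class subsample).  Children
#' exclude the used attribute; records missing a node's split value stay
#' counted at that node but are excluded from deeper membership.  Attributes
#' not observed both TRUE and FALSE within a node (or with an empty
#' class-side cell) are skipped for that node.  Ties are broken by the
#' declared attribute order.
#'
#' @param table labeled, scored \code{variant_table} with all configured
#'   attribute columns.
#' @param cfg a \code{\link{tree_config}}.
#' @return object of class \code{calib_tree}: a flat, id-keyed node list.
#' @export
build_tree <- function(table, cfg = tree_config()) {
  needed <- c(cfg$root_attr, cfg$partition_attrs)
  missing_attr <- setdiff(needed, names(table))
  if (length(missing_attr) > 0) {
    stop("table lacks attribute column(s): ",
         paste(missing_attr, collapse = ", "))
  }
  if (!("label" %in% names(table)) || all(is.na(table$label))) {
    stop("table carries no labels")
  }
  feature <- switch(cfg$divergence_feature,
                    score = table$score,
                    entropy = {
                      if (!("entropy" %in% names(table))) {
                        stop("divergence_feature 'entropy' requires an 'entropy' column")
                      }
                      table$entropy
                    })
  labels <- table$label
  nodes <- list()
  root <- new_tree_node("root", NA_character_, 0L, list(),
                        seq_len(nrow(table)), cfg$partition_attrs, labels)
  # fixed root split on the length class
  queue <- list()
  rv <- table[[cfg$root_attr]][root$members]
  if (any(rv %in% TRUE) && any(rv %in% FALSE)) {
    root$split_attr <- cfg$root_attr
    for (val in c(TRUE, FALSE)) {
      cid <- paste0("root|", cfg$root_attr, "=", as.integer(val))
      child <- new_tree_node(cid, "root", 1L,
                             c(root$path, list(list(attr = cfg$root_attr,
                                                    value = val))),
                             root$members[which(rv %in% val)],
                             cfg$partition_attrs, labels)
      root$children[[if (val) "true" else "false"]] <- cid
      queue[[length(queue) + 1L]] <- child
    }
  } else {
    warning("root attribute '", cfg$root_attr,
            "' is constant; root not split")
  }
  nodes[["root"]] <- root
  while (length(queue) > 0) {
    node <- queue[[1L]]
    queue <- queue[-1L]
    split <- choose_split(node, table, feature, labels, cfg)
    if (!is.null(split)) {
      node$split_attr <- split$attr
      vals <- table[[split$attr]][node$members]
      for (val in c(TRUE, FALSE)) {
        cid <- paste0(node$id, "|", split$attr, "=", as.integer(val))
        child <- new_tree_node(cid, node$id, node$depth + 1L,
                               c(node$path, list(list(attr = split$attr,
                                                      value = val))),
                               node$members[which(vals %in% val)],
                               setdiff(node$available, split$attr), labels)
        node$children[[if (val) "true" else "false"]] <- cid
        queue[[length(queue) + 1L]] <- child
      }
    }
    nodes[[node$id]] <- node
  }
  structure(list(nodes = nodes, root = "root", cfg = cfg),
            class = "calib_tree")
}

# Greedy split selection within a node: the available attribute with maximal
# class-conditional divergence, estimated on a seeded subsample of up to
# cfg$jsd_subset records per class per side.  Returns NULL when no attribute
# is splittable.
choose_split <- function(node, table, feature, labels, cfg) {
  best <- NULL
  best_div <- -Inf
  for (a in node$available) {
    vals <- table[[a]][node$members]
    lab <- labels[node$members]
    cells <- list(c(TRUE, 1L), c(TRUE, 0L), c(FALSE, 1L), c(FALSE, 0L))
    cell_idx <- lapply(cells, function(cl) {
      which(vals %in% cl[1] & lab == cl[2])
    })
    if (any(vapply(cell_idx, length, integer(1)) == 0)) next
    set.seed(derive_seed(cfg$seed, paste0(node$id, "#", a)))
    sel <- unlist(lapply(cell_idx, function(ix) {
      if (length(ix) > cfg$jsd_subset) sample(ix, cfg$jsd_subset) else ix
    }))
    div <- conditional_jsd(feature[node$members][sel], vals[sel], lab[sel])
    if (div > best_div) {
      best_div <- div
      best <- list(attr = a, divergence = div)
    }
  }
  best
}

#' Prune leaves with insufficient data
#'
#' Repeatedly removes every leaf with fewer than \code{min_total} variants,
#' \code{min_pos} pathogenic, or \code{min_neg} benign variants, until a full
#' traversal removes nothing.  A removed leaf's members remain in its
#' ancestors, so its variants are still calibrated at the surviving ancestor
#' node.  Cascades are handled: a parent left childless is itself a leaf in
#' the next sweep.
#'
#' @param tree a \code{calib_tree}.
#' @param cfg a \code{tree_config}; defaults to the tree's own.
#' @return the pruned \code{calib_tree}.
#' @export
prune_tree <- function(tree, cfg = tree$cfg) {
  repeat {
    removed <- FALSE
    for (id in names(tree$nodes)) {
      node <- tree$nodes[[id]]
      if (is.null(node) || !all(is.na(node$children))) next
      fails <- node$n_total < cfg$min_total ||
        node$n_pathogenic < cfg$min_pos || node$n_benign < cfg$min_neg
      if (!fails) next
      if (is.na(node$parent)) {
        stop("root node itself falls below pruning thresholds; ",
             "nothing calibratable")
      }
      parent <- tree$nodes[[node$parent]]
      slot <- names(parent$children)[parent$children %in% id]
      parent$children[slot] <- NA_character_
      if (all(is.na(parent$children))) parent$split_attr <- NA_character_
      tree$nodes[[node$parent]] <- parent
      tree$nodes[[id]] <- NULL
      removed <- TRUE
    }
    if (!removed) break
  }
  tree
}

#' Nodes at which inference-time traversal can terminate
#'
#' Leaves, nodes with a single surviving child, and nodes whose split
#' attribute has missing values among the node's members (a variant missing
#' that annotation stops there).  The fitting routine calibrates every
#' surviving node, a superset of this set, so traversal always lands on a
#' calibrated node.
#'
#' @param tree a pruned \code{calib_tree}.
#' @param table the variant table the tree was built on (for missingness).
#' @return character vector of node ids.
#' @export
calibration_node_set <- function(tree, table) {
  ids <- character(0)
  for (id in names(tree$nodes)) {
    node <- tree$nodes[[id]]
    n_children <- sum(!is.na(node$children))
    if (n_children < 2) {
      ids <- c(ids, id)
    } else if (!is.na(node$split_attr) &&
               anyNA(table[[node$split_attr]][node$members])) {
      ids <- c(ids, id)
    }
  }
  ids
}

# Traverse the tree for one variant given its named tri-state attribute
# vector; returns the id of the node where traversal stops (leaf reached,
# child pruned, or split attribute missing).
traverse_tree <- function(tree, attrs) {
  id <- tree$root
  repeat {
    node <- tree$nodes[[id]]
    if (is.na(node$split_attr)) return(id)
    v <- attrs[[node$split_attr]]
    if (is.null(v) || is.na(v)) return(id)
    child <- node$children[[if (v) "true" else "false"]]
    if (is.na(child)) return(id)
    id <- child
  }
}

#' @export
print.calib_tree <- function(x, ...) {
  cat("Calibration tree:", length(x$nodes), "nodes\n")
  for (id in names(x$nodes)) {
    node <- x$nodes[[id]]
    cat(strrep("  ", node$depth), id, "  [n=", node$n_total,
        ", path=", node$n_pathogenic, ", benign=", node$n_benign, "]",
        if (is.null(node$histogram)) "" else "  (calibrated)", "\n", sep = "")
  }
  invisible(x)
}
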