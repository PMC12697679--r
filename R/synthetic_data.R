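# Synthetic variant tables and logits with the statistical structure the
# calibration assumes: subgroup-dependent pathogenic priors and
# class-conditional two-component Gaussian score mixtures over binary
# residue attributes, with variants grouped into proteins.

#' Define a variant subgroup for the generator
#'
#' @param name subgroup label.
#' @param pattern named logical vector of the subgroup's binary residue
#'   attributes.
#' @param prior pathogenic fraction within the subgroup, in [0, 1].
#' @param benign_mix,pathogenic_mix class-conditional score mixtures
#'   (\code{\link{gmm_params}}).
#' @param weight relative abundance (> 0).
#' @return object of class \code{subgroup_spec}.
#' @export
subgroup_spec <- function(name, pattern, prior, benign_mix, pathogenic_mix,
                          weight = 1) {
  if (prior < 0 || prior > 1) stop("prior must be in [0, 1]")
  if (weight <= 0) stop("weight must be positive")
  stopifnot(inherits(benign_mix, "gmm_params"),
            inherits(pathogenic_mix, "gmm_params"))
  structure(list(name = name, pattern = pattern, prior = prior,
                 benign_mix = benign_mix, pathogenic_mix = pathogenic_mix,
                 weight = weight),
            class = "subgroup_spec")
}

#' Generator configuration
#'
#' @param subgroups list of \code{\link{subgroup_spec}} objects.
#' @param n_variants number of variants to draw.
#' @param n_proteins number of proteins variants are assigned to.
#' @param long_protein_fraction fraction of proteins longer than 1022
#'   residues.
#' @param missing_rate named numeric vector: per-attribute probability that
#'   the annotation is missing (completely at random).
#' @param seed RNG seed.
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(subgroups, n_variants = 50000, n_proteins = 500,
                             long_protein_fraction = 0.47,
                             missing_rate = c(ppi = 0.26), seed = 1) {
  if (length(subgroups) == 0) stop("at least one subgroup required")
  if (any(missing_rate < 0 | missing_rate >= 1)) {
    stop("missing_rate entries must be in [0, 1)")
  }
  structure(list(subgroups = subgroups, n_variants = n_variants,
                 n_proteins = n_proteins,
                 long_protein_fraction = long_protein_fraction,
                 missing_rate = missing_rate, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic variant table
#'
#' Each variant draws a subgroup (by weight), a protein (uniform; protein
#' lengths are drawn once per protein consistent with the long-protein
#' fraction), a label (Bernoulli at the subgroup prior), a score (from the
#' subgroup's class-conditional mixture), and attributes (the subgroup
#' pattern, with per-attribute completely-at-random missingness).  Wild-type
#' residues are drawn consistently with the sulfur-binding attribute when the
#' pattern declares it.  Deterministic given the seed.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return a \code{variant_table} with attribute columns for every pattern
#'   attribute plus \code{long_protein}, and a numeric \code{length} column.
#' @export
generate_table <- function(cfg) {
  set.seed(cfg$seed)
  subs <- cfg$subgroups
  attr_names <- unique(unlist(lapply(subs, function(s) names(s$pattern))))
  n <- cfg$n_variants
  # proteins: long/short status and lengths drawn once
  np <- cfg$n_proteins
  pid <- sprintf("P%04d", seq_len(np))
  is_long <- stats::runif(np) < cfg$long_protein_fraction
  plen <- ifelse(is_long, sample(1100:3000, np, replace = TRUE),
                 sample(200:1000, np, replace = TRUE))
  if (n == 0) {
    df <- data.frame(protein_id = character(0), position = integer(0),
                     wt = character(0), mut = character(0),
                     score = numeric(0), label = integer(0),
                     length = numeric(0))
    for (a in attr_names) df[[a]] <- logical(0)
    df$long_protein <- logical(0)
    return(variant_table(df, attributes = c(attr_names, "long_protein")))
  }
  weights <- vapply(subs, `[[`, numeric(1), "weight")
  sub_id <- sample.int(length(subs), n, replace = TRUE,
                       prob = weights / sum(weights))
  prot <- sample.int(np, n, replace = TRUE)
  position <- 1L + as.integer(floor(stats::runif(n) * plen[prot]))
  label <- integer(n)
  score <- numeric(n)
  wt <- character(n)
  am <- matrix(NA, nrow = n, ncol = length(attr_names),
               dimnames = list(NULL, attr_names))
  sulfur_aa <- c("C", "M")
  other_aa <- setdiff(CANONICAL_AA, sulfur_aa)
  for (k in seq_along(subs)) {
    rows <- which(sub_id == k)
    if (length(rows) == 0) next
    s <- subs[[k]]
    label[rows] <- stats::rbinom(length(rows), 1L, s$prior)
    pos_rows <- rows[label[rows] == 1L]
    neg_rows <- rows[label[rows] == 0L]
    score[pos_rows] <- rgmm(s$pathogenic_mix, length(pos_rows))
    score[neg_rows] <- rgmm(s$benign_mix, length(neg_rows))
    for (a in names(s$pattern)) am[rows, a] <- s$pattern[[a]]
    if (isTRUE(s$pattern[["sulfur_binding"]])) {
      wt[rows] <- sample(sulfur_aa, length(rows), replace = TRUE)
    } else {
      wt[rows] <- sample(other_aa, length(rows), replace = TRUE)
    }
  }
  mut <- vapply(wt, function(w) sample(setdiff(CANONICAL_AA, w), 1),
                character(1), USE.NAMES = FALSE)
  for (a in names(cfg$missing_rate)) {
    if (a %in% attr_names) {
      drop <- stats::runif(n) < cfg$missing_rate[[a]]
      am[drop, a] <- NA
    }
  }
  df <- data.frame(protein_id = pid[prot], position = position, wt = wt,
                   mut = mut, score = score, label = label,
                   length = as.numeric(plen[prot]),
                   stringsAsFactors = FALSE)
  for (a in attr_names) df[[a]] <- as.logical(am[, a])
  df$long_protein <- plen[prot] > 1022
  df$subgroup <- vapply(subs, `[[`, character(1), "name")[sub_id]
  variant_table(df, attributes = c(attr_names, "long_protein"))
}

#' Preset generator emulating the study-like subgroup structure
#'
#' Four subgroups over the attributes disordered / sulfur_binding / ppi with
#' pathogenic priors 0.10 (disordered), 0.61 (interface), and 0.35 elsewhere,
#' weighted so the pooled pathogenic rate is about 0.31.  Pathogenic score
#' mixtures are centered well below benign mixtures (LLR convention: more
#' negative = more deleterious), with a subgroup-specific downward
#' benign-mean shift in the disordered subgroup so that raw scores misrank
#' across subgroups and residue-aware calibration has signal to recover.
#' Interface annotations are missing completely at random for 26\% of
#' variants; 47\% of proteins are long (> 1022 residues).
#'
#' @param n_variants number of variants (default 50000).
#' @param n_proteins number of proteins (default 500).
#' @param seed RNG seed.
#' @return a \code{\link{generator_config}}.
#' @export
paper_like_config <- function(n_variants = 50000, n_proteins = 500, seed = 1) {
  base_benign <- gmm_params(c(0.45, 0.55), c(-4.5, -1.5), c(2.2, 1.5))
  base_path <- gmm_params(c(0.4, 0.6), c(-12, -8), c(3, 2.5))
  shift <- function(g, d) gmm_params(g$weights, g$means + d, g$variances)
  subgroups <- list(
    subgroup_spec("baseline",
                  c(disordered = FALSE, sulfur_binding = FALSE, ppi = FALSE),
                  prior = 0.35, benign_mix = base_benign,
                  pathogenic_mix = base_path, weight = 0.57),
    subgroup_spec("disordered",
                  c(disordered = TRUE, sulfur_binding = FALSE, ppi = FALSE),
                  prior = 0.10, benign_mix = shift(base_benign, -3),
                  pathogenic_mix = shift(base_path, -2.5), weight = 0.25),
    subgroup_spec("sulfur",
                  c(disordered = FALSE, sulfur_binding = TRUE, ppi = FALSE),
                  prior = 0.35, benign_mix = shift(base_benign, -1),
                  pathogenic_mix = shift(base_path, 1), weight = 0.08),
    subgroup_spec("ppi",
                  c(disordered = FALSE, sulfur_binding = FALSE, ppi = TRUE),
                  prior = 0.61, benign_mix = shift(base_benign, -0.5),
                  pathogenic_mix = shift(base_path, 0.5), weight = 0.10))
  generator_config(subgroups, n_variants = n_variants,
                   n_proteins = n_proteins, long_protein_fraction = 0.47,
                   missing_rate = c(ppi = 0.26), seed = seed)
}

#' Generate synthetic per-position logit matrices
#'
#' Random logit rows with controllable entropy: each row is
#' \code{sharpness} times a standard-normal draw, so large sharpness yields
#' near-one-hot softmax rows (normalized entropy near 1) and sharpness 0
#' yields uniform rows (normalized entropy 0).
#'
#' @param n_positions number of rows.
#' @param n_aa alphabet size (default 20).
#' @param sharpness non-negative scale of the logits (default 1).
#' @param seed RNG seed.
#' @return list with \code{logits} (matrix n_positions x n_aa) and
#'   \code{wt_index} (one wild-type token index per row).
#' @export
generate_logits <- function(n_positions, n_aa = 20, sharpness = 1, seed = 1) {
  if (n_aa < 2) stop("n_aa must be >= 2")
  set.seed(seed)
  logits <- matrix(sharpness * stats::rnorm(n_positions * n_aa),
                   nrow = n_positions)
  list(logits = logits,
       wt_index = sample.int(n_aa, n_positions, replace = TRUE))
}
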