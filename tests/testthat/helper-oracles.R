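# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles are written from the definitions directly (pairwise counting,
# exhaustive scans, direct histogram arithmetic) and never reuse the code
# paths they check.

# AUROC as the fraction of concordant (pathogenic, benign) pairs, ties
# counted one half.
auroc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Youden threshold by evaluating TPR - FPR at every candidate cut directly.
youden_brute <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  best_j <- -Inf
  best_c <- NA
  for (c0 in cand) {
    tpr <- mean(scores[labels == 1] >= c0)
    fpr <- mean(scores[labels == 0] >= c0)
    if (tpr - fpr > best_j) {
      best_j <- tpr - fpr
      best_c <- c0
    }
  }
  list(threshold = best_c, J = best_j)
}

# Conditional JSD computed from scratch: explicit equal-width histograms,
# explicit smoothing, explicit KL sums.
jsd_brute <- function(feature, mask, labels, bins = 100, eps = exp(-12)) {
  rng <- range(feature)
  if (rng[1] < 0 || rng[2] > 1) {
    feature <- (feature - rng[1]) / (rng[2] - rng[1])
  }
  hist_of <- function(x) {
    counts <- numeric(bins)
    for (v in x) {
      b <- min(floor(v * bins) + 1, bins)
      counts[b] <- counts[b] + 1
    }
    counts <- counts + eps
    counts / sum(counts)
  }
  total <- 0
  for (l in c(0, 1)) {
    p <- hist_of(feature[mask & labels == l])
    q <- hist_of(feature[!mask & labels == l])
    m <- (p + q) / 2
    total <- total + 0.5 * sum(p * log(p / m)) + 0.5 * sum(q * log(q / m))
  }
  total
}

# Two-sided Fisher exact p-value by hypergeometric enumeration over all
# tables with the observed margins.
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c0 <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c0; n <- a + b + c0 + d
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  total <- 0
  for (x in max(0, r1 - (n - c1)):min(r1, c1)) {
    px <- stats::dhyper(x, c1, n - c1, r1)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  total
}

# Kendall's tau by explicit concordant/discordant pair counting.
kendall_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Small hand-buildable labeled table.
toy_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    protein_id = sample(c("P1", "P2", "P3"), n, replace = TRUE),
    position = sample(1:500, n, replace = TRUE),
    wt = sample(setdiff(racoon::CANONICAL_AA, "A"), n, replace = TRUE),
    mut = "A",
    score = stats::rnorm(n),
    label = sample(0:1, n, replace = TRUE),
    stringsAsFactors = FALSE)
  racoon::variant_table(df)
}

# Shared fitted model on study-condition synthetic data; fitted once per
# test run.
.fixture_env <- new.env(parent = emptyenv())

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$train <- generate_table(paper_like_config(n_variants = 50000,
                                                           seed = 421))
    .fixture_env$cfg <- tree_config(seed = 17)
    .fixture_env$model <- suppressMessages(
      fit_racoon(.fixture_env$train, .fixture_env$cfg))
    .fixture_env$test <- generate_table(paper_like_config(n_variants = 20000,
                                                          seed = 422))
  }
  list(model = .fixture_env$model, train = .fixture_env$train,
       test = .fixture_env$test, cfg = .fixture_env$cfg)
}
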