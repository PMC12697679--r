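test_that("conditional JSD matches a direct brute-force computation", {
  # 8-point worked toy
  feature <- c(0.05, 0.15, 0.22, 0.40, 0.55, 0.71, 0.80, 0.95)
  mask <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  labels <- c(1, 0, 1, 0, 1, 0, 1, 0)
  expect_equal(conditional_jsd(feature, mask, labels),
               jsd_brute(feature, mask, labels), tolerance = 1e-12)
  # larger random case, including min-max mapping of an unbounded feature
  set.seed(21)
  f2 <- rnorm(400, mean = ifelse(runif(400) < 0.5, -4, 2))
  m2 <- runif(400) < 0.5
  l2 <- rbinom(400, 1, 0.4)
  expect_equal(conditional_jsd(f2, m2, l2), jsd_brute(f2, m2, l2),
               tolerance = 1e-12)
})

test_that("conditional JSD is symmetric, bounded and detects identity", {
  set.seed(22)
  # literally identical samples in M and not-M: divergence vanishes
  f0 <- runif(600); l0 <- rbinom(600, 1, 0.5)
  f <- c(f0, f0)
  m <- rep(c(TRUE, FALSE), each = 600)
  l <- c(l0, l0)
  d <- conditional_jsd(f, m, l)
  expect_lt(d, 1e-10)
  expect_equal(conditional_jsd(f, !m, l), d, tolerance = 1e-12)
  # disjoint supports at both labels approach the 2*log(2) maximum
  f2 <- ifelse(m, runif(1200, 0, 0.4), runif(1200, 0.6, 1))
  d2 <- conditional_jsd(f2, m, l)
  expect_gt(d2, 2 * log(2) - 0.01)
  expect_lte(d2, 2 * log(2) + 1e-9)
  expect_error(conditional_jsd(runif(10), rep(TRUE, 10), rbinom(10, 1, 0.5)),
               "empty subgroup-label cell")
})

test_that("conditional JSD decreases as the subgroups are interpolated toward equality", {
  set.seed(23)
  n <- 20000
  m <- rep(c(TRUE, FALSE), n / 2)
  l <- rbinom(n, 1, 0.5)
  prev <- Inf
  for (alpha in c(1, 0.75, 0.5, 0.25, 0)) {
    # subgroup M shifted by alpha * 0.3 on the unit scale
    f <- pmin(pmax(ifelse(m, 0.35 + alpha * 0.3, 0.35) +
                     runif(n, -0.25, 0.25), 0), 1)
    d <- conditional_jsd(f, m, l)
    expect_lt(d, prev + 0.02)
    prev <- d
  }
  expect_lt(prev, 0.05)  # at alpha = 0 the subgroups coincide
})

test_that("a score-shifting attribute receives larger divergence than an inert one", {
  set.seed(24)
  n <- 8000
  shifting <- runif(n) < 0.5
  inert <- runif(n) < 0.5
  lab <- rbinom(n, 1, 0.4)
  score <- rnorm(n, mean = ifelse(lab == 1, -8, -2) + ifelse(shifting, -3, 0))
  expect_gt(conditional_jsd(score, shifting, lab),
            conditional_jsd(score, inert, lab))
})

test_that("label shift is the absolute prior difference", {
  labels <- c(rep(1, 31), rep(0, 69))
  expect_equal(label_shift(labels, rep(TRUE, 100)), 0)
  mask <- c(rep(TRUE, 10), rep(FALSE, 90))
  labels2 <- c(rep(1, 1), rep(0, 9), rep(1, 30), rep(0, 60))
  expect_equal(label_shift(labels2, mask), abs(0.31 - 0.10))
  expect_equal(label_shift(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_error(label_shift(c(1, 0), c(FALSE, FALSE)), "empty")
})

test_that("mutual information recovers closed forms and is reproducible", {
  # group identical to label: MI equals the label entropy
  lab <- c(rep(1L, 300), rep(0L, 700))
  h <- -(0.3 * log(0.3) + 0.7 * log(0.7))
  mi <- mutual_information(lab, lab, bootstrap = 50, seed = 5)
  expect_equal(mi$mi, h, tolerance = 1e-12)
  # independence: MI near zero at large n
  set.seed(26)
  g <- sample(1:3, 20000, replace = TRUE)
  l <- rbinom(20000, 1, 0.4)
  mi0 <- mutual_information(l, g, bootstrap = 50, seed = 5)
  expect_lt(mi0$mi, 0.001)
  # reproducibility
  mi_a <- mutual_information(l, g, bootstrap = 100, seed = 9)
  mi_b <- mutual_information(l, g, bootstrap = 100, seed = 9)
  expect_identical(mi_a, mi_b)
  expect_error(mutual_information(l, rep(1, 20000)), "two groups")
})

test_that("protein-level grouping is protein-constant and bins by fraction", {
  df <- data.frame(protein_id = rep(c("A", "B", "C"), each = 4),
                   position = 1:12, wt = "A", mut = "V", score = 0,
                   label = rep(0:1, 6))
  df$attr <- c(rep(FALSE, 4),                      # fraction 0.0
               c(TRUE, TRUE, FALSE, FALSE),        # fraction 0.5
               rep(TRUE, 4))                       # fraction 1.0
  tab <- variant_table(df, attributes = "attr")
  g <- protein_level_groups(tab, "attr", n_bins = 3)
  expect_equal(length(unique(g)), 3)
  expect_true(all(tapply(g, tab$protein_id, function(v) length(unique(v))) == 1))
  # degenerate: everything at fraction zero collapses to one group
  df$attr <- FALSE
  g0 <- protein_level_groups(variant_table(df, attributes = "attr"), "attr")
  expect_equal(length(unique(g0)), 1)
})

test_that("Fisher tests match hypergeometric enumeration and BH adjusts step-up", {
  flat <- matrix(c(5, 5, 5, 5), 2)
  res <- fisher_bh(list(flat))
  expect_equal(res$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(res$p, 1)
  expect_equal(res$p_adj, res$p)  # BH identity at m = 1
  tabs <- list(matrix(c(10, 0, 0, 10), 2), matrix(c(8, 2, 3, 7), 2), flat)
  res3 <- fisher_bh(tabs)
  for (i in seq_along(tabs)) {
    expect_equal(res3$p[i], fisher_enum(tabs[[i]]), tolerance = 1e-9)
  }
  expect_equal(res3$p_adj, p.adjust(res3$p, "BH"))
  expect_error(fisher_bh(list(matrix(0, 2, 2))), "all-zero")
})

test_that("Kendall tau stability matches brute-force pair counting", {
  a <- c(x1 = 1, x2 = 2, x3 = 3, x4 = 4, x5 = 5)
  same <- list(`100` = a, `50` = a)
  expect_equal(kendall_tau_stability(same)["100", "50"], 1)
  rev5 <- stats::setNames(rev(unname(a)), names(a))
  expect_equal(kendall_tau_stability(list(`100` = a, `50` = rev5))["100", "50"],
               -1)
  set.seed(27)
  b <- stats::setNames(rnorm(5), names(a))
  d <- stats::setNames(rnorm(5), names(a))
  m <- kendall_tau_stability(list(b1 = b, b2 = d))
  expect_equal(m["b1", "b2"], kendall_brute(b[names(a)], d[names(a)]),
               tolerance = 1e-12)
  expect_error(kendall_tau_stability(list(b1 = b, b2 = d[1:4])), "differ")
})

test_that("shift_scan reports one adjusted row per attribute", {
  tab <- generate_table(paper_like_config(n_variants = 6000, seed = 31))
  res <- shift_scan(tab)
  expect_setequal(res$attribute, attribute_names(tab))
  expect_true(all(c("n_M", "n_notM", "label_shift", "divergence",
                    "odds_ratio", "p", "p_adj") %in% names(res)))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  # the disordered subgroup carries the designed strong label shift
  expect_gt(res$label_shift[res$attribute == "disordered"], 0.1)
})
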