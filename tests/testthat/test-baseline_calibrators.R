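test_that("logistic rescaling evaluates the sigmoid and keeps orientation", {
  p <- logistic_params(1, 0)
  expect_equal(apply_logistic(p, 0), 0.5)
  expect_true(all(apply_logistic(p, seq(-30, 30)) > 0))
  expect_true(all(apply_logistic(p, seq(-30, 30)) < 1))
  expect_true(all(diff(apply_logistic(p, seq(-5, 5, 0.1))) > 0))
  # orientation: higher scores in the pathogenic class give positive slope
  set.seed(71)
  s <- c(rnorm(500, 2), rnorm(500, -2))
  l <- rep(c(1L, 0L), each = 500)
  fit <- logistic_calibrate(s, l, seed = 1)
  expect_gt(fit$c1, 0)
  fit_rev <- logistic_calibrate(-s, l, seed = 1)
  expect_lt(fit_rev$c1, 0)
  expect_error(logistic_calibrate(rnorm(100), rep(1L, 100)), "both classes")
})

test_that("the fitted slope approaches the equal-variance Gaussian value", {
  # classes N(-1,1) and N(+1,1): the population logistic slope is
  # (mu1 - mu0) / sigma^2 = 2
  set.seed(72)
  n <- 20000
  s <- c(rnorm(n, 1), rnorm(n, -1))
  l <- rep(c(1L, 0L), each = n)
  fit <- logistic_calibrate(s, l, n_per_class = n - 50, seed = 2)
  expect_equal(fit$c1, 2, tolerance = 0.08)
})

test_that("AUROC is invariant under the logistic transform", {
  set.seed(73)
  s <- rnorm(400)
  l <- rbinom(400, 1, plogis(s))
  p <- logistic_params(1.7, 0.3)
  expect_equal(auroc(apply_logistic(p, s), l), auroc(s, l), tolerance = 1e-12)
})

test_that("per-subgroup logistic calibration handles schemes and fallbacks", {
  tab <- generate_table(paper_like_config(n_variants = 20000, seed = 74))
  # orient scores pathogenic-high for the logistic convention
  tab$score <- -tab$score
  fit <- subgroup_logistic_calibrate(tab, scheme = "fold_split",
                                     n_per_class = 300, seed = 3)
  expect_setequal(names(fit$subgroups), c("disordered", "ordered"))
  pred <- predict(fit, tab)
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  # improves global AUROC over raw scores on subgroup-shifted data
  expect_gt(auroc(pred$probability, tab$label), auroc(tab$score, tab$label))
  # joint scheme: missing interface annotations fall back to global
  fit_j <- subgroup_logistic_calibrate(tab, scheme = "joint",
                                       n_per_class = 300, seed = 3)
  pred_j <- predict(fit_j, tab)
  expect_true(all(pred_j$subgroup[is.na(tab$ppi) & !tab$disordered] == "global"))
  # a subgroup without a feasible balanced sample falls back to the
  # global parameters with a warning (interface residues are rare)
  tiny <- tab[1:2000, ]
  expect_warning(
    fit_t <- subgroup_logistic_calibrate(tiny, scheme = "ppi_split",
                                         n_per_class = 300, seed = 3),
    "falling back")
  expect_equal(fit_t$subgroups[["ppi"]], fit_t$global)
})

test_that("exchangeable subgroups get near-identical parameters", {
  set.seed(75)
  n <- 8000
  df <- data.frame(protein_id = "P1", position = 1:n, wt = "A", mut = "V",
                   score = NA_real_, label = rbinom(n, 1, 0.4),
                   disordered = runif(n) < 0.5)
  df$score <- rnorm(n, mean = ifelse(df$label == 1, 2, -2))
  tab <- variant_table(df, attributes = "disordered")
  fit <- subgroup_logistic_calibrate(tab, scheme = "fold_split",
                                     n_per_class = 1200, seed = 4)
  expect_equal(fit$subgroups$disordered$c1, fit$subgroups$ordered$c1,
               tolerance = 0.25)
})

test_that("direct binning matches hand enumeration", {
  expect_true(all(direct_binning_calibrate(rnorm(100), rep(0L, 100),
                                           10)$bin_fraction == 0))
  h <- direct_binning_calibrate(seq_len(100), rep(c(0L, 1L), 50), 50)
  expect_true(all(h$bin_count == 2))
  # 10-score toy, 2 bins: low bin holds scores 1..5 (2 pathogenic),
  # high bin scores 6..10 (3 pathogenic)
  toy_scores <- 1:10
  toy_labels <- c(1, 0, 1, 0, 0, 1, 1, 0, 0, 1)
  h2 <- direct_binning_calibrate(toy_scores, toy_labels, 2)
  expect_equal(h2$bin_fraction, c(2 / 5, 3 / 5))
  expect_equal(h2$edges, c(-Inf, 5.5, Inf))
  expect_error(direct_binning_calibrate(1:5, rep(0, 5), 10), "exceeds")
})

test_that("hybrid binning reduces to each pure strategy at the boundaries", {
  set.seed(76)
  syn <- rnorm(2000)
  src <- rbinom(2000, 1, 0.4) == 1
  raw <- rnorm(500)
  rawlab <- rbinom(500, 1, 0.5)
  only_syn <- hybrid_binning_calibrate(syn, src, numeric(0), integer(0), 20)
  expect_equal(only_syn, direct_binning_calibrate(syn, as.integer(src), 20))
  only_raw <- hybrid_binning_calibrate(numeric(0), logical(0), raw, rawlab, 20)
  expect_equal(only_raw, direct_binning_calibrate(raw, rawlab, 20))
  # 50/50 pool toy by enumeration: 4 synthetic + 4 raw, 2 bins
  h <- hybrid_binning_calibrate(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE),
                                c(1.5, 2.5, 3.5, 4.5), c(0, 1, 0, 1), 2)
  # sorted pool: 1(T) 1.5(0) 2(F) 2.5(1) | 3(T) 3.5(0) 4(F) 4.5(1)
  expect_equal(h$bin_fraction, c(2 / 4, 2 / 4))
  expect_error(hybrid_binning_calibrate(numeric(0), logical(0), numeric(0),
                                        integer(0), 2), "empty")
})

test_that("subgroup calibration lowers subgroup miscalibration versus a global fit", {
  tab <- generate_table(paper_like_config(n_variants = 40000, seed = 77))
  tab$score <- -tab$score
  glob <- logistic_calibrate(tab$score, tab$label, n_per_class = 3000,
                             seed = 5)
  sub <- subgroup_logistic_calibrate(tab, scheme = "fold_split",
                                     n_per_class = 500, seed = 5)
  test <- generate_table(paper_like_config(n_variants = 20000, seed = 78))
  test$score <- -test$score
  dis <- which(test$disordered)
  p_glob <- apply_logistic(glob, test$score[dis])
  p_sub <- predict(sub, test[dis, ])$probability
  ece_glob <- reliability_histogram(p_glob, test$label[dis])$ece
  ece_sub <- reliability_histogram(p_sub, test$label[dis])$ece
  expect_lt(ece_sub, ece_glob)
})
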