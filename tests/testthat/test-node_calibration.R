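test_that("fraction estimation censuses small nodes and samples large ones", {
  expect_equal(estimate_fraction(rep(1L, 30))$fraction, 1)
  lab <- rep(c(1L, 0L), c(40, 60))
  est <- estimate_fraction(lab, n_p = 500, seed = 2)
  expect_equal(est$fraction, 0.4)          # census below n_p
  expect_identical(est$idx, seq_along(lab))
  # sampling error bounded by 3 binomial SEs of 500 draws
  big <- rbinom(20000, 1, 0.3)
  se <- sqrt(0.3 * 0.7 / 500)
  for (s in 1:8) {
    est_s <- estimate_fraction(big, n_p = 500, seed = s)
    expect_length(est_s$idx, 500)
    expect_lt(abs(est_s$fraction - 0.3), 3 * se)
  }
})

test_that("per-node mixture fitting recovers class distributions and reuses samples", {
  gb <- gmm_params(c(0.5, 0.5), c(-4, -1), c(1, 1))
  gp <- gmm_params(c(0.5, 0.5), c(-12, -7), c(1.5, 1))
  set.seed(61)
  lab <- rbinom(12000, 1, 0.4)
  sc <- numeric(12000)
  sc[lab == 1] <- rgmm(gp, sum(lab == 1))
  sc[lab == 0] <- rgmm(gb, sum(lab == 0))
  fit <- fit_node_gmms(sc, lab, n_gmm = 4000, seed = 3)
  expect_equal(fit$gmm_benign$means, gb$means, tolerance = 0.1)
  expect_equal(fit$gmm_pathogenic$means, gp$means, tolerance = 0.1)
  # determinism and the n_gmm precondition
  expect_identical(fit_node_gmms(sc, lab, n_gmm = 400, seed = 9),
                   fit_node_gmms(sc, lab, n_gmm = 400, seed = 9))
  expect_error(fit_node_gmms(sc, lab, n_gmm = 1e6), "fewer than n_gmm")
})

test_that("calibration histograms conserve the pathogenic draw fraction exactly", {
  gb <- gmm_params(c(0.5, 0.5), c(-4, -1), c(1, 1))
  gp <- gmm_params(c(0.5, 0.5), c(-12, -7), c(1.5, 1))
  for (frac in c(0, 0.31, 0.5)) {
    h <- build_histogram(gb, gp, frac, n_sample = 20000, n_bins = 50, seed = 4)
    expect_equal(sum(h$bin_count * h$bin_fraction) / sum(h$bin_count),
                 round(20000 * frac) / 20000, tolerance = 1e-12)
    expect_true(all(diff(h$bin_count) %in% -1:1))
    expect_identical(h$edges[1], -Inf)
    expect_identical(h$edges[length(h$edges)], Inf)
  }
  expect_true(all(build_histogram(gb, gp, 0, seed = 1)$bin_fraction == 0))
  expect_error(build_histogram(gb, gp, 0.5, n_sample = 10, n_bins = 50),
               "exceeds")
})

test_that("identical class mixtures yield flat histograms at the prior", {
  g <- gmm_params(c(0.5, 0.5), c(-5, -1), c(1, 1))
  p0 <- 0.35
  h <- build_histogram(g, g, p0, n_sample = 40000, n_bins = 50, seed = 5)
  bound <- 3 * sqrt(p0 * (1 - p0) / (40000 / 50))
  expect_true(all(abs(h$bin_fraction - p0) < bound))
})

test_that("well-separated mixtures yield monotone bin fractions", {
  gb <- gmm_params(c(0.5, 0.5), c(-2, 0), c(0.8, 0.8))
  gp <- gmm_params(c(0.5, 0.5), c(-14, -10), c(0.8, 0.8))
  h <- build_histogram(gb, gp, 0.4, n_sample = 40000, n_bins = 50, seed = 6)
  # pathogenic mass sits at low scores: fractions non-increasing up to noise
  viol <- diff(h$bin_fraction)
  expect_true(all(viol < 0.03))
  expect_gt(h$bin_fraction[1], 0.95)
  expect_lt(h$bin_fraction[50], 0.05)
})

test_that("variant mapping follows traversal rules and bin clamping", {
  fx <- fixture_model()
  model <- fx$model
  # full-path variant: probability equals an independent bin lookup
  attrs <- c(long_protein = TRUE, disordered = FALSE, sulfur_binding = FALSE,
             ppi = FALSE)
  leaf_id <- "root|long_protein=1|disordered=0|sulfur_binding=0|ppi=0"
  hist <- model$tree$nodes[[leaf_id]]$histogram
  for (s in c(-20, -6.5, -0.01, 5)) {
    res <- map_variant(model, attrs, s)
    expect_identical(res$node, leaf_id)
    bin <- max(1, min(findInterval(s, hist$edges), length(hist$bin_fraction)))
    expect_equal(res$probability, hist$bin_fraction[bin])
  }
  # missing interface annotation stops above the ppi split
  attrs_na <- c(long_protein = TRUE, disordered = FALSE,
                sulfur_binding = FALSE, ppi = NA)
  res_na <- map_variant(model, attrs_na, -6.5)
  expect_identical(res_na$node,
                   "root|long_protein=1|disordered=0|sulfur_binding=0")
  # clamping: scores beyond the sentinels take the terminal bins
  expect_equal(map_variant(model, attrs, -1e6)$probability,
               hist$bin_fraction[1])
  expect_equal(map_variant(model, attrs, 1e6)$probability,
               hist$bin_fraction[length(hist$bin_fraction)])
})

test_that("vectorized prediction agrees with per-variant mapping", {
  fx <- fixture_model()
  sub <- fx$test[1:200, ]
  pred <- predict(fx$model, sub)
  for (i in seq_len(50)) {
    av <- c(long_protein = sub$long_protein[i], disordered = sub$disordered[i],
            sulfur_binding = sub$sulfur_binding[i], ppi = sub$ppi[i])
    one <- map_variant(fx$model, av, sub$score[i])
    expect_equal(pred$probability[i], one$probability)
    expect_identical(pred$node[i], one$node)
  }
})

test_that("the fitted model is fully populated and deterministic", {
  fx <- fixture_model()
  model <- fx$model
  for (node in model$tree$nodes) {
    expect_false(is.null(node$fraction))
    expect_s3_class(node$gmm_benign, "gmm_params")
    expect_s3_class(node$gmm_pathogenic, "gmm_params")
    expect_s3_class(node$histogram, "calibration_histogram")
    expect_equal(node$n_total, node$n_pathogenic + node$n_benign)
  }
  expect_error(fit_racoon(fx$train[, setdiff(names(fx$train), "label")]),
               "label")
  # refitting with the same master seed reproduces the model byte for byte
  model2 <- suppressMessages(fit_racoon(fx$train, fx$cfg))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_calib_model(model, f1)
  write_calib_model(model2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("model JSON round-trips exactly", {
  fx <- fixture_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_calib_model(fx$model, path)
  back <- read_calib_model(path)
  expect_identical(names(back$tree$nodes), names(fx$model$tree$nodes))
  for (id in names(back$tree$nodes)) {
    a <- fx$model$tree$nodes[[id]]
    b <- back$tree$nodes[[id]]
    expect_identical(b$children, a$children)
    expect_equal(b$fraction, a$fraction, tolerance = 0)
    expect_equal(unclass(b$gmm_benign), unclass(a$gmm_benign), tolerance = 0)
    expect_equal(unclass(b$gmm_pathogenic), unclass(a$gmm_pathogenic),
                 tolerance = 0)
    expect_equal(b$histogram$edges, a$histogram$edges, tolerance = 0)
    expect_equal(b$histogram$bin_fraction, a$histogram$bin_fraction,
                 tolerance = 0)
  }
  # predictions from the deserialized model are identical
  pred_a <- predict(fx$model, fx$test[1:500, ])
  pred_b <- predict(back, fx$test[1:500, ])
  expect_identical(pred_a, pred_b)
})

test_that("node-family synthetic draws are calibrated against their own histogram", {
  fx <- fixture_model()
  nodes <- fx$model$tree$nodes
  leaf_ids <- names(nodes)[vapply(nodes, function(n) all(is.na(n$children)),
                                  logical(1))]
  set.seed(62)
  for (id in leaf_ids[1:3]) {
    node <- nodes[[id]]
    n_test <- 20000
    lab <- rbinom(n_test, 1, node$fraction)
    sc <- numeric(n_test)
    sc[lab == 1] <- rgmm(node$gmm_pathogenic, sum(lab == 1))
    sc[lab == 0] <- rgmm(node$gmm_benign, sum(lab == 0))
    probs <- racoon:::histogram_lookup(node$histogram, sc)
    expect_lt(reliability_histogram(probs, lab)$ece, 0.05)
  }
})

test_that("ensemble prediction trims to the central models", {
  fx <- fixture_model()
  attrs <- c(long_protein = FALSE, disordered = TRUE, sulfur_binding = FALSE,
             ppi = FALSE)
  same <- replicate(10, fx$model, simplify = FALSE)
  res <- ensemble_predict(same, attrs, -6, keep = 8)
  expect_equal(res$sd, 0)
  expect_equal(res$median, map_variant(fx$model, attrs, -6)$probability)
  # distinct seeded models: median inside the per-model range
  models <- lapply(1:6, function(s) {
    suppressMessages(fit_racoon(
      generate_table(paper_like_config(n_variants = 20000, seed = 700 + s)),
      tree_config(seed = s, n_sample = 10000)))
  })
  probs <- vapply(models, function(m) map_variant(m, attrs, -6)$probability,
                  numeric(1))
  res6 <- ensemble_predict(models, attrs, -6, keep = 4)
  expect_gte(res6$median, min(probs))
  expect_lte(res6$median, max(probs))
  expect_equal(ensemble_predict(models, attrs, -6, keep = 6)$median,
               median(probs))
  expect_error(ensemble_predict(models, attrs, -6, keep = 10), "keep")
})
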