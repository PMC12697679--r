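# One-dimensional K-component Gaussian mixtures fitted by seeded
# expectation-maximization.  Per calibration node, one mixture is fitted per
# class on a fixed-size sample; the fitted mixtures are generative, so
# calibration histograms can be built from unlimited synthetic draws without
# exposing the mapping to individual labeled examples.

#' Construct Gaussian mixture parameters
#'
#' @param weights mixture weights (simplex vector of length K).
#' @param means component means.
#' @param variances component variances (> 0).
#' @return object of class \code{gmm_params}.
#' @export
gmm_params <- function(weights, means, variances) {
  stopifnot(length(weights) == length(means),
            length(means) == length(variances))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(variances <= 0)) stop("variances must be positive")
  ord <- order(means)
  structure(list(weights = weights[ord], means = means[ord],
                 variances = variances[ord]),
            class = "gmm_params")
}

#' @export
print.gmm_params <- function(x, ...) {
  cat("Gaussian mixture (", length(x$means), " components):\n", sep = "")
  for (k in seq_along(x$means)) {
    cat(sprintf("  w=%.3f  mean=%.3f  sd=%.3f\n",
                x$weights[k], x$means[k], sqrt(x$variances[k])))
  }
  invisible(x)
}

#' Fit a 1-D Gaussian mixture by expectation-maximization
#'
#' K-means initialization (single start, seeded), then EM with a relative
#' log-likelihood tolerance and a variance floor.  Deterministic given the
#' seed.  A degenerate sample (all values identical) falls back to a
#' near-point mixture with a warning.
#'
#' @param x numeric sample.
#' @param K number of components (default 2).
#' @param seed RNG seed for the k-means initialization.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-3).
#' @param var_floor lower bound on component variances (default 1e-6).
#' @return a \code{gmm_params} object with components sorted by mean.
#' @export
fit_gmm1d <- function(x, K = 2, seed = 1, max_iter = 100, tol = 1e-3,
                      var_floor = 1e-6) {
  n <- length(x)
  if (n < K) stop("need at least K observations")
  if (length(unique(x)) == 1) {
    warning("degenerate sample (all values identical); near-point mixture")
    return(gmm_params(rep(1 / K, K), rep(x[1], K), rep(var_floor, K)))
  }
  set.seed(seed)
  km <- tryCatch(stats::kmeans(x, centers = K, nstart = 1),
                 error = function(e) NULL)
  if (is.null(km)) {
    mu <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
    w <- rep(1 / K, K)
    v <- rep(stats::var(x), K)
  } else {
    mu <- as.numeric(km$centers)
    w <- as.numeric(km$size) / n
    v <- vapply(seq_len(K), function(k) {
      xs <- x[km$cluster == k]
      if (length(xs) > 1) stats::var(xs) else stats::var(x)
    }, numeric(1))
  }
  v <- pmax(v, var_floor)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) {
      w[k] * stats::dnorm(x, mu[k], sqrt(v[k]))
    }, numeric(n))
    if (n == 1) dens <- matrix(dens, nrow = 1)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(vapply(seq_len(K), function(k) {
      sum(resp[, k] * (x - mu[k])^2) / nk[k]
    }, numeric(1)), var_floor)
  }
  gmm_params(w, mu, v)
}

#' Sample from a fitted Gaussian mixture
#' @param gmm a \code{gmm_params} object.
#' @param n number of draws.
#' @return numeric vector of length \code{n}.
#' @export
rgmm <- function(gmm, n) {
  if (n == 0) return(numeric(0))
  comp <- sample.int(length(gmm$weights), n, replace = TRUE,
                     prob = gmm$weights)
  stats::rnorm(n, gmm$means[comp], sqrt(gmm$variances[comp]))
}

#' Gaussian mixture density
#' @param gmm a \code{gmm_params} object.
#' @param x evaluation points.
#' @return numeric density values.
#' @export
dgmm <- function(gmm, x) {
  rowSums(vapply(seq_along(gmm$weights), function(k) {
    gmm$weights[k] * stats::dnorm(x, gmm$means[k], sqrt(gmm$variances[k]))
  }, numeric(length(x))))
}

#' BIC diagnostic across component counts
#'
#' Fits mixtures with 1..\code{max_K} components and reports the Bayesian
#' Information Criterion for each, as a diagnostic for where the BIC curve
#' plateaus.  The package default stays at K = 2.
#'
#' @param x numeric sample.
#' @param max_K largest component count (default 5).
#' @param seed RNG seed.
#' @return data frame with columns \code{K} and \code{bic}.
#' @export
gmm_bic_profile <- function(x, max_K = 5, seed = 1) {
  n <- length(x)
  rows <- lapply(seq_len(max_K), function(K) {
    g <- fit_gmm1d(x, K = K, seed = seed)
    ll <- sum(log(pmax(dgmm(g, x), .Machine$double.xmin)))
    npar <- 3 * K - 1
    data.frame(K = K, bic = -2 * ll + npar * log(n))
  })
  do.call(rbind, rows)
}
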