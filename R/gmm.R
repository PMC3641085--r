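# Diagonal-covariance Gaussian mixture model fitted by EM with k-means
# initialisation. This is the likelihood model of both detector streams.

#' Fit a diagonal-covariance Gaussian mixture model
#'
#' Expectation-maximisation with k-means initialisation (seeded), diagonal
#' covariances with a variance floor, stopping when the relative improvement
#' of the training log-likelihood falls below `tol` or after `max_iter`
#' iterations. The per-iteration log-likelihood trace is stored and checked to
#' be non-decreasing (EM guarantee); a violation beyond numerical noise is an
#' error.
#'
#' @param x Numeric matrix (observations x dimensions) of finite values.
#' @param M Number of mixture components (>= 1, <= `nrow(x)`).
#' @param seed Integer seed for the k-means initialisation.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood improvement stopping threshold.
#' @param var_floor Lower bound applied to every variance.
#' @return Object of class `gmm`: `weights`, `means` (M x d), `vars` (M x d),
#'   `M`, `d`, `loglik` (final average per-observation log-likelihood) and
#'   `loglik_trace`.
#' @examples
#' x <- matrix(rnorm(200), ncol = 2)
#' fit_gmm(x, M = 1, seed = 1)
#' @export
fit_gmm <- function(x, M, seed = 1L, max_iter = 200L, tol = 1e-4,
                    var_floor = 1e-6) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("`x` must be finite")
  n <- nrow(x); d <- ncol(x)
  if (M < 1) abort("`M` must be >= 1")
  if (n < M) abort("need at least M training vectors")

  km_centers <- if (M == 1) {
    matrix(colMeans(x), 1)
  } else {
    with_seed(seed, stats::kmeans(x, centers = M, nstart = 3,
                                  iter.max = 50)$centers)
  }
  means <- matrix(km_centers, M, d)
  gvar <- pmax(apply(x, 2, stats::var), var_floor)
  vars <- matrix(rep(gvar, each = M), M, d)
  weights <- rep(1 / M, M)

  trace <- numeric(0)
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    lp <- gmm_component_logdens(x, means, vars) +
      matrix(log(weights), n, M, byrow = TRUE)
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (length(trace) > 1 && ll < prev_ll - 1e-6 * (abs(prev_ll) + 1)) {
      abort("EM log-likelihood decreased; this should be impossible")
    }
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    weights <- nk / n
    means <- (t(resp) %*% x) / nk
    ex2 <- (t(resp) %*% (x^2)) / nk
    vars <- pmax(ex2 - means^2, var_floor)
    if (is.finite(prev_ll) &&
        (ll - prev_ll) < tol * abs(prev_ll)) break
    prev_ll <- ll
  }

  structure(
    list(weights = weights, means = means, vars = vars, M = M, d = d,
         n_train = n, loglik = ll / n, loglik_trace = trace,
         iterations = length(trace), seed = seed),
    class = "gmm"
  )
}

# n x M matrix of per-component Gaussian log-densities (diagonal covariance).
gmm_component_logdens <- function(x, means, vars) {
  n <- nrow(x); M <- nrow(means)
  out <- matrix(0, n, M)
  for (m in seq_len(M)) {
    z <- sweep(x, 2, means[m, ])
    out[, m] <- -0.5 * (ncol(x) * log(2 * pi) + sum(log(vars[m, ])) +
                          rowSums(sweep(z^2, 2, vars[m, ], "/")))
  }
  out
}

#' Log-density of observations under a fitted GMM
#'
#' @param model A [fit_gmm()] fit.
#' @param x Matrix (or vector, taken as one observation) in the model's
#'   feature space.
#' @return Numeric vector of per-observation mixture log-densities.
#' @export
gmm_logdens <- function(model, x) {
  stopifnot(inherits(model, "gmm"))
  if (is.null(dim(x))) x <- matrix(x, 1)
  x <- as.matrix(x)
  if (ncol(x) != model$d) {
    abort(sprintf("feature dimension %d does not match model dimension %d",
                  ncol(x), model$d))
  }
  lp <- gmm_component_logdens(x, model$means, model$vars) +
    matrix(log(model$weights), nrow(x), model$M, byrow = TRUE)
  mx <- apply(lp, 1, max)
  mx + log(rowSums(exp(lp - mx)))
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("<gmm> M=%d  d=%d  n=%d  avg logLik=%.3f  (%d EM iterations)\n",
              x$M, x$d, x$n_train, x$loglik, x$iterations))
  invisible(x)
}
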