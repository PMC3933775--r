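# Gaussian mixture modeling of instantaneous voltage topographies.
# The mixture lives in channel space (one dimension per electrode) and is
# fitted by EM on the pooled topographies of all latencies and trials of one
# condition. Template maps = component means.

# Pool an epoch set into an (trials*samples) x channels matrix of
# average-referenced topographies. Row order: sample-fastest within trial,
# i.e. row (tr-1)*n_samples + s is trial tr at sample s.
pool_topographies <- function(epochs) {
  x <- matrix(aperm(epochs$data, c(2, 3, 1)), nrow = n_channels(epochs))
  average_reference(t(x))
}

# Subtract the spatial mean of each row (topography).
average_reference <- function(x) x - rowMeans(x)

# Log-density of each row of X under each mixture component (+ log weight),
# via one BLAS product per term; va floored by the caller.
gmm_component_logdens <- function(X, X2, mu, va, w) {
  A <- X2 %*% t(0.5 / va)
  B <- X %*% t(mu / va)
  cst <- -0.5 * rowSums(mu^2 / va) - 0.5 * rowSums(log(2 * pi * va)) + log(w)
  sweep(B - A, 2, cst, "+")
}

em_diag_gmm <- function(X, X2, mu, va, w, floor_va, max_iter, tol) {
  n <- nrow(X)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lg <- gmm_component_logdens(X, X2, mu, va, w)
    rls <- row_logsumexp(lg)
    ll <- sum(rls)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lg - rls)
    nk <- colSums(resp)
    if (any(nk < 1e-8 * n)) {
      return(list(mu = mu, va = va, w = w, loglik = ll, ll_trace = ll_trace,
                  degenerate = TRUE, n_iter = it))
    }
    w <- nk / n
    mu <- crossprod(resp, X) / nk
    va <- pmax(crossprod(resp, X2) / nk - mu^2, floor_va)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(mu = mu, va = va, w = w, loglik = ll, ll_trace = ll_trace,
       degenerate = FALSE, n_iter = length(ll_trace))
}

# EM fit of a K-component diagonal-covariance Gaussian mixture.
# k-means initialization on a subsample, `n_restarts` short restarts, best
# continued to convergence. Deterministic under the ambient RNG state.
fit_gmm <- function(X, K, n_restarts = 5, max_iter = 300, tol = 1e-4,
                    cov_floor_frac = 1e-6, restart_iter = 20) {
  n <- nrow(X); d <- ncol(X)
  if (n < K) stop("fewer pooled topographies than mixture components", call. = FALSE)
  pooled_va <- mean(apply(X, 2, var))
  floor_va <- max(cov_floor_frac * pooled_va, .Machine$double.eps)
  X2 <- X^2

  if (K == 1) {
    mu <- matrix(colMeans(X), 1)
    va <- matrix(pmax(colMeans(X2) - mu[1, ]^2, floor_va), 1)
    lg <- gmm_component_logdens(X, X2, mu, va, 1)
    return(list(K = 1L, means = mu, vars = va, weights = 1,
                loglik = sum(lg), ll_trace = sum(lg), n_iter = 1L))
  }

  best <- NULL
  failures <- 0L
  attempt <- 0L
  while (is.null(best) || attempt < n_restarts) {
    attempt <- attempt + 1L
    if (failures >= 5L) {
      stop(sprintf("GMM fit degenerate after 5 restarts (K = %d)", K),
           call. = FALSE)
    }
    sub <- if (n > 3000) X[sample.int(n, 3000), , drop = FALSE] else X
    km <- suppressWarnings(kmeans(sub, K, nstart = 1, iter.max = 20))
    mu0 <- km$centers
    va0 <- matrix(pmax(apply(X, 2, var), floor_va), K, d, byrow = TRUE)
    w0 <- rep(1 / K, K)
    fit <- em_diag_gmm(X, X2, mu0, va0, w0, floor_va, restart_iter, tol)
    if (fit$degenerate) {
      failures <- failures + 1L
      attempt <- attempt - 1L
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  fin <- em_diag_gmm(X, X2, best$mu, best$va, best$w, floor_va, max_iter, tol)
  if (fin$degenerate) fin <- best
  list(K = as.integer(K), means = unname(fin$mu), vars = unname(fin$va),
       weights = unname(fin$w),
       loglik = fin$loglik,
       ll_trace = c(best$ll_trace, fin$ll_trace),
       n_iter = best$n_iter + fin$n_iter)
}

#' Fit a Gaussian mixture to one condition's single-trial topographies
#'
#' Pools the instantaneous voltage topographies of all latencies and trials
#' of `epochs`, average-references them, and fits a `K`-component Gaussian
#' mixture (diagonal covariances) by EM with k-means initialization,
#' restarts and a covariance floor. The component means are the condition's
#' template maps.
#'
#' @param epochs An [epoch_set()] containing a single condition's trials.
#' @param K Number of mixture components (template maps).
#' @param seed Integer seed (k-means initialization and restarts); `NULL`
#'   uses the ambient RNG state.
#' @param n_restarts Number of short restarts; the best continues to
#'   convergence.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param cov_floor_frac Covariance floor as a fraction of the pooled
#'   per-channel variance.
#' @return An object of class `gmm_model` with `means` (`K x channels`
#'   template maps), `vars`, `weights`, `loglik`, the log-likelihood trace
#'   `ll_trace`, and `condition`.
#' @export
fit_condition_gmm <- function(epochs, K, seed = NULL, n_restarts = 5,
                              max_iter = 300, tol = 1e-4,
                              cov_floor_frac = 1e-6) {
  stopifnot(inherits(epochs, "epoch_set"), K >= 1)
  labs <- unique(epochs$labels)
  if (length(labs) > 1) {
    stop("`epochs` must contain a single condition; subset first", call. = FALSE)
  }
  X <- pool_topographies(epochs)
  if (nrow(X) < 10 * K * ncol(X)) {
    warning("fewer than 10 * K * n_channels pooled topographies; fit may be unstable",
            call. = FALSE)
  }
  fit <- with_seed(seed, fit_gmm(X, K, n_restarts = n_restarts,
                                 max_iter = max_iter, tol = tol,
                                 cov_floor_frac = cov_floor_frac))
  structure(c(fit, list(condition = labs, channels = epochs$channels)),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("gmm_model: K = %d template maps over %d channels (condition \"%s\"), loglik = %.4g after %d EM iterations\n",
              x$K, ncol(x$means), x$condition %||% "?", x$loglik, x$n_iter))
  invisible(x)
}

# Total log-density of topography rows under a fitted mixture.
gmm_logdens <- function(gmm, X) {
  row_logsumexp(gmm_component_logdens(X, X^2, gmm$means, gmm$vars,
                                      gmm$weights))
}
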