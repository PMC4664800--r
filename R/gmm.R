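#' Diagonal-covariance Gaussian mixture universal background model
#'
#' Container for a GMM-UBM: mixture weights on the simplex, component
#' means and per-dimension (diagonal) variances.
#'
#' @param weights Numeric vector of C mixture weights (must sum to 1).
#' @param means C x D matrix of component means.
#' @param covariances C x D matrix of positive diagonal variances.
#' @return A `ubm_model` list.
#' @export
ubm_model <- function(weights, means, covariances) {
  means <- as.matrix(means); covariances <- as.matrix(covariances)
  if (length(weights) != nrow(means) || !all(dim(means) == dim(covariances))) {
    abort("Inconsistent UBM dimensions.")
  }
  if (abs(sum(weights) - 1) > 1e-10) {
    abort("UBM weights must sum to 1 (within 1e-10).")
  }
  if (any(covariances <= 0)) {
    abort("UBM variances must be strictly positive.")
  }
  structure(list(weights = as.numeric(weights), means = means,
                 covariances = covariances),
            class = "ubm_model")
}

#' @export
print.ubm_model <- function(x, ...) {
  cat(sprintf("<ubm_model> %d components x %d dims\n",
              nrow(x$means), ncol(x$means)))
  invisible(x)
}

# Per-frame, per-component Gaussian log-densities (n x C), diagonal
# covariances, computed with three matrix products.
gmm_log_densities <- function(X, ubm) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(ubm$means)) {
    abort(sprintf("Feature dimension %d does not match UBM dimension %d.",
                  ncol(X), ncol(ubm$means)))
  }
  D <- ncol(X)
  inv_var <- 1 / ubm$covariances
  logdet <- rowSums(log(ubm$covariances))
  quad <- X^2 %*% t(inv_var) - 2 * (X %*% t(ubm$means * inv_var))
  quad <- sweep(quad, 2L, rowSums(ubm$means^2 * inv_var), "+")
  sweep(-0.5 * quad, 2L, 0.5 * (D * log(2 * pi) + logdet), "-")
}

# Posterior responsibilities and per-frame log-likelihood under the UBM.
gmm_posteriors <- function(X, ubm) {
  ld <- sweep(gmm_log_densities(X, ubm), 2L, log(ubm$weights), "+")
  m <- apply(ld, 1L, max)
  lse <- m + log(rowSums(exp(ld - m)))
  list(gamma = exp(ld - lse), loglik = sum(lse))
}

#' Total log-likelihood of feature frames under a UBM
#'
#' @param X Feature matrix (frames x dims) or list of such matrices.
#' @param ubm A [ubm_model()].
#' @return Scalar total log-likelihood.
#' @export
gmm_log_likelihood <- function(X, ubm) {
  if (is.list(X)) X <- do.call(rbind, X)
  gmm_posteriors(X, ubm)$loglik
}

#' Train a diagonal-covariance GMM universal background model
#'
#' Fits the UBM by expectation-maximization from a k-means initialization,
#' with per-dimension variance flooring (a fraction of the global variance)
#' to prevent component collapse.  The per-iteration total log-likelihood
#' is recorded and is non-decreasing up to floating tolerance.
#'
#' @param features Feature matrix (frames x dims) or list of matrices
#'   (pooled for training).
#' @param n_components Number of mixture components C.
#' @param n_iter EM iterations (default 10).
#' @param seed Integer seed for the initialization.
#' @param var_floor_frac Variance floor as a fraction of the global
#'   per-dimension variance (default 1e-3).
#' @return A [ubm_model()] with attribute `loglik_trace` (one value per EM
#'   iteration, computed before each M-step) and `seed`.
#' @export
train_ubm <- function(features, n_components, n_iter = 10L, seed = 1L,
                      var_floor_frac = 1e-3) {
  X <- if (is.list(features)) do.call(rbind, features) else as.matrix(features)
  n <- nrow(X); D <- ncol(X); C <- as.integer(n_components)
  if (C < 1L) abort("`n_components` must be >= 1.")
  if (n < C) {
    abort(sprintf("Cannot train %d components from %d frames.", C, n))
  }
  global_var <- apply(X, 2L, stats::var)
  floor_vec <- pmax(var_floor_frac * global_var, .Machine$double.eps)

  init <- with_local_seed(seed, {
    if (C == 1L) {
      list(means = matrix(colMeans(X), 1L, D),
           cluster = rep(1L, n))
    } else {
      km <- kmeans(X, centers = C, iter.max = 20L, nstart = 1L)
      list(means = km$centers, cluster = km$cluster)
    }
  })
  means <- init$means
  covs <- matrix(0, C, D)
  weights <- numeric(C)
  for (c in seq_len(C)) {
    idx <- init$cluster == c
    weights[c] <- mean(idx)
    Xc <- X[idx, , drop = FALSE]
    covs[c, ] <- if (nrow(Xc) > 1L) apply(Xc, 2L, stats::var) else global_var
  }
  covs <- pmax(covs, rep(floor_vec, each = C))
  weights <- pmax(weights, 1e-8); weights <- weights / sum(weights)
  ubm <- ubm_model(weights, means, covs)

  trace <- numeric(n_iter)
  X2 <- X^2
  for (it in seq_len(n_iter)) {
    post <- gmm_posteriors(X, ubm)
    trace[it] <- post$loglik
    Nk <- colSums(post$gamma)
    Nk_safe <- pmax(Nk, .Machine$double.eps)
    means <- (t(post$gamma) %*% X) / Nk_safe
    covs <- (t(post$gamma) %*% X2) / Nk_safe - means^2
    covs <- pmax(covs, rep(floor_vec, each = C))
    weights <- Nk / n
    weights <- pmax(weights, 1e-10); weights <- weights / sum(weights)
    ubm <- ubm_model(weights, means, covs)
  }
  attr(ubm, "loglik_trace") <- trace
  attr(ubm, "seed") <- seed
  ubm
}

#' Zeroth- and first-order Baum-Welch statistics of an utterance
#'
#' Per-frame component posteriors under the UBM are summed into the
#' occupancy counts `N[c]` and the posterior-weighted, UBM-mean-centered
#' first-order sums `F[c, ]`.  The occupancies sum to the number of frames.
#'
#' @param utterance Feature matrix (frames x dims).
#' @param ubm A [ubm_model()].
#' @return A `bw_stats` list with `N` (length C) and `F` (C x D).
#' @export
accumulate_bw_stats <- function(utterance, ubm) {
  X <- as.matrix(utterance)
  if (!all(is.finite(X))) abort("Non-finite feature frames.")
  post <- gmm_posteriors(X, ubm)
  N <- colSums(post$gamma)
  F_raw <- t(post$gamma) %*% X
  F_centered <- F_raw - N * ubm$means
  structure(list(N = N, F = F_centered, n_frames = nrow(X)),
            class = "bw_stats")
}

#' MAP-adapted mean supervector of an utterance
#'
#' Mean-only maximum a posteriori adaptation of the UBM towards the
#' utterance: `adapted_c = mu_c + alpha_c * F_c / N_c` with
#' `alpha_c = N_c / (N_c + r)`, where `r` is the relevance factor.  All
#' adapted component means are stacked (component-major) into a single
#' vector of length C * D.  Components never visited (`N_c = 0`) keep the
#' UBM mean.
#'
#' @param stats A `bw_stats` object from [accumulate_bw_stats()].
#' @param ubm A [ubm_model()].
#' @param relevance Relevance factor `r` (> 0, default 16).
#' @return Numeric vector of length C * D.
#' @export
map_adapt_supervector <- function(stats, ubm, relevance = 16) {
  if (relevance <= 0) abort("`relevance` must be > 0.")
  N <- stats$N
  alpha <- N / (N + relevance)
  ratio <- stats$F / pmax(N, .Machine$double.eps)
  ratio[N <= 0, ] <- 0
  adapted <- ubm$means + alpha * ratio
  as.numeric(t(adapted))  # component-major stacking, matching T's row order
}
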