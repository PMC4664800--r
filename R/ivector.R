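#' Total-variability model
#'
#' Container for the factor-analysis model of the GMM mean supervector,
#' `m = mu + T w`: a low-rank matrix `T` spanning the total-variability
#' subspace, tied to the UBM whose Baum-Welch statistics it consumes.  The
#' latent `w` has a standard-normal prior; the posterior mean of `w` given
#' an utterance's statistics is its i-vector.
#'
#' @param T_matrix `(C * D) x R` matrix (component-major row order: rows
#'   `((c-1)*D + 1):(c*D)` belong to component c).
#' @param ubm The [ubm_model()] the statistics are computed against.
#' @param objective_trace Optional per-iteration training objective.
#' @param seed Optional training seed.
#' @return A `tv_model` list.
#' @export
tv_model <- function(T_matrix, ubm, objective_trace = numeric(), seed = NA_integer_) {
  T_matrix <- as.matrix(T_matrix)
  C <- nrow(ubm$means); D <- ncol(ubm$means)
  if (nrow(T_matrix) != C * D) {
    abort("T must have n_components * feature_dim rows.")
  }
  if (ncol(T_matrix) >= C * D) {
    abort("The i-vector rank must be smaller than the supervector dimension.")
  }
  if (!all(is.finite(T_matrix))) abort("T must be finite.")
  structure(list(T = T_matrix, ubm = ubm, rank = ncol(T_matrix),
                 objective_trace = objective_trace, seed = seed),
            class = "tv_model")
}

#' @export
print.tv_model <- function(x, ...) {
  cat(sprintf("<tv_model> rank %d over %d x %d UBM (%d EM iterations)\n",
              x$rank, nrow(x$ubm$means), ncol(x$ubm$means),
              length(x$objective_trace)))
  invisible(x)
}

# Stack per-component centered stats F (C x D) into the supervector layout
# used by T (component-major).
stack_stats <- function(F_mat) as.numeric(t(F_mat))

# Build the U x C occupancy matrix and U x (C*D) stacked first-order matrix
# from a list of bw_stats.
collate_stats <- function(stats_list) {
  Nmat <- do.call(rbind, lapply(stats_list, `[[`, "N"))
  Fmat <- do.call(rbind, lapply(stats_list, function(s) stack_stats(s$F)))
  list(N = Nmat, F = Fmat)
}

# Shared E-step machinery: for each utterance, the posterior precision
# L = I + T' Sigma^-1 N T, the projected statistic b = T' Sigma^-1 F, and
# the posterior mean w = L^-1 b.  Returns per-utterance quantities.
ivector_posteriors <- function(Nmat, Fmat, T_matrix, ubm, want_cov = FALSE) {
  C <- nrow(ubm$means); D <- ncol(ubm$means); R <- ncol(T_matrix)
  U <- nrow(Nmat)
  inv_sigma <- as.numeric(t(1 / ubm$covariances))   # length C*D, comp-major
  TS <- T_matrix * inv_sigma                        # Sigma^-1 T (rowwise)
  # Per-component R x R Gram blocks M_c = T_c' Sigma_c^-1 T_c
  Mmat <- matrix(0, C, R * R)
  for (c in seq_len(C)) {
    rows <- ((c - 1L) * D + 1L):(c * D)
    Mmat[c, ] <- as.numeric(crossprod(T_matrix[rows, , drop = FALSE],
                                      TS[rows, , drop = FALSE]))
  }
  Lflat <- Nmat %*% Mmat                            # U x R^2
  Ball <- Fmat %*% TS                               # U x R  (b_u)
  Wbar <- matrix(0, U, R)
  logdetL <- numeric(U)
  quad <- numeric(U)
  Covs <- if (want_cov) vector("list", U) else NULL
  I_R <- diag(R)
  for (u in seq_len(U)) {
    L <- I_R + matrix(Lflat[u, ], R, R)
    ch <- chol(L)
    w <- backsolve(ch, forwardsolve(t(ch), Ball[u, ]))
    Wbar[u, ] <- w
    logdetL[u] <- 2 * sum(log(diag(ch)))
    quad[u] <- sum(Ball[u, ] * w)
    if (want_cov) Covs[[u]] <- chol2inv(ch)
  }
  list(Wbar = Wbar, logdetL = logdetL, quad = quad, Covs = Covs,
       TS = TS, Ball = Ball)
}

#' Extract the i-vector of one utterance
#'
#' The exact closed-form posterior mean of the total factors given the
#' utterance's Baum-Welch statistics:
#' `w = (I + T' Sigma^-1 N T)^-1 T' Sigma^-1 F`, with `N` the diagonal
#' expansion of the occupancies and `F` the stacked centered first-order
#' statistics.  Zero first-order statistics or a null subspace give
#' exactly `w = 0`.
#'
#' @param stats A `bw_stats` object from [accumulate_bw_stats()].
#' @param model A [tv_model()].
#' @return Numeric i-vector of length `model$rank`.
#' @export
extract_ivector <- function(stats, model) {
  if (!all(is.finite(stats$N)) || !all(is.finite(stats$F))) {
    abort("Non-finite Baum-Welch statistics.")
  }
  if (ncol(stats$F) != ncol(model$ubm$means) ||
        length(stats$N) != nrow(model$ubm$means)) {
    abort("Statistics dimensions do not match the model's UBM.")
  }
  post <- ivector_posteriors(matrix(stats$N, 1L), matrix(stack_stats(stats$F), 1L),
                             model$T, model$ubm)
  as.numeric(post$Wbar[1L, ])
}

#' Extract i-vectors for a collection of utterances
#'
#' @param stats_list List of `bw_stats`.
#' @param model A [tv_model()].
#' @return A matrix (utterances x rank); row names follow the list names.
#' @export
extract_ivectors <- function(stats_list, model) {
  co <- collate_stats(stats_list)
  post <- ivector_posteriors(co$N, co$F, model$T, model$ubm)
  W <- post$Wbar
  rownames(W) <- names(stats_list)
  W
}

#' Train the total-variability matrix by EM
#'
#' Maximum-likelihood estimation of the low-rank matrix `T` in the
#' supervector factor model from a collection of Baum-Welch statistics.
#' The E-step computes each utterance's posterior over `w` (precision
#' `L = I + T' Sigma^-1 N T`, mean `L^-1 T' Sigma^-1 F`); the M-step solves
#' one `R x R` linear system per mixture component from the accumulated
#' `E[w]` and `E[w w']`.  `T` is initialized with seeded Gaussian noise.
#' The marginal log-likelihood of the statistics (up to terms constant in
#' `T`) is recorded per iteration and is non-decreasing.
#'
#' @param stats_list List of `bw_stats` (at least `rank` utterances).
#' @param ubm The [ubm_model()] the statistics were computed against.
#' @param rank The i-vector dimension R (e.g. 400, 300, 200, 100, 50, 30).
#' @param n_iter EM iterations (default 10).
#' @param seed Integer seed for the initialization.
#' @return A [tv_model()] with per-iteration `objective_trace`.
#' @export
train_total_variability <- function(stats_list, ubm, rank, n_iter = 10L,
                                    seed = 1L) {
  C <- nrow(ubm$means); D <- ncol(ubm$means)
  rank <- as.integer(rank)
  if (rank >= C * D) abort("`rank` must be smaller than C * D.")
  if (length(stats_list) < rank) {
    abort(sprintf("Need at least %d utterances to train rank %d.",
                  rank, length(stats_list)))
  }
  co <- collate_stats(stats_list)
  U <- nrow(co$N)
  T_matrix <- with_local_seed(seed, {
    matrix(rnorm(C * D * rank, sd = 0.1), C * D, rank)
  })
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    post <- ivector_posteriors(co$N, co$F, T_matrix, ubm, want_cov = TRUE)
    trace[it] <- 0.5 * sum(post$quad - post$logdetL)
    # Accumulate E[w w'] per utterance, then per-component normal equations
    EwwMat <- matrix(0, U, rank * rank)
    for (u in seq_len(U)) {
      EwwMat[u, ] <- as.numeric(post$Covs[[u]] +
                                  tcrossprod(post$Wbar[u, ]))
    }
    A <- crossprod(co$N, EwwMat)                 # C x R^2
    T_new <- matrix(0, C * D, rank)
    for (c in seq_len(C)) {
      rows <- ((c - 1L) * D + 1L):(c * D)
      Cc <- crossprod(co$F[, rows, drop = FALSE], post$Wbar)   # D x R
      Ac <- matrix(A[c, ], rank, rank)
      T_c <- tryCatch(t(solve(Ac, t(Cc))), error = function(e) {
        abort(sprintf("Singular accumulator for component %d: %s",
                      c, conditionMessage(e)))
      })
      T_new[rows, ] <- T_c
    }
    T_matrix <- T_new
  }
  tv_model(T_matrix, ubm, objective_trace = trace, seed = seed)
}

#' Largest principal angle between two subspaces
#'
#' The largest principal angle (degrees) between the column spans of two
#' matrices, via the singular values of the product of their orthonormal
#' bases.  Used to check recovery of a known total-variability subspace.
#'
#' @param A,B Matrices with the same number of rows.
#' @return Angle in degrees in \[0, 90\].
#' @export
principal_angle <- function(A, B) {
  Qa <- qr.Q(qr(as.matrix(A)))
  Qb <- qr.Q(qr(as.matrix(B)))
  s <- svd(crossprod(Qa, Qb))$d
  s <- pmin(pmax(s, -1), 1)
  max(acos(s)) * 180 / pi
}

#' Orthogonal alignment of estimated latent vectors to a reference
#'
#' Solves the orthogonal Procrustes problem aligning the rows of `W_est`
#' to `W_ref`, then reports the per-column Pearson correlation after
#' alignment.  i-vectors are identifiable only up to rotation of the
#' subspace, so planted-latent recovery is judged after alignment.
#'
#' @param W_est,W_ref Matrices (subjects x rank) with matching dimensions.
#' @return Named list: `rotation`, `aligned`, `correlations`.
#' @export
procrustes_align <- function(W_est, W_ref) {
  W_est <- as.matrix(W_est); W_ref <- as.matrix(W_ref)
  stopifnot(all(dim(W_est) == dim(W_ref)))
  s <- svd(crossprod(W_est, W_ref))
  rot <- s$u %*% t(s$v)
  aligned <- W_est %*% rot
  cors <- vapply(seq_len(ncol(W_ref)), function(j) {
    cor(aligned[, j], W_ref[, j])
  }, numeric(1))
  list(rotation = rot, aligned = aligned, correlations = cors)
}
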