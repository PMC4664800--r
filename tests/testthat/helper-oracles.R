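# Independent oracles and small fixture builders shared across tests.

# Monte-Carlo rasterization area oracle: fraction of uniform samples in the
# polygon's bounding box that fall inside, by even-odd ray crossing.
# Independent of the shoelace formula under test.
mc_polygon_area <- function(vertices, n_samples = 8e5, seed = 1) {
  v <- as.matrix(vertices)
  nv <- nrow(v)
  withr::with_seed(seed, {
    px <- runif(n_samples, min(v[, 1]), max(v[, 1]))
    py <- runif(n_samples, min(v[, 2]), max(v[, 2]))
    inside <- rep(FALSE, n_samples)
    j <- nv
    for (i in seq_len(nv)) {
      xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
    box <- (max(v[, 1]) - min(v[, 1])) * (max(v[, 2]) - min(v[, 2]))
    box * mean(inside)
  })
}

# Random star-shaped (hence simple) polygon around the origin.
random_simple_polygon <- function(n_vertices = 10) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 0.5, 1.5)
  cbind(r * cos(ang), r * sin(ang))
}

# Angle at `b` between rays b->a and b->c via arccos of the normalized dot
# product (the documented contract, independent of the atan2 route).
acos_angle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

# Replace the coordinates of a landmark set, keeping the view.
with_coords <- function(landmarks, coords) {
  landmark_set(coords, landmark_view(landmarks))
}

# Rigid/similarity transform of an n x 2 coordinate matrix.
similarity_transform <- function(coords, angle = 0, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * coords %*% t(R), 2, shift, "+")
}

# Profile landmark set whose cervicomental contour is replaced by the rows
# of `contour` (first row = point 11, last = point 23).
profile_with_contour <- function(contour) {
  tpl <- template_landmarks("profile")
  xy <- cbind(tpl$x, tpl$y)
  xy[c(11, 12, 20, 21, 22, 23), ] <- contour
  with_coords(tpl, xy)
}

# Hand-built two-component, two-dimensional UBM for toy statistics.
toy_ubm <- function() {
  ubm_model(weights = c(0.4, 0.6),
            means = matrix(c(0, 0, 3, 3), 2, 2, byrow = TRUE),
            covariances = matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE))
}

# Small cohort configuration with a toy acoustic scale, for fast tests.
small_cohort_config <- function(n_subjects = 40, seed = 3, ...) {
  cohort_config(n_subjects = n_subjects, seed = seed,
                acoustic_params = list(n_components = 8L, feature_dim = 10L,
                                       true_rank = 3L,
                                       frames_per_utterance = 200L,
                                       latent_ahi_correlation = 0.2),
                ...)
}

# Records with a planted linear AHI signal (optionally noisy).
planted_records <- function(n = 30, noise = 0, seed = 1, p = 2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- 20 + 10 * X[, 1] + 5 * X[, min(2, p)] + rnorm(n, sd = noise)
    out <- tibble::as_tibble(as.data.frame(X))
    names(out) <- paste0("f", seq_len(p))
    out$subject_id <- sprintf("P%03d", seq_len(n))
    out$ahi <- y
    out
  })
}

# Regressor stub that always predicts the training mean.
mean_stub_regressor <- function() {
  list(fit = function(X, y, C, epsilon) list(mu = mean(y)),
       predict = function(fit, X) rep(fit$mu, nrow(X)))
}

fast_grid <- function() {
  svr_grid(C_values = c(0.5, 4), epsilon_values = c(0.25, 1))
}
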