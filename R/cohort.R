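#' Configuration for the synthetic OSA cohort generator
#'
#' Defines the study conditions emulated by the generator: clinical
#' marginals matching the descriptive statistics of the 285-subject male
#' clinical population the analysis targets (AHI mean 21.7, SD 17.4, range
#' 0-84.4 events/hour; weight, height, age and cervical perimeter
#' likewise), planted correlations between each craniofacial measurement
#' and AHI, and a feature-level acoustic simulation in which GMM component
#' means are shifted along a known low-rank subspace by a per-subject
#' latent vector.
#'
#' @param n_subjects Number of subjects (default 285, the clinical cohort
#'   size).
#' @param seed Integer seed; the whole cohort is reproducible from
#'   (config, seed).
#' @param clinical_params Named list of `c(mean, sd, min, max)` vectors for
#'   `ahi`, `weight_kg`, `height_cm`, `bmi`, `age`, `cervical_cm`.  Values
#'   parameterize the parent normal of a truncated-normal draw.  BMI is not
#'   sampled: it is recomputed as weight / (height in m)^2; its entry is
#'   kept as the reference marginal used for standardization.
#' @param facial_effect_sizes Named vector of target Pearson correlations
#'   (in \[-1, 1\]) between each measurement and AHI: `cervicomental`
#'   (negative: the contour area shrinks as neck fat grows with severity),
#'   `face_width`, `trs_angle`.
#' @param ahi_link Coefficients of the monotone AHI link: standardized BMI,
#'   age and cervical perimeter are combined with these weights plus
#'   Gaussian noise (`noise_sd`), and the resulting latent is mapped through
#'   a Gaussian-copula quantile transform onto the configured truncated-
#'   normal AHI marginal.  Monotone in every driver, and the AHI marginal
#'   matches the configured parameters exactly in distribution.
#' @param acoustic_params List with `n_components`, `feature_dim`,
#'   `true_rank`, `frames_per_utterance`, `latent_ahi_correlation` (the
#'   tilt of the first latent coordinate towards standardized AHI).
#' @param noise_scales Named vector: `landmark_jitter_px` (isotropic
#'   landmark jitter, pixels) and `feature_noise` (multiplier on the
#'   acoustic within-component standard deviation).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 285L,
                          seed = 1123L,
                          clinical_params = list(
                            ahi = c(mean = 21.7, sd = 17.4, min = 0, max = 84.4),
                            weight_kg = c(mean = 92.5, sd = 16.9, min = 61, max = 162),
                            height_cm = c(mean = 175.7, sd = 7.1, min = 157, max = 197),
                            bmi = c(mean = 30.0, sd = 5.0, min = 20.0, max = 52.3),
                            age = c(mean = 48.4, sd = 12.0, min = 21, max = 85),
                            cervical_cm = c(mean = 42.3, sd = 3.1, min = 34, max = 52)
                          ),
                          facial_effect_sizes = c(cervicomental = -0.45,
                                                  face_width = 0.40,
                                                  trs_angle = 0.45),
                          ahi_link = c(bmi = 0.5, age = 0.25,
                                       cervical = 0.35, noise_sd = 0.88),
                          acoustic_params = list(n_components = 64L,
                                                 feature_dim = 40L,
                                                 true_rank = 30L,
                                                 frames_per_utterance = 300L,
                                                 latent_ahi_correlation = 0.2),
                          noise_scales = c(landmark_jitter_px = 1.0,
                                           feature_noise = 1.0)) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 0) {
    abort("`n_subjects` must be a single non-negative integer.")
  }
  needed <- c("ahi", "weight_kg", "height_cm", "bmi", "age", "cervical_cm")
  missing <- setdiff(needed, names(clinical_params))
  if (length(missing)) {
    abort(sprintf("`clinical_params` is missing: %s", paste(missing, collapse = ", ")))
  }
  for (v in names(clinical_params)) {
    p <- clinical_params[[v]]
    if (!all(c("mean", "sd", "min", "max") %in% names(p))) {
      abort(sprintf("clinical_params$%s must name mean, sd, min, max.", v))
    }
    if (p[["sd"]] <= 0) abort(sprintf("clinical_params$%s: sd must be > 0.", v))
    if (p[["min"]] >= p[["max"]]) {
      abort(sprintf("clinical_params$%s: min must be < max.", v))
    }
  }
  if (!all(c("cervicomental", "face_width", "trs_angle") %in%
             names(facial_effect_sizes))) {
    abort("`facial_effect_sizes` must name cervicomental, face_width, trs_angle.")
  }
  if (any(abs(facial_effect_sizes) > 1)) {
    abort("Facial effect sizes must lie in [-1, 1].")
  }
  if (abs(acoustic_params$latent_ahi_correlation) > 1) {
    abort("`latent_ahi_correlation` must lie in [-1, 1].")
  }
  if (acoustic_params$true_rank >=
        acoustic_params$n_components * acoustic_params$feature_dim) {
    abort("`true_rank` must be smaller than n_components * feature_dim.")
  }
  if (any(noise_scales < 0)) abort("`noise_scales` must be non-negative.")
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed),
                 clinical_params = clinical_params,
                 facial_effect_sizes = facial_effect_sizes,
                 ahi_link = ahi_link,
                 acoustic_params = acoustic_params,
                 noise_scales = noise_scales),
            class = "cohort_config")
}

# Truncated-normal draw by rejection against the parent normal.  The
# parameters are those of the parent, so truncation biases the realized
# moments slightly; at the range/SD ratios of the default clinical
# marginals the bias is small but accounted for analytically where tested.
rtruncnorm_reject <- function(n, mean, sd, min, max) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, mean, sd)
    out <- c(out, draw[draw >= min & draw <= max])
  }
  out[seq_len(n)]
}

# Analytic mean and sd of the truncated normal (oracle for generator tests).
truncnorm_moments <- function(mean, sd, min, max) {
  a <- (min - mean) / sd; b <- (max - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# Quantile function of the truncated normal (used by the AHI copula link).
qtruncnorm <- function(p, mean, sd, min, max) {
  p_lo <- pnorm(min, mean, sd); p_hi <- pnorm(max, mean, sd)
  qnorm(p_lo + p * (p_hi - p_lo), mean, sd)
}

#' Generate clinical variables and true AHI for a synthetic cohort
#'
#' Weight, height, age and cervical perimeter are drawn from truncated
#' normals with the configured marginals; BMI is recomputed as
#' weight / (height in m)^2.  AHI depends monotonically on standardized
#' BMI, age and cervical perimeter through a noisy latent mapped onto the
#' configured truncated-normal AHI marginal (Gaussian-copula link), so the
#' AHI marginal matches its configured parameters in distribution while
#' remaining positively linked to the anthropometric risk factors.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `subject_id`, `age`, `weight_kg`,
#'   `height_cm`, `bmi`, `cervical_cm`, `ahi`.
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  if (n == 0L) {
    return(tibble(subject_id = character(), age = numeric(),
                  weight_kg = numeric(), height_cm = numeric(),
                  bmi = numeric(), cervical_cm = numeric(), ahi = numeric()))
  }
  cp <- config$clinical_params
  with_local_seed(derive_seed(config$seed, 1L), {
    draw <- function(v) {
      p <- cp[[v]]
      rtruncnorm_reject(n, p[["mean"]], p[["sd"]], p[["min"]], p[["max"]])
    }
    weight <- draw("weight_kg")
    height <- draw("height_cm")
    age <- draw("age")
    cervical <- draw("cervical_cm")
    bmi <- weight / (height / 100)^2
    link <- config$ahi_link
    z <- function(x, v) (x - cp[[v]][["mean"]]) / cp[[v]][["sd"]]
    latent <- link[["bmi"]] * z(bmi, "bmi") +
      link[["age"]] * z(age, "age") +
      link[["cervical"]] * z(cervical, "cervical_cm") +
      rnorm(n, 0, link[["noise_sd"]])
    # Empirical cohort-level standardization: the drivers are truncated
    # (and BMI nonlinearly derived), so their analytic z-scores are not
    # exactly standard normal; standardizing the realized latent keeps the
    # copula transform calibrated and the AHI marginal on target.
    latent_sd <- if (n >= 2) sd(latent) else
      sqrt(link[["bmi"]]^2 + link[["age"]]^2 +
             link[["cervical"]]^2 + link[["noise_sd"]]^2)
    u <- pnorm((latent - if (n >= 2) mean(latent) else 0) / latent_sd)
    p_ahi <- cp$ahi
    ahi <- qtruncnorm(u, p_ahi[["mean"]], p_ahi[["sd"]],
                      p_ahi[["min"]], p_ahi[["max"]])
    tibble(subject_id = sprintf("S%04d", seq_len(n)),
           age = age, weight_kg = weight, height_cm = height,
           bmi = bmi, cervical_cm = cervical, ahi = ahi)
  })
}

# Standardized AHI against the analytic moments of the configured
# truncated marginal (not the parent parameters, whose sd overstates the
# realized spread), so the per-subject landmark generator needs no
# cohort-level pass and planted correlations are not attenuated.
ahi_zscore <- function(ahi, config) {
  p <- config$clinical_params$ahi
  m <- truncnorm_moments(p[["mean"]], p[["sd"]], p[["min"]], p[["max"]])
  (ahi - m[["mean"]]) / m[["sd"]]
}

#' Generate frontal and profile landmarks for one subject
#'
#' Starts from the fixed schematic templates and perturbs only the point
#' groups entering the three craniofacial measurements, so that across a
#' cohort each measurement's correlation with AHI approaches the configured
#' effect size:
#' \itemize{
#'   \item cervicomental: the four intermediate contour points are blended
#'     towards the bottom-right rectangle corner (severity bulge, shrinking
#'     the measurement) or the top-left corner;
#'   \item face width: the midface pair is displaced symmetrically along
#'     its own axis;
#'   \item angle: the tragion is rotated about the ramus, changing the
#'     angle by an exactly linear amount.
#' }
#' Each perturbation is driven by `effect * z_AHI + sqrt(1 - effect^2) *
#' noise`; isotropic Gaussian jitter is then added to all points and
#' coordinates are clamped to the 640x480 frame.  The measurements
#' computed from the pre-jitter geometry are returned as the subject's
#' noise-free facial signal, used by the generator's regression ceiling
#' oracle.
#'
#' @param subject A one-row clinical tibble (needs `ahi`), as produced by
#'   [generate_clinical()].
#' @param effect_sizes Named vector as in [cohort_config()].
#' @param seed Integer seed for this subject.
#' @param config A [cohort_config()] (provides the AHI marginal and
#'   jitter scale).
#' @return A list with `frontal`, `profile` ([landmark_set()]s) and
#'   `signal` (one-row tibble of noise-free measurement values).
#' @export
generate_landmarks <- function(subject, effect_sizes, seed,
                               config = cohort_config()) {
  if (any(abs(effect_sizes) > 1)) {
    abort("Effect sizes must lie in [-1, 1].")
  }
  z_ahi <- ahi_zscore(subject$ahi, config)
  jitter_sd <- config$noise_scales[["landmark_jitter_px"]]
  with_local_seed(seed, {
    # A zero effect size leaves the point group at the template (up to
    # jitter): the measurement then carries no planted variation at all.
    tilt <- function(effect) {
      if (effect == 0) return(0)
      effect * z_ahi + sqrt(1 - effect^2) * rnorm(1)
    }
    frontal <- as_xy_matrix(template_landmarks("frontal"))
    profile <- as_xy_matrix(template_landmarks("profile"))
    imap_def <- landmark_index_map()

    # cervicomental bulge: measurement decreases as points move towards the
    # bottom-right corner, so the driver is the negated effect size
    g_cerv <- tilt(-effect_sizes[["cervicomental"]])
    t_cerv <- pmax(-0.45, pmin(0.45, 0.35 * g_cerv))
    contour_idx <- imap_def$cervicomental_contour
    p_ur <- profile[imap_def$rect_upper_right, ]
    p_bl <- profile[imap_def$rect_bottom_left, ]
    corner_br <- c(p_ur[1], p_bl[2])
    corner_tl <- c(p_bl[1], p_ur[2])
    for (k in contour_idx[2:5]) {
      d <- profile[k, ]
      profile[k, ] <- if (t_cerv >= 0) {
        d + t_cerv * (corner_br - d)
      } else {
        d - t_cerv * (corner_tl - d)
      }
    }

    # face width: symmetric midface displacement along the midface axis
    g_width <- tilt(effect_sizes[["face_width"]])
    t_width <- pmax(-3, pmin(3, g_width))
    axis_dir <- frontal[imap_def$midface_right, ] - frontal[imap_def$midface_left, ]
    axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
    frontal[imap_def$midface_left, ] <- frontal[imap_def$midface_left, ] -
      10 * t_width * axis_dir
    frontal[imap_def$midface_right, ] <- frontal[imap_def$midface_right, ] +
      10 * t_width * axis_dir

    # angle: rotate the tragion about the ramus; positive t widens the angle
    g_ang <- tilt(effect_sizes[["trs_angle"]])
    t_ang <- pmax(-3, pmin(3, g_ang))
    ramus <- profile[imap_def$ramus, ]
    v1 <- profile[imap_def$stomion, ] - ramus
    v2 <- profile[imap_def$tragion, ] - ramus
    s <- sign(v1[1] * v2[2] - v1[2] * v2[1])
    if (s == 0) s <- 1
    delta <- s * 6 * t_ang * pi / 180
    rot <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2L)
    profile[imap_def$tragion, ] <- ramus + as.numeric(rot %*% v2)

    frontal_clean <- landmark_set(frontal, "frontal")
    profile_clean <- landmark_set(profile, "profile")
    signal <- craniofacial_vector(frontal_clean, profile_clean, imap_def)

    clamp <- function(m) {
      m[, 1] <- pmax(0, pmin(639.999, m[, 1]))
      m[, 2] <- pmax(0, pmin(479.999, m[, 2]))
      m
    }
    if (jitter_sd > 0) {
      frontal <- frontal + matrix(rnorm(length(frontal), 0, jitter_sd),
                                  ncol = 2L)
      profile <- profile + matrix(rnorm(length(profile), 0, jitter_sd),
                                  ncol = 2L)
    }
    list(frontal = landmark_set(clamp(frontal), "frontal"),
         profile = landmark_set(clamp(profile), "profile"),
         signal = signal)
  })
}

#' Ground-truth acoustic model for the feature simulator
#'
#' Builds a deterministic (given seed) ground-truth universal background
#' model and low-rank total-variability matrix from which synthetic speech
#' feature streams are sampled.
#'
#' @param config A [cohort_config()].
#' @param rank Rank of the true subspace (defaults to the configured
#'   `true_rank`).
#' @return A list with `ubm` (a [ubm_model()]) and `T_true`
#'   (a `(n_components * feature_dim) x rank` matrix).
#' @export
true_acoustic_model <- function(config, rank = NULL) {
  ap <- config$acoustic_params
  rank <- rank %||% ap$true_rank
  C <- ap$n_components; D <- ap$feature_dim
  with_local_seed(derive_seed(config$seed, 2L), {
    w <- runif(C, 0.5, 1.5)
    ubm <- ubm_model(weights = w / sum(w),
                     means = matrix(rnorm(C * D, 0, 3), C, D),
                     covariances = matrix(runif(C * D, 0.5, 1.5), C, D))
    T_true <- matrix(rnorm(C * D * rank), C * D, rank)
    list(ubm = ubm, T_true = T_true)
  })
}

#' Simulate a speech feature stream for one subject
#'
#' Inverts the total-variability model: frames are sampled from the
#' ground-truth GMM with component means shifted by `T_true %*% w`, where
#' `w` is the subject's latent acoustic vector.  With `w = 0` the frames
#' are draws from the unshifted background model.
#'
#' @param w Latent vector (length = rank of `T_true`).
#' @param model A list as returned by [true_acoustic_model()].
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param feature_noise Multiplier on the within-component standard
#'   deviation.
#' @return An `n_frames x feature_dim` matrix.
#' @export
generate_speech_features <- function(w, model, n_frames, seed,
                                     feature_noise = 1.0) {
  ubm <- model$ubm
  C <- nrow(ubm$means); D <- ncol(ubm$means)
  if (nrow(model$T_true) != C * D) {
    abort("Dimension mismatch: T_true rows must equal n_components * feature_dim.")
  }
  if (length(w) != ncol(model$T_true)) {
    abort("Dimension mismatch: length(w) must equal the rank of T_true.")
  }
  shift <- matrix(model$T_true %*% w, C, D, byrow = TRUE)
  with_local_seed(seed, {
    comp <- sample.int(C, n_frames, replace = TRUE, prob = ubm$weights)
    noise <- matrix(rnorm(n_frames * D), n_frames, D)
    ubm$means[comp, , drop = FALSE] + shift[comp, , drop = FALSE] +
      noise * sqrt(ubm$covariances[comp, , drop = FALSE]) * feature_noise
  })
}

#' Generate a full synthetic cohort
#'
#' Produces clinical variables, landmark sets, latent acoustic vectors and
#' speech feature streams for every subject, fully reproducible from the
#' configuration (which includes the seed).  If `dir` is given, the cohort
#' is persisted as plain files: `clinical.csv`, per-subject
#' `<id>_frontal.pts` / `<id>_profile.pts`, per-subject feature matrices
#' (`<id>_features.csv` plus a JSON sidecar with dimensions) and a
#' `manifest.json`.
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory (created if needed).
#' @param features Logical: simulate speech feature streams (can be turned
#'   off for facial-only studies to save time and memory).
#' @return An `osa_cohort` list with elements `clinical`, `landmarks`,
#'   `features`, `latent_w`, `facial_signal`, `acoustic_truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL,
                            features = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  clinical <- generate_clinical(config)
  n <- nrow(clinical)
  ap <- config$acoustic_params
  lms <- vector("list", n)
  signals <- vector("list", n)
  for (i in seq_len(n)) {
    gen <- generate_landmarks(clinical[i, ], config$facial_effect_sizes,
                              seed = derive_seed(config$seed, 100L + i),
                              config = config)
    lms[[i]] <- gen[c("frontal", "profile")]
    signals[[i]] <- gen$signal
  }
  names(lms) <- clinical$subject_id
  facial_signal <- if (n > 0) {
    bind_cols(tibble(subject_id = clinical$subject_id), bind_rows(signals))
  } else {
    tibble(subject_id = character(), cervicomental = numeric(),
           face_width = numeric(), trs_angle = numeric())
  }

  acoustic_truth <- NULL
  latent_w <- matrix(numeric(0), 0L, ap$true_rank)
  feats <- NULL
  if (features && n > 0) {
    acoustic_truth <- true_acoustic_model(config)
    rho <- ap$latent_ahi_correlation
    latent_w <- with_local_seed(derive_seed(config$seed, 3L), {
      W <- matrix(rnorm(n * ap$true_rank), n, ap$true_rank)
      W[, 1] <- rho * ahi_zscore(clinical$ahi, config) +
        sqrt(1 - rho^2) * W[, 1]
      W
    })
    feats <- lapply(seq_len(n), function(i) {
      generate_speech_features(latent_w[i, ], acoustic_truth,
                               ap$frames_per_utterance,
                               seed = derive_seed(config$seed, 10000L + i),
                               feature_noise = config$noise_scales[["feature_noise"]])
    })
    names(feats) <- clinical$subject_id
  }

  cohort <- structure(list(clinical = clinical,
                           landmarks = lms,
                           features = feats,
                           latent_w = latent_w,
                           facial_signal = facial_signal,
                           acoustic_truth = acoustic_truth,
                           config = config),
                      class = "osa_cohort")
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
  }
  cohort
}

#' @export
print.osa_cohort <- function(x, ...) {
  cat(sprintf("<osa_cohort> %d subjects, seed %d\n",
              nrow(x$clinical), x$config$seed))
  cat(sprintf("  AHI: mean %.1f, range %.1f-%.1f events/hour\n",
              mean(x$clinical$ahi), min(x$clinical$ahi), max(x$clinical$ahi)))
  if (!is.null(x$features)) {
    cat(sprintf("  speech features: %d frames x %d dims per subject\n",
                nrow(x$features[[1]]), ncol(x$features[[1]])))
  }
  invisible(x)
}

# Persist a cohort as plain files with a manifest (no timestamps, so two
# identical runs are byte-identical).
write_cohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L) {
    abort(sprintf("Output directory is not writable: %s", dir))
  }
  clinical_path <- file.path(dir, "clinical.csv")
  write.csv(cohort$clinical, clinical_path, row.names = FALSE)
  files <- "clinical.csv"
  for (id in cohort$clinical$subject_id) {
    fp <- paste0(id, "_frontal.pts"); pp <- paste0(id, "_profile.pts")
    write_pts(cohort$landmarks[[id]]$frontal, file.path(dir, fp))
    write_pts(cohort$landmarks[[id]]$profile, file.path(dir, pp))
    files <- c(files, fp, pp)
  }
  if (!is.null(cohort$features)) {
    for (id in cohort$clinical$subject_id) {
      fc <- paste0(id, "_features.csv")
      utils::write.table(round(cohort$features[[id]], 6),
                         file.path(dir, fc),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      sidecar <- paste0(id, "_features.json")
      jsonlite::write_json(list(n_frames = nrow(cohort$features[[id]]),
                                feature_dim = ncol(cohort$features[[id]]),
                                subject_id = id),
                           file.path(dir, sidecar), auto_unbox = TRUE)
      files <- c(files, fc, sidecar)
    }
  }
  manifest <- list(
    n_subjects = nrow(cohort$clinical),
    seed = cohort$config$seed,
    files = sort(files),
    md5 = as.list(tools::md5sum(file.path(dir, sort(files))))
  )
  names(manifest$md5) <- sort(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Regression ceiling implied by the planted signal
#'
#' The generator's own noise-free oracle: the multiple correlation between
#' true AHI and a linear fit on the planted signal variables, i.e. the
#' correlation a regression could at best reach if measurement noise were
#' absent.  For `"craniofacial"` the signal variables are the three
#' measurements computed from the pre-jitter landmark geometry; for
#' `"clinical"` they are the link drivers (BMI, age, cervical perimeter);
#' `"combined"` uses both sets.
#'
#' @param cohort An `osa_cohort`.
#' @param source `"craniofacial"`, `"clinical"` or `"combined"`.
#' @return The multiple correlation coefficient (in \[0, 1\]).
#' @export
signal_ceiling <- function(cohort,
                           source = c("craniofacial", "clinical", "combined")) {
  source <- match.arg(source)
  facial <- cohort$facial_signal[, c("cervicomental", "face_width", "trs_angle")]
  clin <- cohort$clinical[, c("bmi", "age", "cervical_cm")]
  X <- switch(source,
              craniofacial = facial,
              clinical = clin,
              combined = bind_cols(facial, clin))
  fit <- stats::lm(cohort$clinical$ahi ~ ., data = as.data.frame(X))
  sqrt(summary(fit)$r.squared)
}
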