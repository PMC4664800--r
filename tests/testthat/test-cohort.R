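test_that("configuration validation rejects inconsistent parameters", {
  expect_error(cohort_config(n_subjects = -1), "non-negative")
  cp <- cohort_config()$clinical_params
  cp$age[["sd"]] <- 0
  expect_error(cohort_config(clinical_params = cp), "sd must be > 0")
  cp <- cohort_config()$clinical_params
  cp$ahi[["min"]] <- 100
  expect_error(cohort_config(clinical_params = cp), "min must be < max")
  expect_error(cohort_config(facial_effect_sizes = c(cervicomental = -1.2,
                                                     face_width = 0, trs_angle = 0)),
               "\\[-1, 1\\]")
})

test_that("clinical sampling matches analytic truncated-normal moments", {
  cfg <- cohort_config(n_subjects = 20000, seed = 31)
  clin <- generate_clinical(cfg)
  # directly sampled variables: sample mean within 4 standard errors of the
  # analytic truncated mean (CLT bound from the analytic truncated sd)
  for (v in c("weight_kg", "height_cm", "age", "cervical_cm", "ahi")) {
    p <- cfg$clinical_params[[v]]
    mom <- apneaface:::truncnorm_moments(p[["mean"]], p[["sd"]],
                                         p[["min"]], p[["max"]])
    se <- mom[["sd"]] / sqrt(nrow(clin))
    expect_lt(abs(mean(clin[[v]]) - mom[["mean"]]), 4 * se)
    expect_true(all(clin[[v]] >= p[["min"]] & clin[[v]] <= p[["max"]]))
  }
  # BMI is recomputed, not sampled
  expect_equal(clin$bmi, clin$weight_kg / (clin$height_cm / 100)^2)
  # the AHI link is monotone in its anthropometric drivers
  expect_gt(cor(clin$ahi, clin$bmi), 0.2)
  expect_gt(cor(clin$ahi, clin$cervical_cm), 0.05)
})

test_that("empty and singleton cohorts are handled", {
  empty <- generate_clinical(cohort_config(n_subjects = 0))
  expect_equal(nrow(empty), 0)
  one <- generate_cohort(small_cohort_config(n_subjects = 1), features = FALSE)
  expect_equal(nrow(one$clinical), 1)
  feats <- craniofacial_features(one)
  feats$ahi <- one$clinical$ahi
  expect_error(loocv_predict(feats), "at least 6")
})

test_that("cohort generation is deterministic in (config, seed)", {
  cfg <- small_cohort_config(n_subjects = 6)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$features, b$features)
  c2 <- generate_cohort(small_cohort_config(n_subjects = 6, seed = 4))
  expect_false(identical(a$clinical$ahi, c2$clinical$ahi))
})

test_that("persisted cohorts are byte-identical across reruns", {
  cfg <- small_cohort_config(n_subjects = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in setdiff(files, "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$md5, m2$md5)
})

test_that("zero effects and zero jitter reproduce the template exactly", {
  cfg <- cohort_config(n_subjects = 2, seed = 5,
                       facial_effect_sizes = c(cervicomental = 0,
                                               face_width = 0, trs_angle = 0),
                       noise_scales = c(landmark_jitter_px = 0,
                                        feature_noise = 1))
  clin <- generate_clinical(cfg)
  gen <- generate_landmarks(clin[1, ], cfg$facial_effect_sizes, seed = 9,
                            config = cfg)
  expect_equal(cbind(gen$frontal$x, gen$frontal$y),
               cbind(template_landmarks("frontal")$x,
                     template_landmarks("frontal")$y))
  expect_equal(cbind(gen$profile$x, gen$profile$y),
               cbind(template_landmarks("profile")$x,
                     template_landmarks("profile")$y))
  # all coordinates inside the frame
  for (lm in list(gen$frontal, gen$profile)) {
    expect_true(all(lm$x >= 0 & lm$x < 640 & lm$y >= 0 & lm$y < 480))
  }
  expect_error(generate_landmarks(clin[1, ], c(cervicomental = 2,
                                               face_width = 0, trs_angle = 0),
                                  seed = 1, config = cfg),
               "\\[-1, 1\\]")
})

test_that("planted measurement-AHI correlations are recovered within 0.1", {
  cfg <- cohort_config(n_subjects = 2000, seed = 7)
  cohort <- generate_cohort(cfg, features = FALSE)
  feats <- craniofacial_features(cohort)
  ahi <- cohort$clinical$ahi
  targets <- cfg$facial_effect_sizes
  expect_lt(abs(cor(feats$cervicomental, ahi) - targets[["cervicomental"]]), 0.1)
  expect_lt(abs(cor(feats$face_width, ahi) - targets[["face_width"]]), 0.1)
  expect_lt(abs(cor(feats$trs_angle, ahi) - targets[["trs_angle"]]), 0.1)
  # the noise-free regression ceiling exceeds every single-measurement
  # correlation and the landmark frame constraint holds cohort-wide
  expect_gt(signal_ceiling(cohort, "craniofacial"),
            max(abs(targets)) - 0.05)
  one <- cohort$landmarks[[17]]
  expect_true(all(one$frontal$x >= 0 & one$frontal$x < 640))
  expect_true(all(one$profile$y >= 0 & one$profile$y < 480))
})

test_that("feature streams with w = 0 come from the unshifted background model", {
  cfg <- small_cohort_config()
  truth <- true_acoustic_model(cfg, rank = 3)
  X <- generate_speech_features(rep(0, 3), truth, n_frames = 20000, seed = 2)
  overall <- colSums(truth$ubm$weights * truth$ubm$means)
  expect_equal(colMeans(X), overall, tolerance = 0.1)
  # dimension mismatches are refused
  expect_error(generate_speech_features(rep(0, 4), truth, 10, seed = 1),
               "rank")
  bad <- truth; bad$T_true <- bad$T_true[-1, , drop = FALSE]
  expect_error(generate_speech_features(rep(0, 3), bad, 10, seed = 1),
               "Dimension mismatch")
})

test_that("planted latent vectors are recoverable from extracted i-vectors", {
  cfg <- cohort_config(n_subjects = 120, seed = 13,
                       acoustic_params = list(n_components = 16L,
                                              feature_dim = 12L,
                                              true_rank = 2L,
                                              frames_per_utterance = 300L,
                                              latent_ahi_correlation = 0))
  cohort <- generate_cohort(cfg)
  stats <- lapply(cohort$features, accumulate_bw_stats,
                  ubm = cohort$acoustic_truth$ubm)
  tv <- train_total_variability(stats, cohort$acoustic_truth$ubm, rank = 2,
                                n_iter = 8, seed = 21)
  W <- extract_ivectors(stats, tv)
  al <- procrustes_align(W, cohort$latent_w)
  expect_true(all(abs(al$correlations) > 0.8))
})
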