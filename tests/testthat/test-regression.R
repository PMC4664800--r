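test_that("standardization fits on training data only", {
  rec <- planted_records(20)
  std <- standardize_features(rec)
  feats <- setdiff(names(std$train), c("subject_id", "ahi"))
  for (f in feats) {
    expect_equal(mean(std$train[[f]]), 0, tolerance = 1e-12)
    expect_equal(sd(std$train[[f]]), 1, tolerance = 1e-12)
  }
  # constant features are centered, not divided
  rec$f1 <- 7
  std2 <- standardize_features(rec)
  expect_true(all(std2$train$f1 == 0))
  # the transform of held-out records uses training statistics only:
  # permuting the held-out rows changes nothing about the fit
  test_a <- planted_records(10, seed = 5)
  test_b <- test_a[sample(10), ]
  sa <- standardize_features(rec, test_a)
  sb <- standardize_features(rec, test_b)
  expect_identical(sa$center, sb$center)
  expect_identical(sa$scale, sb$scale)
  expect_equal(dplyr::arrange(sa$apply_to, subject_id),
               dplyr::arrange(sb$apply_to, subject_id))
  expect_error(standardize_features(rec[0, ]), "Empty")
})

test_that("a singleton grid is returned without ambiguity", {
  rec <- planted_records(15)
  g <- svr_grid(C_values = 2, epsilon_values = 0.5)
  sel <- grid_search_5fold(rec, g, seed = 3)
  expect_equal(sel$C, 2)
  expect_equal(sel$epsilon, 0.5)
  expect_equal(nrow(sel$cv_table), 1)
  expect_error(grid_search_5fold(rec[1:4, ], g), "at least 5")
  expect_error(svr_grid(C_values = numeric()), "non-empty")
  expect_error(svr_grid(C_values = -1), "positive")
})

test_that("grid search agrees with an exhaustive independent re-evaluation", {
  rec <- planted_records(40, noise = 3, seed = 9)
  g <- svr_grid(C_values = c(0.125, 1, 8), epsilon_values = c(0.25, 1))
  seed <- 12
  sel <- grid_search_5fold(rec, g, seed = seed)
  # oracle: rebuild the same deterministic folds and score every pair with
  # direct e1071 calls and hand-rolled standardization
  folds <- withr::with_seed(seed, sample(rep_len(1:5, nrow(rec))))
  pairs <- expand.grid(epsilon = g$epsilon_values, C = g$C_values)
  oracle_mae <- sapply(seq_len(nrow(pairs)), function(p) {
    errs <- c()
    for (f in 1:5) {
      tr <- rec[folds != f, ]; te <- rec[folds == f, ]
      mu <- colMeans(tr[c("f1", "f2")]); sg <- sapply(tr[c("f1", "f2")], sd)
      Xtr <- scale(as.matrix(tr[c("f1", "f2")]), mu, sg)
      Xte <- scale(as.matrix(te[c("f1", "f2")]), mu, sg)
      fit <- e1071::svm(Xtr, tr$ahi, type = "eps-regression",
                        kernel = "linear", cost = pairs$C[p],
                        epsilon = pairs$epsilon[p], scale = FALSE)
      errs <- c(errs, abs(as.numeric(predict(fit, Xte)) - te$ahi))
    }
    mean(errs)
  })
  best <- which.min(oracle_mae)
  expect_equal(sel$C, pairs$C[best])
  expect_equal(sel$epsilon, pairs$epsilon[best])
  expect_lt(min(sel$cv_table$cv_mae), min(oracle_mae) * 1.1)
})

test_that("selection optimizes MAE, not squared error", {
  # a rigged regressor whose held-out errors depend only on (C, epsilon):
  # pair (1, .) -> errors (0, 0, 3, 0, 0, ...): MAE small, MSE large
  # pair (2, .) -> errors (1.2, 1.2, ...):      MAE larger, MSE smaller
  rigged <- list(
    fit = function(X, y, C, epsilon) list(C = C),
    predict = function(fit, X) {
      key <- X[, 1]  # the f1 feature enumerates the records
      if (fit$C == 1) ifelse(rank(key) == 1, 3, 0) else rep(1.2, nrow(X))
    })
  n <- 20
  rec <- tibble::tibble(f1 = seq_len(n), subject_id = as.character(seq_len(n)),
                        ahi = rep(0, n))
  g <- svr_grid(C_values = c(1, 2), epsilon_values = 0.5)
  sel <- grid_search_5fold(rec, g, seed = 2, regressor = rigged)
  # per fold of 4: pair C=1 has MAE 3/4 = 0.75 (MSE 2.25); C=2 has MAE 1.2
  # (MSE 1.44).  MAE prefers C=1, squared error would prefer C=2.
  expect_equal(sel$C, 1)
})

test_that("ties break towards smaller C then smaller epsilon", {
  constant <- list(fit = function(X, y, C, epsilon) list(),
                   predict = function(fit, X) rep(0, nrow(X)))
  rec <- planted_records(12)
  g <- svr_grid(C_values = c(8, 0.5, 2), epsilon_values = c(1, 0.25))
  sel <- grid_search_5fold(rec, g, seed = 1, regressor = constant)
  expect_equal(sel$C, 0.5)
  expect_equal(sel$epsilon, 0.25)
})

test_that("LOOCV predictions are leakage-free", {
  rec <- planted_records(14, noise = 2, seed = 4)
  g <- svr_grid(C_values = c(0.5, 4), epsilon_values = 0.5)
  base <- loocv_predict(rec, g, seed = 6)
  # perturbing the held-out subject's label must not change its prediction
  rec2 <- rec
  rec2$ahi[7] <- rec2$ahi[7] + 1000
  pert <- loocv_predict(rec2, g, seed = 6)
  expect_equal(pert$ahi_pred[7], base$ahi_pred[7], tolerance = 1e-12)
  expect_equal(pert$C[7], base$C[7])
  expect_error(loocv_predict(rec[1:5, ], g), "at least 6")
})

test_that("a mean-stub regressor yields the closed-form LOOCV prediction", {
  rec <- planted_records(11, noise = 1, seed = 8)
  got <- loocv_predict(rec, svr_grid(C_values = 1, epsilon_values = 1),
                       seed = 2, regressor = mean_stub_regressor())
  for (i in seq_len(nrow(rec))) {
    expect_equal(got$ahi_pred[i], mean(rec$ahi[-i]), tolerance = 1e-12)
  }
})

test_that("noise-free planted linear data is recovered almost exactly", {
  rec <- planted_records(36, noise = 0, seed = 10)
  preds <- loocv_predict(rec, fast_grid(), seed = 3)
  expect_gt(pearson_cc(preds$ahi_truth, preds$ahi_pred), 0.99)
  expect_lt(mae(preds$ahi_truth, preds$ahi_pred), 1.5)
})

test_that("error metrics match brute-force definitional oracles", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(4, 5, 6)), 3)
  expect_error(mae(1:3, 1:4), "equal")
  expect_equal(pearson_cc(1:10, 1:10), 1)
  expect_equal(pearson_cc(1:10, -(1:10)), -1)
  expect_error(pearson_cc(rep(1, 5), 1:5), "constant")
  withr::with_seed(14, {
    for (i in 1:10) {
      a <- rnorm(50); b <- rnorm(50)
      expect_equal(mae(a, b), sum(abs(a - b)) / 50, tolerance = 1e-12)
      cc_bf <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
      expect_equal(pearson_cc(a, b), cc_bf, tolerance = 1e-12)
    }
  })
})

test_that("classification metrics match enumeration and a rank AUC oracle", {
  perfect <- classify_from_ahi(c(5, 15, 25, 3), c(6, 14, 30, 2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$auc, 1)
  # 6-subject toy with one false positive and one false negative
  y_t <- c(20, 15, 12, 5, 8, 3)     # classes: P P P N N N
  y_p <- c(25, 14, 7, 11, 6, 2)     # predicted: P P N P N N
  cls <- classify_from_ahi(y_t, y_p)
  expect_equal(cls[c("tp", "fp", "tn", "fn")],
               tibble::tibble(tp = 2, fp = 1, tn = 2, fn = 1))
  expect_equal(cls$accuracy, 4 / 6)
  expect_equal(cls$sensitivity, 2 / 3)
  expect_equal(cls$specificity, 2 / 3)
  # pairwise-concordance oracle with half credit for ties
  conc <- function(truth_pos, score) {
    pos <- which(truth_pos); neg <- which(!truth_pos)
    s <- 0
    for (i in pos) for (j in neg) {
      s <- s + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
    s / (length(pos) * length(neg))
  }
  expect_equal(cls$auc, conc(y_t >= 10, y_p), tolerance = 1e-12)
  withr::with_seed(15, {
    for (i in 1:10) {
      y_t <- runif(30, 0, 40)
      y_p <- y_t + rnorm(30, sd = 10)
      y_p[1:3] <- y_p[4:6]  # inject ties
      got <- classify_from_ahi(y_t, y_p)
      expect_equal(got$auc, conc(y_t >= 10, y_p), tolerance = 1e-12)
    }
  })
  skip_if_not_installed("pROC")
  y_t <- runif(40, 0, 40); y_p <- y_t + rnorm(40, sd = 8)
  expect_equal(classify_from_ahi(y_t, y_p)$auc,
               as.numeric(pROC::auc(pROC::roc(y_t >= 10, y_p, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("single-class truth returns NA AUC with a warning", {
  expect_warning(cls <- classify_from_ahi(c(20, 30, 40), c(22, 28, 35)),
                 "undefined")
  expect_true(is.na(cls$auc))
  expect_equal(cls$accuracy, 1)
})

test_that("experiments assemble the documented feature sets", {
  cohort <- generate_cohort(small_cohort_config(n_subjects = 12),
                            features = FALSE)
  rec <- apneaface:::assemble_features(cohort, "clinical")
  expect_named(rec, c("subject_id", "age", "bmi", "cervical_cm", "ahi"))
  cranio <- craniofacial_features(cohort)
  rec2 <- apneaface:::assemble_features(cohort, "craniofacial+clinical",
                                        craniofacial = cranio)
  expect_named(rec2, c("subject_id", "cervicomental", "face_width",
                       "trs_angle", "age", "bmi", "cervical_cm", "ahi"))
  expect_error(apneaface:::assemble_features(cohort, "ivector"),
               "ivectors")
  expect_error(apneaface:::assemble_features(cohort, "voodoo"), "Unknown")
})

test_that("facial features out-predict pure-noise i-vectors", {
  cfg <- cohort_config(n_subjects = 40, seed = 27,
                       acoustic_params = list(n_components = 8L,
                                              feature_dim = 10L,
                                              true_rank = 3L,
                                              frames_per_utterance = 150L,
                                              latent_ahi_correlation = 0))
  cohort <- generate_cohort(cfg)
  ivecs <- cohort_ivectors(cohort, rank = 3, n_iter_ubm = 3, n_iter_tv = 3,
                           seed = 5)$ivectors
  g <- svr_grid(C_values = 1, epsilon_values = 0.5)
  ev_face <- run_experiment(cohort, "craniofacial", grid = g, seed = 2)
  ev_ivec <- run_experiment(cohort, "ivector", grid = g, seed = 2,
                            ivectors = ivecs)
  expect_gt(ev_face$cc, ev_ivec$cc)
  # evaluation object contract
  g1 <- glance(ev_face)
  expect_equal(g1$n, 40)
  expect_true(abs(g1$cc) <= 1 && g1$mae >= 0)
  expect_equal(nrow(tidy(ev_face)), 40)
})
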