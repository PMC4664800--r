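#' Hyperparameter grid for epsilon-SVR
#'
#' The exhaustive search grid for the complexity parameter C and the
#' epsilon-insensitive-zone width.  Defaults follow the usual power-of-two
#' convention: C over 2^-5..2^9 (step 2^2) and epsilon over 2^-6..2^0
#' (step 2^2).
#'
#' @param C_values Positive reals.
#' @param epsilon_values Positive reals.
#' @param kernel Kernel name; `"linear"` is the primary contract, `"radial"`
#'   is available behind this flag.
#' @return An `svr_grid` list.
#' @export
svr_grid <- function(C_values = 2^seq(-5, 9, by = 2),
                     epsilon_values = 2^seq(-6, 0, by = 2),
                     kernel = c("linear", "radial")) {
  kernel <- match.arg(kernel)
  if (length(C_values) == 0 || length(epsilon_values) == 0) {
    abort("Grids must be non-empty.")
  }
  if (any(C_values <= 0) || any(epsilon_values <= 0)) {
    abort("C and epsilon values must be positive.")
  }
  structure(list(C_values = sort(unique(C_values)),
                 epsilon_values = sort(unique(epsilon_values)),
                 kernel = kernel),
            class = "svr_grid")
}

# Default regressor: epsilon-SVR (libsvm via e1071).  A regressor is a
# list(fit(X, y, C, epsilon), predict(fit, X)); tests inject stubs through
# the same interface.
svr_regressor <- function(kernel = "linear") {
  list(
    fit = function(X, y, C, epsilon) {
      e1071::svm(X, y, type = "eps-regression", kernel = kernel,
                 cost = C, epsilon = epsilon, scale = FALSE)
    },
    predict = function(fit, X) as.numeric(predict(fit, X))
  )
}

#' Z-score features on a training set, apply to both sets
#'
#' Standardization statistics (per-feature mean and standard deviation)
#' are fitted on the training records only and applied unchanged to the
#' records to transform, so no information from held-out data leaks into
#' the transform.  Zero-variance features are centered but not divided.
#'
#' @param train Data frame / tibble of training records (feature columns
#'   only, or with non-feature columns named in `exclude`).
#' @param apply_to Records to transform with the training statistics
#'   (default: the training records themselves).
#' @param exclude Character vector of column names to pass through
#'   untouched (default `c("subject_id", "ahi")`).
#' @return List with `train`, `apply_to` (transformed tibbles), `center`,
#'   `scale`.
#' @export
standardize_features <- function(train, apply_to = train,
                                 exclude = c("subject_id", "ahi")) {
  if (nrow(train) == 0L) abort("Empty training set.")
  feat_cols <- setdiff(names(train), exclude)
  center <- vapply(train[feat_cols], mean, numeric(1))
  scale_ <- vapply(train[feat_cols], sd, numeric(1))
  scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
  transform <- function(df) {
    df[feat_cols] <- map2(df[feat_cols], feat_cols, function(col, nm) {
      (col - center[[nm]]) / scale_[[nm]]
    })
    df
  }
  list(train = transform(train), apply_to = transform(apply_to),
       center = center, scale = scale_)
}

feature_matrix <- function(records, exclude = c("subject_id", "ahi")) {
  as.matrix(records[setdiff(names(records), exclude)])
}

#' Inner 5-fold grid search for (C, epsilon)
#'
#' Deterministic (given seed) 5-fold partition of the training records;
#' every (C, epsilon) pair is scored by the mean out-of-fold MAE and the
#' minimizing pair is returned, ties broken towards smaller C, then
#' smaller epsilon.  Fold-internal feature standardization is refitted on
#' each fold's training part.
#'
#' @param train_records Tibble with `ahi` and feature columns (at least 5
#'   rows).
#' @param grid An [svr_grid()].
#' @param seed Integer seed for the fold assignment.
#' @param regressor Regressor interface (see Details in [loocv_predict()]).
#' @param n_folds Number of inner folds (default 5).
#' @return List with `C`, `epsilon`, and `cv_table` (a tibble of mean CV
#'   MAE per grid pair).
#' @export
grid_search_5fold <- function(train_records, grid = svr_grid(), seed = 1L,
                              regressor = svr_regressor(grid$kernel),
                              n_folds = 5L) {
  n <- nrow(train_records)
  if (n < n_folds) {
    abort(sprintf("Need at least %d training records for %d-fold CV, got %d.",
                  n_folds, n_folds, n))
  }
  folds <- with_local_seed(seed, {
    sample(rep_len(seq_len(n_folds), n))
  })
  pairs <- tidyr::expand_grid(C = grid$C_values, epsilon = grid$epsilon_values)
  fold_preds <- vector("list", n_folds)
  abs_err <- matrix(0, nrow(pairs), n)  # per-pair, per-record held-out error
  for (f in seq_len(n_folds)) {
    tr <- train_records[folds != f, , drop = FALSE]
    te <- train_records[folds == f, , drop = FALSE]
    std <- standardize_features(tr, te)
    Xtr <- feature_matrix(std$train); ytr <- std$train$ahi
    Xte <- feature_matrix(std$apply_to); yte <- std$apply_to$ahi
    for (p in seq_len(nrow(pairs))) {
      fit <- regressor$fit(Xtr, ytr, pairs$C[p], pairs$epsilon[p])
      abs_err[p, folds == f] <- abs(regressor$predict(fit, Xte) - yte)
    }
  }
  cv_mae <- rowMeans(abs_err)
  # ties (within numerical noise) break towards smaller C, then epsilon;
  # pairs are generated in that order
  best <- which(cv_mae <= min(cv_mae) + 1e-12)[1L]
  list(C = pairs$C[best], epsilon = pairs$epsilon[best],
       cv_table = bind_cols(pairs, tibble(cv_mae = cv_mae)))
}

#' Leave-one-out AHI prediction with nested grid search
#'
#' The outer protocol: each subject in turn is held out; feature
#' standardization and the 5-fold grid search are fitted on the remaining
#' n - 1 subjects only; the SVR is retrained with the selected (C,
#' epsilon) on those n - 1 and predicts the held-out subject.  The
#' held-out subject's label and features influence nothing on its own
#' training side.
#'
#' `regressor` is a list of `fit(X, y, C, epsilon)` and `predict(fit, X)`;
#' the default wraps the epsilon-SVR of libsvm.  Tests substitute stub
#' regressors through the same interface.
#'
#' @param records Tibble with `subject_id`, `ahi` and feature columns (at
#'   least 6 rows, so that 5 inner folds remain formable).
#' @param grid An [svr_grid()].
#' @param seed Integer seed (drives only the inner fold assignments).
#' @param regressor Regressor interface.
#' @return Tibble with one row per subject: `subject_id`, `ahi_truth`,
#'   `ahi_pred`, `C`, `epsilon`.
#' @export
loocv_predict <- function(records, grid = svr_grid(), seed = 1L,
                          regressor = svr_regressor(grid$kernel)) {
  n <- nrow(records)
  if (n < 6L) {
    abort("Leave-one-out with an inner 5-fold search needs at least 6 records.")
  }
  feat_cols <- setdiff(names(records), c("subject_id", "ahi"))
  if (length(feat_cols) == 0L) abort("No feature columns found.")
  incomplete <- !complete.cases(records[feat_cols])
  if (any(incomplete)) {
    abort(sprintf("Missing features for subjects: %s",
                  paste(records$subject_id[incomplete], collapse = ", ")))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    train <- records[-i, , drop = FALSE]
    test <- records[i, , drop = FALSE]
    sel <- grid_search_5fold(train, grid, seed = derive_seed(seed, i),
                             regressor = regressor)
    std <- standardize_features(train, test)
    fit <- regressor$fit(feature_matrix(std$train), std$train$ahi,
                         sel$C, sel$epsilon)
    pred <- regressor$predict(fit, feature_matrix(std$apply_to))
    out[[i]] <- tibble(subject_id = records$subject_id[i],
                       ahi_truth = records$ahi[i],
                       ahi_pred = pred,
                       C = sel$C, epsilon = sel$epsilon)
  }
  bind_rows(out)
}

#' Mean absolute error
#'
#' @param y_truth,y_pred Equal-length numeric vectors.
#' @return Mean of absolute differences (events/hour for AHI).
#' @export
mae <- function(y_truth, y_pred) {
  if (length(y_truth) != length(y_pred) || length(y_truth) < 1L) {
    abort("`y_truth` and `y_pred` must have equal positive length.")
  }
  mean(abs(y_truth - y_pred))
}

#' Pearson correlation between truth and prediction
#'
#' @param y_truth,y_pred Equal-length numeric vectors (length >= 2), both
#'   non-constant.
#' @return Product-moment correlation coefficient.
#' @export
pearson_cc <- function(y_truth, y_pred) {
  if (length(y_truth) != length(y_pred) || length(y_truth) < 2L) {
    abort("Need equal lengths >= 2.")
  }
  if (sd(y_truth) < 1e-15 || sd(y_pred) < 1e-15) {
    abort("Correlation undefined for constant input.")
  }
  cor(y_truth, y_pred)
}

# Rank-statistic ROC AUC with half credit for ties (Mann-Whitney form).
rank_auc <- function(truth_pos, score) {
  n_pos <- sum(truth_pos); n_neg <- sum(!truth_pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' OSA classification metrics from estimated AHI
#'
#' Subjects are classified as OSA when AHI >= `threshold` (10 events/hour,
#' the conventional non-OSA boundary), on both the truth and the
#' prediction side.  Sensitivity is the true-positive rate on OSA
#' subjects, specificity the true-negative rate on non-OSA subjects, and
#' the ROC AUC treats the predicted AHI as a continuous score (rank
#' statistic, ties counted half).  With a single-class truth the AUC is
#' undefined and returned as `NA` with a warning; the other metrics are
#' still computed.
#'
#' @param y_truth,y_pred Equal-length numeric vectors.
#' @param threshold Positive AHI decision boundary (default 10).
#' @return One-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
classify_from_ahi <- function(y_truth, y_pred, threshold = 10) {
  if (length(y_truth) != length(y_pred)) abort("Length mismatch.")
  if (threshold <= 0) abort("`threshold` must be positive.")
  truth_pos <- y_truth >= threshold
  pred_pos <- y_pred >= threshold
  tp <- sum(truth_pos & pred_pos); fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos); fp <- sum(!truth_pos & pred_pos)
  auc <- rank_auc(truth_pos, y_pred)
  if (is.na(auc)) {
    warn("Single-class truth: ROC AUC is undefined (returned as NA).")
  }
  tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / length(y_truth),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         auc = auc)
}

# Assemble the per-subject feature table for a named source.
assemble_features <- function(cohort, source,
                              craniofacial = NULL, ivectors = NULL,
                              index_map = landmark_index_map()) {
  clin <- cohort$clinical[, c("subject_id", "age", "bmi", "cervical_cm")]
  parts <- strsplit(source, "+", fixed = TRUE)[[1]]
  tabs <- lapply(parts, function(p) {
    switch(p,
      clinical = clin,
      craniofacial = craniofacial %||% craniofacial_features(cohort, index_map),
      ivector = {
        if (is.null(ivectors)) {
          abort("`ivectors` must be supplied for i-vector feature sources.")
        }
        ivectors
      },
      abort(sprintf("Unknown feature source '%s'.", p)))
  })
  out <- Reduce(function(a, b) left_join(a, b, by = "subject_id"), tabs)
  out$ahi <- cohort$clinical$ahi[match(out$subject_id,
                                       cohort$clinical$subject_id)]
  out
}

#' Run one AHI-estimation experiment on a cohort
#'
#' Assembles the requested feature vector for every subject (clinical uses
#' age, BMI and cervical perimeter; `"craniofacial+clinical"` and
#' `"ivector+clinical"` concatenate the sources), runs leave-one-out SVR
#' prediction with the nested grid search, and summarizes MAE, Pearson CC
#' and threshold-10 classification metrics.
#'
#' @param cohort An `osa_cohort` from [generate_cohort()].
#' @param source One of `"clinical"`, `"craniofacial"`, `"ivector"`,
#'   `"craniofacial+clinical"`, `"ivector+clinical"`.
#' @param grid An [svr_grid()].
#' @param seed Integer seed for the inner fold assignments.
#' @param ivectors Optional tibble `subject_id, w_1..w_R` (required for
#'   i-vector sources; produce it with [cohort_ivectors()]).
#' @param craniofacial Optional precomputed [craniofacial_features()]
#'   table (computed from the cohort when absent).
#' @param index_map A [landmark_index_map()].
#' @param threshold Classification boundary (default 10 events/hour).
#' @return An `osa_evaluation` object; see [tidy.osa_evaluation()] and
#'   [glance.osa_evaluation()].
#' @export
run_experiment <- function(cohort, source = "craniofacial+clinical",
                           grid = svr_grid(), seed = 1L,
                           ivectors = NULL, craniofacial = NULL,
                           index_map = landmark_index_map(),
                           threshold = 10) {
  records <- assemble_features(cohort, source, craniofacial, ivectors,
                               index_map)
  preds <- loocv_predict(records, grid, seed)
  cls <- classify_from_ahi(preds$ahi_truth, preds$ahi_pred, threshold)
  structure(list(source = source,
                 predictions = preds,
                 mae = mae(preds$ahi_truth, preds$ahi_pred),
                 cc = pearson_cc(preds$ahi_truth, preds$ahi_pred),
                 classification = cls,
                 grid = grid, seed = seed),
            class = "osa_evaluation")
}

#' @export
print.osa_evaluation <- function(x, ...) {
  cat(sprintf("<osa_evaluation> source: %s (n = %d)\n",
              x$source, nrow(x$predictions)))
  cat(sprintf("  MAE %.2f events/hour, Pearson CC %.3f\n", x$mae, x$cc))
  cat(sprintf("  OSA classification @ AHI >= %g: accuracy %.1f%%, sens %.1f%%, spec %.1f%%, AUC %.2f\n",
              x$classification$threshold, 100 * x$classification$accuracy,
              100 * x$classification$sensitivity,
              100 * x$classification$specificity, x$classification$auc))
  invisible(x)
}

#' Extract per-subject i-vectors for a cohort
#'
#' Trains (or reuses) a UBM and a total-variability model on the cohort's
#' pooled speech feature streams and extracts one i-vector per subject
#' (frames pooled per subject into a single utterance).
#'
#' @param cohort An `osa_cohort` with simulated features.
#' @param rank i-vector dimension (default 50).
#' @param n_components UBM components (default the cohort's configured
#'   count).
#' @param n_iter_ubm,n_iter_tv EM iterations.
#' @param seed Integer seed.
#' @param ubm,tv Optional pre-trained models to reuse.
#' @return List with `ivectors` (tibble `subject_id, w_1..w_R`), `ubm`,
#'   `tv`, `stats`.
#' @export
cohort_ivectors <- function(cohort, rank = 50L, n_components = NULL,
                            n_iter_ubm = 5L, n_iter_tv = 5L, seed = 1L,
                            ubm = NULL, tv = NULL) {
  if (is.null(cohort$features)) {
    abort("Cohort has no speech features (generated with features = FALSE).")
  }
  n_components <- n_components %||% cohort$config$acoustic_params$n_components
  if (is.null(ubm)) {
    ubm <- train_ubm(cohort$features, n_components, n_iter = n_iter_ubm,
                     seed = derive_seed(seed, 71L))
  }
  stats_list <- lapply(cohort$features, accumulate_bw_stats, ubm = ubm)
  if (is.null(tv)) {
    tv <- train_total_variability(stats_list, ubm, rank = rank,
                                  n_iter = n_iter_tv,
                                  seed = derive_seed(seed, 72L))
  }
  W <- extract_ivectors(stats_list, tv)
  colnames(W) <- paste0("w_", seq_len(ncol(W)))
  ivectors <- bind_cols(tibble(subject_id = names(cohort$features)),
                        as_tibble(W))
  list(ivectors = ivectors, ubm = ubm, tv = tv, stats = stats_list)
}
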