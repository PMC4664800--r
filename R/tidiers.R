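#' Tidy per-subject predictions of an evaluation
#'
#' @param x An `osa_evaluation` from [run_experiment()].
#' @param ... Ignored.
#' @return Tibble with one row per subject (`subject_id`, `ahi_truth`,
#'   `ahi_pred`, chosen `C` and `epsilon`).
#' @exportS3Method generics::tidy
#' @export
tidy.osa_evaluation <- function(x, ...) {
  x$predictions
}

#' One-row summary of an evaluation
#'
#' @param x An `osa_evaluation`.
#' @param ... Ignored.
#' @return One-row tibble: `source`, `n`, `mae`, `cc`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc`.
#' @exportS3Method generics::glance
#' @export
glance.osa_evaluation <- function(x, ...) {
  bind_cols(tibble(source = x$source, n = nrow(x$predictions),
                   mae = x$mae, cc = x$cc),
            x$classification[, c("accuracy", "sensitivity",
                                 "specificity", "auc")])
}

#' Truth-versus-prediction plot for an evaluation
#'
#' Scatter of estimated against true AHI with the identity line and the
#' OSA decision threshold.
#'
#' @param object An `osa_evaluation`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.osa_evaluation <- function(object, ...) {
  thr <- object$classification$threshold
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$ahi_truth, y = .data$ahi_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      title = sprintf("LOOCV AHI estimation (%s)", object$source),
      subtitle = sprintf("MAE %.2f events/hour, CC %.2f", object$mae, object$cc),
      x = "true AHI (events/hour)", y = "estimated AHI (events/hour)")
}

#' Tidy a UBM into one row per mixture component
#'
#' @param x A [ubm_model()].
#' @param ... Ignored.
#' @return Tibble with `component`, `weight`, `mean_norm`, `var_mean`.
#' @exportS3Method generics::tidy
#' @export
tidy.ubm_model <- function(x, ...) {
  tibble(component = seq_along(x$weights),
         weight = x$weights,
         mean_norm = sqrt(rowSums(x$means^2)),
         var_mean = rowMeans(x$covariances))
}

#' One-row summary of a UBM fit
#'
#' @param x A [ubm_model()].
#' @param ... Ignored.
#' @return One-row tibble with dimensions and the final training
#'   log-likelihood (NA for hand-built models).
#' @exportS3Method generics::glance
#' @export
glance.ubm_model <- function(x, ...) {
  trace <- attr(x, "loglik_trace")
  tibble(n_components = nrow(x$means), feature_dim = ncol(x$means),
         final_loglik = if (is.null(trace)) NA_real_ else trace[length(trace)],
         n_iter = if (is.null(trace)) NA_integer_ else length(trace))
}

#' One-row summary of a total-variability model
#'
#' @param x A [tv_model()].
#' @param ... Ignored.
#' @return One-row tibble with the rank, supervector dimension and final
#'   training objective.
#' @exportS3Method generics::glance
#' @export
glance.tv_model <- function(x, ...) {
  tr <- x$objective_trace
  tibble(rank = x$rank,
         supervector_dim = nrow(x$T),
         final_objective = if (length(tr)) tr[length(tr)] else NA_real_,
         n_iter = length(tr))
}

#' EM objective trace plot
#'
#' @param object A [ubm_model()] or [tv_model()] with a recorded trace.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.tv_model <- function(object, ...) {
  tr <- object$objective_trace
  ggplot2::ggplot(tibble(iteration = seq_along(tr), objective = tr),
                  ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(title = "Total-variability EM objective",
                  x = "iteration", y = "objective (up to constants)")
}

#' @rdname autoplot.tv_model
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ubm_model <- function(object, ...) {
  tr <- attr(object, "loglik_trace")
  if (is.null(tr)) abort("This UBM has no recorded training trace.")
  ggplot2::ggplot(tibble(iteration = seq_along(tr), loglik = tr),
                  ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(title = "UBM EM log-likelihood",
                  x = "iteration", y = "total log-likelihood")
}
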