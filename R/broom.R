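#' Tidy a task result
#'
#' One row per selected feature, in selection order.
#'
#' @param x An `oprs_task_result`.
#' @param ... Unused.
#' @return A tibble `task_id`, `rank`, `feature`.
#' @export
tidy.oprs_task_result <- function(x, ...) {
  tibble(
    task_id = x$task_id,
    rank = seq_along(x$selected_features),
    feature = x$selected_features
  )
}

#' Glance at a task result
#'
#' @param x An `oprs_task_result`.
#' @param ... Unused.
#' @return A one-row tibble: `task_id`, `n`, `n_pos`, `n_features`, `auc`,
#'   `sensitivity_pct`, `specificity_pct`, `threshold`.
#' @export
glance.oprs_task_result <- function(x, ...) {
  tibble(
    task_id = x$task_id, n = x$n, n_pos = x$n_pos,
    n_features = length(x$selected_features), auc = x$auc,
    sensitivity_pct = x$sensitivity_pct,
    specificity_pct = x$specificity_pct,
    threshold = x$threshold
  )
}

#' Tidy a permutation report
#'
#' @param x An `oprs_permutation`.
#' @param ... Unused.
#' @return A tibble `task_id`, `shuffle`, `auc`.
#' @export
tidy.oprs_permutation <- function(x, ...) {
  tibble(
    task_id = x$task_id,
    shuffle = seq_along(x$shuffled_auc),
    auc = x$shuffled_auc
  )
}

#' Glance at a permutation report
#'
#' @param x An `oprs_permutation`.
#' @param ... Unused.
#' @return A one-row tibble with the real AUC, the shuffled mean and sd, and
#'   the pass flag (`real_auc > mean + 2 sd`).
#' @export
glance.oprs_permutation <- function(x, ...) {
  tibble(
    task_id = x$task_id, n_shuffles = x$n_shuffles, real_auc = x$real_auc,
    mean_shuffled = x$mean_shuffled, sd_shuffled = x$sd_shuffled,
    pass = x$pass
  )
}

#' Tidy / glance a concentration calibration fit
#'
#' Delegates to the underlying linear model.
#'
#' @param x An `oprs_concentration_fit`.
#' @param ... Passed on.
#' @export
tidy.oprs_concentration_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.oprs_concentration_fit
#' @export
glance.oprs_concentration_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r_squared = s$r.squared, sigma = s$sigma,
         n = length(s$residuals))
}
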