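#' Permutation test for overtraining
#'
#' Shuffles the diagnostic labels of the task's measurements (measurement
#' level, class counts preserved) and reruns the entire selection and
#' classification pipeline -- discriminatory wavelengths, mRMR, feature-count
#' selection and grouped LOOCV -- for each shuffle. If the real AUC does not
#' clearly exceed the shuffled-AUC distribution the apparent performance is
#' attributable to overtraining. The pass rule is
#' `real AUC > mean(shuffled) + 2 * sd(shuffled)`.
#'
#' @inheritParams run_task
#' @param n_shuffles Number of label shuffles (>= 2; 100 by default).
#' @param seed Seed for the shuffles (classifier seeds derive from it).
#' @param patient_level Shuffle labels between patients instead of between
#'   measurements (optional stricter variant; default `FALSE`).
#' @return An `oprs_permutation` object: `task_id`, `real_auc`,
#'   `shuffled_auc` (vector), `mean_shuffled`, `sd_shuffled`, `pass`.
#' @export
permutation_test <- function(channels, manifest, task, config = task_config(),
                             n_shuffles = 100, seed = config$seed,
                             patient_level = FALSE) {
  if (n_shuffles < 2) abort("n_shuffles must be at least 2")
  if (is.character(task)) {
    task <- filter(binary_tasks(), .data$task_id == !!task)
    if (nrow(task) == 0) abort("unknown task id")
  }
  ord <- match(channels$measurement_id, manifest$measurement_id)
  patient_id <- manifest$patient_id[ord]
  labels <- task_labels(manifest[ord, ], task)
  real <- run_task_labels(channels, patient_id, labels, config,
    task_id = task$task_id
  )

  idx <- which(!is.na(labels))
  shuffled <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      perm <- labels
      if (patient_level) {
        pats <- unique(patient_id[idx])
        pat_lab <- vapply(
          pats, function(p) labels[idx][match(p, patient_id[idx])], character(1)
        )
        new_lab <- setNames(sample(pat_lab), pats)
        perm[idx] <- unname(new_lab[patient_id[idx]])
      } else {
        perm[idx] <- sample(labels[idx])
      }
      cfg <- config
      cfg$seed <- config$seed + 1000L * s
      suppressWarnings(
        run_task_labels(channels, patient_id, perm, cfg,
          task_id = task$task_id
        )$auc
      )
    }, numeric(1))
  })

  structure(
    list(
      task_id = task$task_id,
      real_auc = real$auc,
      shuffled_auc = shuffled,
      mean_shuffled = mean(shuffled),
      sd_shuffled = sd(shuffled),
      n_shuffles = n_shuffles,
      pass = real$auc > mean(shuffled) + 2 * sd(shuffled)
    ),
    class = "oprs_permutation"
  )
}

#' @export
print.oprs_permutation <- function(x, ...) {
  cat(
    "Permutation test for", x$task_id, ": real AUC", sprintf("%.3f", x$real_auc),
    "vs shuffled", sprintf("%.3f +/- %.3f", x$mean_shuffled, x$sd_shuffled),
    if (x$pass) "(significant)" else "(overtrained / not significant)", "\n"
  )
  invisible(x)
}
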