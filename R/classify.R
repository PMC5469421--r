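#' The eight binary diagnostic tasks
#'
#' Normal-versus-dysplasia, benign-versus-dysplasia, benign-versus-normal and
#' MD-versus-SD contrasts. The dysplastic (or, for `benign_vs_normal`, the
#' benign-lesion) side is scored as positive.
#'
#' @return A tibble `task_id`, `negative`, `positive` (list columns of class
#'   names), 8 rows.
#' @export
binary_tasks <- function() {
  tibble(
    task_id = c(
      "normal_vs_MD", "normal_vs_SD", "normal_vs_MDSD", "MD_vs_SD",
      "benign_vs_MD", "benign_vs_SD", "benign_vs_MDSD", "benign_vs_normal"
    ),
    negative = list(
      "normal", "normal", "normal", "MD",
      "benign", "benign", "benign", "normal"
    ),
    positive = list(
      "MD", "SD", c("MD", "SD"), "SD",
      "MD", "SD", c("MD", "SD"), "benign"
    )
  )
}

#' Classification pipeline configuration
#'
#' @param lambda_policy Where the discriminatory wavelengths and mRMR
#'   selection are computed: `"global"` (once on the full task data, the
#'   fidelity default) or `"per_fold"` (recomputed inside each training fold;
#'   leakage-safe but slower).
#' @param num_trees Trees in the ensemble classifier.
#' @param selection_trees Trees used for the out-of-bag feature-count search.
#' @param mtry Split-feature count (default floor(sqrt(p))).
#' @param bins Mutual-information discretization bins.
#' @param max_features Cap on the selected feature-set size.
#' @param auc_tol Minimum AUC improvement to keep growing the feature set.
#' @param mrmr_scheme `"MID"` or `"MIQ"`.
#' @param seed Root seed for all classifier randomness.
#' @return A list of class `oprs_task_config`.
#' @export
task_config <- function(lambda_policy = c("global", "per_fold"),
                        num_trees = 500, selection_trees = 200, mtry = NULL,
                        bins = 3, max_features = 8, auc_tol = 0.01,
                        mrmr_scheme = "MID", seed = 1) {
  structure(
    list(
      lambda_policy = match.arg(lambda_policy),
      num_trees = num_trees, selection_trees = selection_trees, mtry = mtry,
      bins = bins, max_features = max_features, auc_tol = auc_tol,
      mrmr_scheme = mrmr_scheme, seed = as.integer(seed)
    ),
    class = "oprs_task_config"
  )
}

#' Nonparametric ROC curve and AUC
#'
#' AUC in the Mann-Whitney form: the fraction of (positive, negative) pairs
#' in which the positive scores higher, ties counted one half. ROC points are
#' computed at every distinct threshold.
#'
#' @param scores Classifier scores (higher = more positive).
#' @param labels `"pos"`/`"neg"` per score.
#' @return List with `auc` and `points` (tibble `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "pos"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores) # midranks handle ties as 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  )
  list(auc = auc, points = points)
}

#' Sensitivity and specificity at the balanced threshold
#'
#' Picks the score threshold maximizing Youden's J (sensitivity +
#' specificity - 1); J-ties break toward the higher sensitivity. Percentages
#' are rounded to whole percent.
#'
#' @inheritParams roc_auc
#' @return A tibble `sensitivity_pct`, `specificity_pct`, `threshold`.
#' @export
sens_spec <- function(scores, labels) {
  pos <- labels == "pos"
  if (!any(pos) || all(pos)) abort("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  j <- sens + spec - 1
  cand <- which(j >= max(j) - 1e-12)
  best <- cand[which.max(sens[cand])]
  tibble(
    sensitivity_pct = as.integer(round(100 * sens[best])),
    specificity_pct = as.integer(round(100 * spec[best])),
    threshold = thr[best]
  )
}

fit_forest <- function(x, y, config, seed, num_trees = config$num_trees) {
  mtry <- config$mtry
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  ranger::ranger(
    x = x, y = factor(y, levels = c("neg", "pos")),
    probability = TRUE, num.trees = num_trees,
    mtry = min(mtry, ncol(x)), seed = seed, num.threads = 1
  )
}

oob_auc <- function(x, y, config, seed) {
  fit <- fit_forest(x, y, config, seed, num_trees = config$selection_trees)
  p <- fit$predictions[, "pos"]
  ok <- is.finite(p)
  roc_auc(p[ok], y[ok])$auc
}

#' Choose the feature-set size along an mRMR ranking
#'
#' Grows the feature set in rank order and stops when the ensemble's
#' out-of-bag AUC on the training data no longer improves by at least
#' `auc_tol` (default 0.01), capped at `max_features`.
#'
#' @param ranked Feature names in mRMR order.
#' @param features Feature table (columns include `ranked`).
#' @param labels `"pos"`/`"neg"` labels.
#' @param config [task_config()].
#' @return Character vector: the selected feature subset (a prefix of
#'   `ranked`).
#' @export
select_feature_count <- function(ranked, features, labels, config = task_config()) {
  if (length(ranked) == 0) abort("ranked feature list is empty")
  ranked <- head(ranked, config$max_features)
  best_auc <- -Inf
  size <- 1
  for (s in seq_along(ranked)) {
    x <- as.data.frame(features[ranked[seq_len(s)]])
    auc <- oob_auc(x, labels, config, seed = config$seed + 7919 * s)
    if (auc >= best_auc + config$auc_tol || s == 1) {
      best_auc <- auc
      size <- s
    } else {
      break
    }
  }
  ranked[seq_len(size)]
}

#' Grouped leave-one-patient-out cross-validated scores
#'
#' One fold per patient; all of a patient's measurements are held out
#' together, so no patient ever spans train and test. The classifier is a
#' seeded probability forest; the score is the predicted positive-class
#' probability.
#'
#' @param features Feature table (selected columns only).
#' @param labels `"pos"`/`"neg"` per row.
#' @param patient_id Patient of each row.
#' @param config [task_config()].
#' @return A tibble `row`, `patient_id`, `label`, `score`; rows of folds
#'   whose training data lacked a class are dropped with a warning.
#' @export
loocv_scores <- function(features, labels, patient_id, config = task_config()) {
  x <- as.data.frame(features)
  patients <- sort(unique(patient_id))
  out <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    test <- patient_id == patients[i]
    ytr <- labels[!test]
    if (length(unique(ytr)) < 2) {
      warn(paste0("fold for ", patients[i], " skipped: training set lacks a class"))
      next
    }
    fit <- fit_forest(x[!test, , drop = FALSE], ytr, config,
      seed = config$seed + i
    )
    p <- predict(fit, data = x[test, , drop = FALSE],
      num.threads = 1
    )$predictions[, "pos"]
    out[[i]] <- tibble(
      row = which(test), patient_id = patients[i],
      label = labels[test], score = unname(p)
    )
  }
  bind_rows(out)
}

task_labels <- function(manifest, task) {
  cls <- manifest$class
  labels <- rep(NA_character_, length(cls))
  labels[cls %in% task$negative[[1]]] <- "neg"
  labels[cls %in% task$positive[[1]]] <- "pos"
  labels
}

# core pipeline on an arbitrary label vector (NA = not in task); used both
# for the real labels and for permutation shuffles
run_task_labels <- function(channels, patient_id, labels, config,
                            task_id = "task") {
  subset <- which(!is.na(labels))
  lam <- discriminatory_wavelengths(channels, patient_id, labels, subset = subset)
  feats <- extract_features(channels, lam)
  fsub <- feats[subset, setdiff(names(feats), "measurement_id")]
  # drop features that are not finite everywhere (masked ratios etc.)
  keep <- vapply(fsub, function(v) all(is.finite(v)), logical(1))
  fsub <- fsub[keep]
  y <- labels[subset]
  pid <- patient_id[subset]

  if (config$lambda_policy == "global") {
    ranked <- mrmr_rank(fsub, y,
      k = min(config$max_features, ncol(fsub)),
      bins = config$bins, scheme = config$mrmr_scheme
    )
    selected <- select_feature_count(ranked, fsub, y, config)
    scores <- loocv_scores(fsub[selected], y, pid, config)
  } else {
    patients <- sort(unique(pid))
    selected <- character(0)
    pieces <- vector("list", length(patients))
    for (i in seq_along(patients)) {
      test <- pid == patients[i]
      tr_idx <- subset[!test]
      ytr <- y[!test]
      if (length(unique(ytr)) < 2) {
        warn(paste0("fold for ", patients[i], " skipped: training set lacks a class"))
        next
      }
      lam_f <- discriminatory_wavelengths(channels, patient_id, labels,
        subset = tr_idx
      )
      feats_f <- extract_features(channels, lam_f)
      ff <- feats_f[subset, setdiff(names(feats_f), "measurement_id")]
      ff <- ff[vapply(ff, function(v) all(is.finite(v)), logical(1))]
      ranked <- mrmr_rank(ff[!test, ], ytr,
        k = min(config$max_features, ncol(ff)),
        bins = config$bins, scheme = config$mrmr_scheme
      )
      sel <- select_feature_count(ranked, ff[!test, ], ytr, config)
      selected <- union(selected, sel)
      fit <- fit_forest(as.data.frame(ff[sel])[!test, , drop = FALSE], ytr,
        config,
        seed = config$seed + i
      )
      p <- predict(fit,
        data = as.data.frame(ff[sel])[test, , drop = FALSE],
        num.threads = 1
      )$predictions[, "pos"]
      pieces[[i]] <- tibble(
        row = which(test), patient_id = patients[i],
        label = y[test], score = unname(p)
      )
    }
    scores <- bind_rows(pieces)
  }

  roc <- roc_auc(scores$score, scores$label)
  ss <- sens_spec(scores$score, scores$label)
  scores$measurement_id <- channels$measurement_id[subset][scores$row]
  structure(
    list(
      task_id = task_id,
      lambda_report = lam,
      selected_features = selected,
      scores = select(scores, "measurement_id", "patient_id", "label", "score"),
      roc_points = roc$points,
      auc = roc$auc,
      sensitivity_pct = ss$sensitivity_pct,
      specificity_pct = ss$specificity_pct,
      threshold = ss$threshold,
      n = length(y),
      n_pos = sum(y == "pos"),
      config = config
    ),
    class = "oprs_task_result"
  )
}

#' Run one binary classification task
#'
#' Full per-task analysis: discriminatory-wavelength selection, feature
#' extraction, mRMR ranking, feature-count selection, grouped
#' leave-one-patient-out scoring, nonparametric ROC/AUC and the balanced
#' sensitivity/specificity operating point.
#'
#' @param channels [build_channels()] object for the standardized cohort.
#' @param manifest Cohort manifest (`measurement_id`, `patient_id`, `class`).
#' @param task One row of [binary_tasks()] or a task id string.
#' @param config [task_config()].
#' @return An `oprs_task_result`; see [glance.oprs_task_result()].
#' @export
run_task <- function(channels, manifest, task, config = task_config()) {
  if (is.character(task)) {
    task <- filter(binary_tasks(), .data$task_id == !!task)
    if (nrow(task) == 0) abort("unknown task id")
  }
  ord <- match(channels$measurement_id, manifest$measurement_id)
  if (anyNA(ord)) abort("manifest does not cover all measurements")
  run_task_labels(
    channels, manifest$patient_id[ord],
    task_labels(manifest[ord, ], task), config,
    task_id = task$task_id
  )
}

#' Run all eight binary tasks
#'
#' @inheritParams run_task
#' @param tasks Task table, default [binary_tasks()].
#' @return A list of class `oprs_task_set`: `results` (named list of
#'   `oprs_task_result`) and `summary` (one [glance] row per task).
#' @export
run_all_tasks <- function(channels, manifest, config = task_config(),
                          tasks = binary_tasks()) {
  results <- lapply(seq_len(nrow(tasks)), function(i) {
    run_task(channels, manifest, tasks[i, ], config)
  })
  names(results) <- tasks$task_id
  structure(
    list(
      results = results,
      summary = bind_rows(lapply(results, glance)),
      config = config
    ),
    class = "oprs_task_set"
  )
}

#' @export
print.oprs_task_result <- function(x, ...) {
  cat(
    "OPRS task", x$task_id, ": AUC", sprintf("%.3f", x$auc),
    "| sens/spec", paste0(x$sensitivity_pct, "%/", x$specificity_pct, "%"),
    "|", length(x$selected_features), "features, n =", x$n, "\n"
  )
  invisible(x)
}

#' @export
print.oprs_task_set <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
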