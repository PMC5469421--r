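test_that("the eight binary tasks are registered", {
  tasks <- binary_tasks()
  expect_equal(nrow(tasks), 8)
  expect_setequal(tasks$task_id, c(
    "normal_vs_MD", "normal_vs_SD", "normal_vs_MDSD", "MD_vs_SD",
    "benign_vs_MD", "benign_vs_SD", "benign_vs_MDSD", "benign_vs_normal"
  ))
  expect_equal(tasks$positive[[3]], c("MD", "SD"))
})

test_that("mutual information matches closed forms and the plug-in table value", {
  # x == y, balanced binary: MI = ln 2
  y <- rep(c("a", "b"), each = 50)
  x <- rep(c(0, 1), each = 50)
  expect_equal(mutual_information(x, y), log(2), tolerance = 1e-12)

  # 2x2 table (40, 10; 10, 40): plug-in value from the independent oracle
  x2 <- c(rep(0, 50), rep(1, 50))
  y2 <- c(rep("a", 40), rep("b", 10), rep("a", 10), rep("b", 40))
  expect_equal(
    mutual_information(x2, y2),
    unname(brute_mi(table(x2, y2))),
    tolerance = 1e-12
  )
  expect_equal(mutual_information(x2, y2), 0.1927447, tolerance = 1e-6)

  # independence: MI near zero for large n
  withr::with_seed(5, {
    xi <- rnorm(5000)
    yi <- rep(c("a", "b"), 2500)
    expect_lt(mutual_information(xi, yi), 0.002)
  })

  # constant feature: zero with warning
  expect_warning(mi0 <- mutual_information(rep(1, 10), rep(c("a", "b"), 5)), "constant")
  expect_equal(mi0, 0)
})

test_that("mRMR defers redundant copies and is column-order invariant", {
  withr::with_seed(17, {
    n <- 80
    y <- rep(c("neg", "pos"), each = n / 2)
    f1 <- ifelse(y == "pos", 1, 0) + rnorm(n, 0, 0.1)
    f2 <- f1 # exact copy: fully redundant
    f3 <- ifelse(y == "pos", 1, 0) + rnorm(n, 0, 0.8) # independent, informative
    feats <- tibble::tibble(f1 = f1, f2 = f2, f3 = f3)
    sel <- mrmr_rank(feats, y, k = 3)
    expect_equal(sel, c("f1", "f3", "f2"))

    # brute-force verification of every greedy step (MID objective)
    mi <- function(a, b) {
      mutual_information(a, as.character(b))
    }
    bin <- function(v) oprs:::discretize_ef(v, 3)
    rel <- sapply(feats, function(f) oprs:::mi_binned(bin(f), as.integer(factor(y))))
    greedy <- character(0)
    remaining <- sort(names(feats))
    while (length(remaining) > 0) {
      score <- sapply(remaining, function(f) {
        red <- if (length(greedy) == 0) 0 else {
          mean(sapply(greedy, function(s) {
            oprs:::mi_binned(bin(feats[[f]]), bin(feats[[s]]))
          }))
        }
        rel[[f]] - red
      })
      pick <- remaining[score >= max(score) - 1e-12][1]
      greedy <- c(greedy, pick)
      remaining <- setdiff(remaining, pick)
    }
    expect_equal(sel, greedy)

    # permuting columns does not change the selection
    sel_perm <- mrmr_rank(feats[c("f3", "f2", "f1")], y, k = 3)
    expect_equal(sel_perm, sel)
  })

  # single feature is returned alone
  expect_equal(
    mrmr_rank(tibble::tibble(only = rnorm(20)), rep(c("a", "b"), 10), k = 1),
    "only"
  )
  expect_error(mrmr_rank(tibble::tibble(), rep("a", 5), k = 1), "empty")
})

test_that("mRMR greedy matches exhaustive per-step search on random tables", {
  withr::with_seed(29, {
    for (rep in 1:10) {
      n <- 60
      p <- sample(4:10, 1)
      y <- sample(rep(c("neg", "pos"), each = n / 2))
      feats <- as.data.frame(matrix(rnorm(n * p), n, p))
      names(feats) <- sprintf("v%02d", seq_len(p))
      feats$v01 <- feats$v01 + 2 * (y == "pos")
      sel <- mrmr_rank(feats, y, k = p)

      bin <- function(v) oprs:::discretize_ef(v, 3)
      iy <- as.integer(factor(y))
      rel <- sapply(feats, function(f) oprs:::mi_binned(bin(f), iy))
      greedy <- character(0)
      remaining <- sort(names(feats))
      while (length(remaining) > 0) {
        score <- sapply(remaining, function(f) {
          red <- if (length(greedy) == 0) 0 else {
            mean(sapply(greedy, function(s) {
              oprs:::mi_binned(bin(feats[[f]]), bin(feats[[s]]))
            }))
          }
          rel[[f]] - red
        })
        pick <- remaining[score >= max(score) - 1e-12][1]
        greedy <- c(greedy, pick)
        remaining <- setdiff(remaining, pick)
      }
      expect_equal(sel, greedy)
    }
  })
})

test_that("ROC AUC equals brute-force pair counting", {
  # worked example: AUC = 0.75
  labels <- c("neg", "neg", "pos", "pos")
  scores <- c(0.1, 0.4, 0.35, 0.8)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, 0.75)
  expect_equal(brute_auc(scores, labels), 0.75)

  # perfect separation and all-ties
  expect_equal(roc_auc(c(1, 2, 3, 4), c("neg", "neg", "pos", "pos"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("neg", "pos"), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("pos", 3)), "both classes")

  # ROC points span (0,0) to (1,1)
  expect_equal(min(r$points$fpr), 0)
  expect_equal(max(r$points$fpr), 1)
  expect_equal(max(r$points$tpr), 1)

  # property: exact agreement with pair counting on random instances
  withr::with_seed(41, {
    for (i in 1:100) {
      n <- sample(4:20, 1)
      labs <- sample(c("neg", "pos"), n, replace = TRUE)
      if (length(unique(labs)) < 2) labs[1:2] <- c("neg", "pos")
      sc <- round(runif(n), 2) # coarse scores force ties
      expect_equal(roc_auc(sc, labs)$auc, brute_auc(sc, labs))
    }
  })
})

test_that("sensitivity/specificity picks the Youden point with high-sensitivity ties", {
  # worked example: J ties at 0.5; higher-sensitivity side wins
  ss <- sens_spec(c(0.1, 0.4, 0.35, 0.8), c("neg", "neg", "pos", "pos"))
  expect_equal(ss$sensitivity_pct, 100L)
  expect_equal(ss$specificity_pct, 50L)

  # perfect separation: 100/100
  ss2 <- sens_spec(c(1, 2, 10, 11), c("neg", "neg", "pos", "pos"))
  expect_equal(c(ss2$sensitivity_pct, ss2$specificity_pct), c(100L, 100L))

  # shift invariance (rank statistic)
  ss3 <- sens_spec(c(0.1, 0.4, 0.35, 0.8) + 5, c("neg", "neg", "pos", "pos"))
  expect_equal(ss3$sensitivity_pct, ss$sensitivity_pct)
  expect_equal(ss3$specificity_pct, ss$specificity_pct)
})

test_that("feature-count selection stops early and respects the cap", {
  withr::with_seed(53, {
    n <- 60
    y <- rep(c("neg", "pos"), each = n / 2)
    cfg <- task_config(seed = 2, selection_trees = 100)
    # one perfectly separating feature: size 1
    feats <- tibble::tibble(
      perfect = ifelse(y == "pos", 1, 0),
      noise1 = rnorm(n), noise2 = rnorm(n)
    )
    sel <- select_feature_count(c("perfect", "noise1", "noise2"), feats, y, cfg)
    expect_equal(sel, "perfect")

    # all-noise features: no growth beyond the first
    noise <- tibble::tibble(
      a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n)
    )
    sel_noise <- select_feature_count(c("a", "b", "c", "d"), noise, y, cfg)
    expect_equal(length(sel_noise), 1)

    # cap: never more than max_features even with many informative features
    many <- as.data.frame(matrix(rnorm(n * 20), n, 20))
    names(many) <- sprintf("g%02d", 1:20)
    for (j in 1:20) many[[j]] <- many[[j]] + 0.3 * j * (y == "pos")
    sel_many <- select_feature_count(names(many), many, y, cfg)
    expect_lte(length(sel_many), 8)
  })
  expect_error(select_feature_count(character(0), tibble::tibble(), "y"), "empty")
})

test_that("grouped LOOCV never leaks a patient across train and test", {
  co <- small_cohort(seed = 19)
  ch <- standardized_channels(co)
  res <- run_task(ch, co$manifest, "normal_vs_MDSD", task_config(seed = 4, num_trees = 100))

  # every task measurement scored exactly once
  task_ids <- co$manifest$measurement_id[
    co$manifest$class %in% c("normal", "MD", "SD")
  ]
  expect_setequal(res$scores$measurement_id, task_ids)
  expect_equal(anyDuplicated(res$scores$measurement_id), 0)

  # fold label equals the patient of the held-out measurement: no overlap
  joined <- dplyr::left_join(
    res$scores,
    dplyr::select(co$manifest, measurement_id, true_pat = patient_id),
    by = "measurement_id"
  )
  expect_true(all(joined$patient_id == joined$true_pat))

  # folds = patients
  expect_equal(
    sort(unique(res$scores$patient_id)),
    sort(unique(co$manifest$patient_id))
  )

  # strong synthetic separation gives high out-of-fold AUC
  expect_gte(res$auc, 0.95)

  # determinism: identical rerun
  res2 <- run_task(ch, co$manifest, "normal_vs_MDSD", task_config(seed = 4, num_trees = 100))
  expect_identical(res$scores, res2$scores)
  expect_identical(glance(res), glance(res2))
})

test_that("per-fold policy recomputes selection inside each fold", {
  co <- small_cohort(seed = 23)
  ch <- standardized_channels(co)
  cfg <- task_config(
    lambda_policy = "per_fold", num_trees = 100, selection_trees = 50,
    max_features = 4, seed = 6
  )
  res <- run_task(ch, co$manifest, "normal_vs_MDSD", cfg)
  expect_true(res$auc >= 0 && res$auc <= 1)
  expect_gt(length(res$selected_features), 0)
  # strong dysplasia effect still detected without global leakage
  expect_gte(res$auc, 0.85)
})

test_that("permutation shuffles preserve class counts and detect real signal", {
  co <- small_cohort(seed = 29)
  ch <- standardized_channels(co)
  cfg <- task_config(
    lambda_policy = "per_fold", num_trees = 100, selection_trees = 50,
    max_features = 4, seed = 8
  )
  perm <- permutation_test(ch, co$manifest, "normal_vs_MDSD", cfg,
    n_shuffles = 20, seed = 9
  )
  expect_length(perm$shuffled_auc, 20)
  expect_true(all(perm$shuffled_auc >= 0 & perm$shuffled_auc <= 1))
  # informative cohort: the real AUC clears the shuffled band
  expect_true(perm$pass)
  expect_gt(perm$real_auc, perm$mean_shuffled + 2 * perm$sd_shuffled)
  expect_error(
    permutation_test(ch, co$manifest, "normal_vs_MDSD", cfg, n_shuffles = 1),
    "n_shuffles"
  )

  # label histogram preservation is structural: a shuffle is a permutation
  labs <- c(rep("neg", 10), rep("pos", 5))
  shuffled <- withr::with_seed(3, sample(labs))
  expect_equal(as.vector(table(shuffled)), as.vector(table(labs)))
})

test_that("tidy and glance methods summarize results", {
  co <- small_cohort(seed = 31)
  ch <- standardized_channels(co)
  res <- run_task(ch, co$manifest, "normal_vs_SD", task_config(seed = 2, num_trees = 100))
  td <- tidy(res)
  expect_equal(td$feature, res$selected_features)
  gl <- glance(res)
  expect_equal(gl$auc, res$auc)
  expect_equal(gl$task_id, "normal_vs_SD")
  expect_s3_class(autoplot(res), "ggplot")
})
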