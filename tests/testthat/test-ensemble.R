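# raw-intensity training fixture with three pole classes, patient-nested
pole_fixture <- function(n_per_class = 8, tp = 2, p = 40, effect = 2,
                         seed = 1, noise = 0.4) {
  set.seed(seed)
  classes <- c("cholestatic", "hepatocellular", "recovered")
  base <- runif(p, 12, 16)
  dc <- c(rep(effect, 6), rep(0, p - 6))
  dh <- c(rep(0, 6), rep(effect, 6), rep(0, p - 12))
  rows <- list(); labels <- character(); patients <- character()
  for (ci in seq_along(classes)) for (i in seq_len(n_per_class)) {
    pid <- sprintf("%s%02d", substr(classes[ci], 1, 1), i)
    for (t in seq_len(tp)) {
      w <- switch(ci, c(1, 0), c(0, 1), c(0, 0))
      rows[[length(rows) + 1]] <-
        2^(base + w[1] * dc + w[2] * dh + rnorm(p, 0, noise))
      labels <- c(labels, classes[ci]); patients <- c(patients, pid)
    }
  }
  x <- do.call(rbind, rows)
  dimnames(x) <- list(sprintf("s%03d", seq_len(nrow(x))), paste0("F", 1:p))
  list(x = x, labels = labels, patients = patients)
}

test_that("subject folds partition patients and never split one", {
  ids <- sprintf("P%02d", 1:11)
  plan <- make_subject_folds(ids, k = 3, seed = 5)
  expect_length(plan$folds, 3)
  expect_setequal(unlist(plan$folds), ids)
  expect_identical(anyDuplicated(unlist(plan$folds)), 0L)
  sizes <- lengths(plan$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(plan, make_subject_folds(ids, 3, seed = 5))
  expect_false(identical(plan$folds, make_subject_folds(ids, 3, seed = 6)$folds))
  expect_error(make_subject_folds(ids[1:2], 3), "exceeds")
})

test_that("latent-variable selection tracks signal strength", {
  fx <- pole_fixture(n_per_class = 10, seed = 2)
  y <- ifelse(fx$labels == "cholestatic", 1, -1)
  sel <- select_n_lv(fx$x, y, fx$patients, k = 4, max_lv = 5, seed = 3)
  expect_gte(sel$n_lv, 1); expect_lte(sel$n_lv, 5)
  expect_gt(max(sel$curve, na.rm = TRUE), 0.9)
  # the 1-SE rule never picks a larger model than the argmax
  sel_max <- select_n_lv(fx$x, y, fx$patients, k = 4, max_lv = 5, seed = 3,
                         rule = "max")
  expect_lte(sel$n_lv, sel_max$n_lv)
  expect_identical(select_n_lv(fx$x, y, fx$patients, k = 4, max_lv = 1,
                               seed = 3)$n_lv, 1L)
})

test_that("pure-noise labels stay inside the binomial chance band", {
  fx <- pole_fixture(n_per_class = 10, effect = 0, seed = 7)
  set.seed(8)
  y <- sample(c(1, -1), length(fx$labels), replace = TRUE)
  sel <- select_n_lv(fx$x, y, fx$patients, k = 4, max_lv = 4, seed = 9)
  n <- length(y)
  band <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(max(sel$curve, na.rm = TRUE), band[1] - 0.25)
  expect_lte(max(sel$curve, na.rm = TRUE), band[2] + 0.1)
})

test_that("one-vs-rest training recovers informative features via VIP", {
  fx <- pole_fixture(n_per_class = 10, seed = 4)
  m <- train_ovr(fx$x, fx$labels, fx$patients, "cholestatic", k_inner = 4,
                 max_lv = 4, seed = 5)
  # the 6 C-informative features should be VIP-selected
  expect_gte(mean(paste0("F", 1:6) %in% m$selected_features), 0.7)
  expect_true(all(m$selected_features %in% colnames(fx$x)))
  expect_identical(length(m$model$feature_ids), length(m$selected_features))
  # vip threshold 0 keeps every stage-1 feature
  m0 <- train_ovr(fx$x, fx$labels, fx$patients, "cholestatic", k_inner = 4,
                  max_lv = 3, vip_threshold = 0, seed = 5)
  expect_setequal(m0$selected_features, m0$stage1$model$feature_ids)
  expect_error(train_ovr(fx$x, fx$labels, fx$patients, "cholestatic",
                         vip_threshold = 99, k_inner = 4, seed = 5),
               "VIP")
})

test_that("the ensemble trains three models and excludes mixed patients", {
  fx <- pole_fixture(n_per_class = 8, seed = 6)
  # relabel two whole patients as mixed
  mixed_pat <- unique(fx$patients)[c(1, 12)]
  fx$labels[fx$patients %in% mixed_pat] <- "mixed"
  ens <- train_ensemble(fx$x, fx$labels, fx$patients, k_inner = 3,
                        max_lv = 3, seed = 2)
  expect_named(ens$models, c("cholestatic", "hepatocellular", "recovered"))
  expect_setequal(ens$excluded_patients, mixed_pat)
  expect_false(any(ens$training_samples %in%
                     rownames(fx$x)[fx$patients %in% mixed_pat]))
  for (m in ens$models) expect_true(is.finite(m$cv_accuracy))
  # retraining with the same seed is identical
  ens2 <- train_ensemble(fx$x, fx$labels, fx$patients, k_inner = 3,
                         max_lv = 3, seed = 2)
  expect_identical(lapply(ens$models, function(m) m$model$coefficients),
                   lapply(ens2$models, function(m) m$model$coefficients))
  expect_error(train_ensemble(fx$x, fx$labels, fx$patients,
                              k_inner = 3, seed = 2,
                              vip_threshold = 1e6), "VIP")
  expect_error(train_ensemble(fx$x[fx$labels == "recovered", ],
                              fx$labels[fx$labels == "recovered"],
                              fx$patients[fx$labels == "recovered"]),
               "missing class")
})

test_that("pure-pole samples are predicted as their own pole", {
  fx <- pole_fixture(n_per_class = 10, seed = 3)
  ens <- train_ensemble(fx$x, fx$labels, fx$patients, k_inner = 4,
                        max_lv = 3, seed = 1)
  pr <- predict(ens, fx$x)
  expect_gte(mean(pr$class == fx$labels), 0.9)
  # membership triple of a cholestatic sample peaks on the C column
  csamp <- which(fx$labels == "cholestatic")
  expect_gte(mean(max.col(pr$membership[csamp, ]) == 1), 0.9)
})

test_that("double CV predicts each sample exactly once and stays subject-wise", {
  fx <- pole_fixture(n_per_class = 8, seed = 9)
  dcv <- suppressWarnings(
    double_cv_evaluate(fx$x, fx$labels, fx$patients, k_outer = 4,
                       k_inner = 3, seed = 11, max_lv = 3))
  expect_setequal(dcv$predictions$sample_id, rownames(fx$x))
  expect_identical(anyDuplicated(dcv$predictions$sample_id), 0L)
  # patients never straddle folds
  by_pat <- split(dcv$predictions$outer_fold, dcv$predictions$patient_id)
  expect_true(all(vapply(by_pat, function(f) length(unique(f)) == 1, TRUE)))
  expect_gte(dcv$balanced_accuracy, 0.8)
  expect_identical(sum(dcv$confusion), sum(fx$labels %in% colnames(dcv$confusion)))
  # determinism
  dcv2 <- suppressWarnings(
    double_cv_evaluate(fx$x, fx$labels, fx$patients, k_outer = 4,
                       k_inner = 3, seed = 11, max_lv = 3))
  expect_identical(dcv$predictions, dcv2$predictions)
})

test_that("ensembles survive a JSON round trip with identical predictions", {
  fx <- pole_fixture(n_per_class = 6, seed = 10)
  ens <- train_ensemble(fx$x, fx$labels, fx$patients, k_inner = 3,
                        max_lv = 2, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, f)
  back <- read_ensemble(f)
  pr1 <- predict(ens, fx$x)
  pr2 <- predict(back, fx$x)
  expect_equal(pr2$membership, pr1$membership, tolerance = 1e-12)
  expect_identical(pr2$class, pr1$class)
})

test_that("VIP selection recovers the generating informative features", {
  sim <- simulate_cohort(small_config(seed = 13))
  rec <- sim$cohort$records
  labels <- classify_cohort(sim$cohort)$calls$label
  pt <- sim$cohort$peak_table
  x <- pt$intensities[match(rec$sample_id, pt$sample_ids), ]
  rownames(x) <- rec$sample_id
  classes <- c("cholestatic", "hepatocellular", "recovered")
  mixed_pat <- unique(rec$patient_id[labels == "mixed"])
  keep <- labels %in% classes & !(rec$patient_id %in% mixed_pat)
  m <- train_ovr(x[keep, ], labels[keep], rec$patient_id[keep],
                 "cholestatic", k_inner = 4, seed = 2)
  truth_c <- attr(sim$truth, "informative_c")
  expect_gte(mean(truth_c %in% m$selected_features), 0.7)
})
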