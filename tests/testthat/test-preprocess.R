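test_that("flat QC trends leave intensities essentially unchanged", {
  set.seed(1)
  p <- 6
  base <- runif(p, 1e3, 1e4)
  m <- matrix(rep(base, each = 20), 20, p)   # constant across injections
  m[7, 2] <- NA
  roles <- rep("study", 20); roles[c(1, 6, 11, 16, 20)] <- "qc"
  pt <- peak_table(m, role = roles,
                   feature_ids = paste0("F", 1:p))
  out <- qc_svrc_correct(pt, min_qc = 4)
  rel <- abs(out$peak_table$intensities / pt$intensities - 1)
  expect_lt(max(rel, na.rm = TRUE), 1e-6)
  expect_true(is.na(out$peak_table$intensities[7, 2]))
})

test_that("correction halves QC dispersion under strong linear drift", {
  pt <- qc_peak_table(n_study = 40, p = 20, noise = 0.03)
  drifted <- corrupt_with_drift(pt, amplitude = 0.5, seed = 3)
  out <- qc_svrc_correct(drifted)
  rsd_before <- qc_rsd(drifted)
  rsd_after <- qc_rsd(out$peak_table)
  expect_lte(median(rsd_after), 0.5 * median(rsd_before))
  # corrected intensities stay nonnegative and missingness is untouched
  expect_true(all(out$peak_table$intensities >= 0, na.rm = TRUE))
  expect_identical(is.na(out$peak_table$intensities), is.na(drifted$intensities))
})

test_that("insufficient QCs flag the feature and pass values through", {
  pt <- qc_peak_table(n_study = 15, p = 4, qc_every = 50)  # only 2 interleaved
  expect_identical(sum(pt$role == "qc"), 2L)
  out <- qc_svrc_correct(pt, min_qc = 5)
  expect_true(all(out$report$status == "skipped_insufficient_qc"))
  expect_identical(out$peak_table$intensities, pt$intensities)
  no_qc <- peak_table(pt$intensities[pt$role == "study", ])
  expect_error(qc_svrc_correct(no_qc), "no QC samples")
})

test_that("correction is independent across batches", {
  pt <- qc_peak_table(n_study = 30, p = 8, seed = 7)
  two <- peak_table(rbind(pt$intensities, pt$intensities * 1.3),
                    sample_ids = c(pt$sample_ids, paste0("x", pt$sample_ids)),
                    feature_ids = pt$feature_ids,
                    batch = rep(c("B1", "B2"), each = length(pt$sample_ids)),
                    injection_order = rep(pt$injection_order, 2),
                    role = rep(pt$role, 2))
  swapped <- subset_peak_table(two, samples = rev(seq_along(two$sample_ids)))
  a <- qc_svrc_correct(two)$peak_table
  b <- qc_svrc_correct(swapped)$peak_table
  expect_equal(a$intensities[a$sample_ids, ],
               b$intensities[a$sample_ids, ])
})

test_that("blank and missingness filters drop the right features", {
  set.seed(2)
  m <- matrix(runif(60, 5e3, 6e3), 10, 6)
  m[9:10, ] <- runif(12, 50, 150)              # blanks near-empty overall
  m[, 2] <- c(rep(100, 8), 5e3, 5e3)           # strong in blanks only
  m[1:5, 3] <- NA                              # 62.5% missing among study
  roles <- c(rep("study", 8), "blank", "blank")
  pt <- peak_table(m, role = roles)
  out <- filter_features(pt, blank_ratio = 3, max_missing = 0.5)
  expect_setequal(out$dropped$feature_id, c("F2", "F3"))
  expect_identical(out$dropped$reason[out$dropped$feature_id == "F2"], "blank")
  expect_identical(out$dropped$reason[out$dropped$feature_id == "F3"],
                   "missingness")
  expect_identical(ncol(out$peak_table$intensities), 4L)
  # without blanks the blank filter is skipped with a warning
  pt2 <- peak_table(m[1:8, ], role = rep("study", 8))
  expect_warning(out2 <- filter_features(pt2), "blank filter skipped")
  expect_true("F3" %in% out2$dropped$feature_id)
  expect_false("F2" %in% out2$dropped$feature_id)
})

test_that("scaling parameters come from train only and invert exactly", {
  set.seed(3)
  train <- matrix(10^runif(80, 2, 5), 20, 4,
                  dimnames = list(NULL, paste0("F", 1:4)))
  train[3, 1] <- NA
  test <- matrix(10^runif(40, 2, 5), 10, 4,
                 dimnames = list(NULL, paste0("F", 1:4)))
  out <- impute_and_scale(train, test)
  expect_equal(unname(colMeans(out$train)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(out$train, 2, sd)), rep(1, 4), tolerance = 1e-9)
  # imputed value is half the train minimum of that feature
  tmin <- min(train[, 1], na.rm = TRUE)
  expect_equal(out$scaler$impute[["F1"]], tmin / 2)
  # round trip on complete cells
  back <- unscale(out$scaler, out$train)
  expect_equal(back[-3, 1], train[-3, 1], tolerance = 1e-9)
  expect_equal(back[, 2], train[, 2], tolerance = 1e-9)
  # constant feature excluded with a warning
  train2 <- cbind(train, Fc = rep(100, 20))
  expect_warning(out2 <- impute_and_scale(train2), "excluded")
  expect_identical(out2$scaler$excluded, "Fc")
})

test_that("Welch/BH screen matches base R on a small case", {
  set.seed(4)
  x <- matrix(rnorm(60), 12, 5,
              dimnames = list(paste0("S", 1:12), paste0("F", 1:5)))
  x[1:6, 2] <- x[1:6, 2] + 3
  res <- univariate_screen(x, 1:6, 7:12)
  for (j in 1:5) {
    ref <- t.test(x[1:6, j], x[7:12, j])   # Welch by default
    expect_equal(res$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-12)
  }
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_true(res$selected[2])
  expect_error(univariate_screen(x, 1, 2:12), "at least 2")
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  # p = (.01,.02,.03,.04), m = 4: q_i = min_{j>=i} p_j * m / j = 0.04 for all
  pv <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(pv, "BH"), rep(0.04, 4))
  set.seed(9)
  x <- matrix(rnorm(200), 10, 20)
  res <- univariate_screen(x, 1:5, 6:10)
  expect_true(all(res$q >= res$p))
  # monotone: ordering by q preserves ordering by p
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-15))
})

test_that("identical groups give zero statistics and unit p values", {
  x <- matrix(rnorm(40), 8, 5)
  x[5:8, ] <- x[1:4, ]
  res <- univariate_screen(x, 1:4, 5:8)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
})
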