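#' Subject-wise cross-validation folds
#'
#' Deals patients (not samples) into `k` folds, so that all samples collected
#' from one patient always travel together — the requirement for honest
#' out-of-sample error with repeated-measures cohorts. Patients are shuffled
#' with the seed and dealt round-robin.
#'
#' @param patient_ids Character vector of unique patient identifiers.
#' @param k Number of folds, at most `length(patient_ids)`.
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `folds` (list of k character vectors of
#'   patient ids), `k`, `seed`.
#' @export
make_subject_folds <- function(patient_ids, k, seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  if (k > length(patient_ids))
    stop("k (", k, ") exceeds number of patients (", length(patient_ids), ")")
  if (k < 2) stop("k must be at least 2")
  set.seed(seed)
  shuffled <- sample(patient_ids)
  folds <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  structure(list(folds = unname(folds), k = k, seed = seed),
            class = "fold_plan")
}

# pooled CV accuracy for each 1..max_lv; scaling refitted inside every fold
.inner_cv_curve <- function(x_raw, y, patients, k, max_lv, seed) {
  plan <- make_subject_folds(patients, k, seed)
  acc <- matrix(NA_real_, plan$k, max_lv)
  n_val <- integer(plan$k)
  used <- 0L
  for (f in seq_len(plan$k)) {
    val <- patients %in% plan$folds[[f]]
    ytr <- y[!val]
    if (length(unique(ytr)) < 2 || length(unique(y[val])) < 1) {
      warning("inner fold ", f, " degenerate (single class); skipped",
              call. = FALSE)
      next
    }
    sc <- impute_and_scale(x_raw[!val, , drop = FALSE],
                           x_raw[val, , drop = FALSE])
    a_max <- min(max_lv, qr(sc$train)$rank)
    fit <- tryCatch(fit_pls(sc$train, ytr, a_max), error = function(e) NULL)
    if (is.null(fit)) next
    used <- used + 1L
    n_val[f] <- sum(val)
    for (a in seq_len(fit$n_lv)) {
      pred <- predict(fit, sc$newdata, n_lv = a)
      acc[f, a] <- mean(sign(pred) == y[val])
    }
  }
  if (used == 0L) stop("all inner folds degenerate")
  list(acc = acc, n_val = n_val)
}

#' Select the number of latent variables by inner cross-validation
#'
#' For each candidate count of latent variables the subject-wise inner-CV
#' classification accuracy (decision threshold 0 on the `+1/-1` encoded
#' prediction) is estimated, with imputation and autoscaling refitted inside
#' every fold. The chosen complexity is the smallest count whose mean
#' accuracy is within one standard error of the maximum (`rule = "1se"`), or
#' the argmax (`rule = "max"`, ties to the smaller count).
#'
#' @param x_raw Raw-scale feature matrix of the training samples.
#' @param y Encoded class vector (`+1/-1`).
#' @param patients Patient id per row of `x_raw`.
#' @param k Inner fold count.
#' @param max_lv Largest candidate.
#' @param seed Seed for the fold deal.
#' @param rule `"1se"` or `"max"`.
#' @return List with `n_lv` (selected), `curve` (mean accuracy per candidate),
#'   `se` (standard errors).
#' @export
select_n_lv <- function(x_raw, y, patients, k = 5, max_lv = 8, seed = 1L,
                        rule = c("1se", "max")) {
  rule <- match.arg(rule)
  stopifnot(max_lv >= 1)
  cv <- .inner_cv_curve(x_raw, y, patients, k, max_lv, seed)
  curve <- colMeans(cv$acc, na.rm = TRUE)
  nf <- colSums(!is.na(cv$acc))
  se <- apply(cv$acc, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nf, 1))
  ok <- which(!is.nan(curve))
  if (!length(ok)) stop("no usable accuracy estimates")
  best <- ok[which.max(curve[ok])]
  n_lv <- if (rule == "max") ok[which.max(curve[ok])] else {
    thr <- curve[best] - ifelse(is.finite(se[best]), se[best], 0)
    min(ok[curve[ok] >= thr])
  }
  list(n_lv = n_lv, curve = curve, se = se)
}

#' Train one one-vs-rest PLS-DA model with VIP refitting
#'
#' Stage 1 fits a PLS-DA model of the target class against the rest on all
#' features, with the number of latent variables chosen by subject-wise inner
#' cross-validation. Variable importance in projection (VIP) is computed on
#' that model, and stage 2 refits — scaler included — on the features with
#' VIP at or above the threshold. Rows from mixed-type patients must already
#' be excluded.
#'
#' @param x_raw Raw-scale training matrix (samples x features).
#' @param labels Per-row class label.
#' @param patients Per-row patient id.
#' @param target_class The class this model separates from the rest.
#' @param k_inner Inner folds for complexity selection.
#' @param max_lv Largest candidate complexity.
#' @param vip_threshold Keep features with VIP >= this (default 1).
#' @param seed Seed for the inner fold deal.
#' @param lv_rule Complexity rule passed to [select_n_lv()].
#' @return An `ovr_model`: list with `target_class`, `n_lv`, `cv_curve`,
#'   `cv_accuracy`, `selected_features`, `vip` (stage-1 scores), `scaler`
#'   (stage-2), `model` (stage-2 `pls_model`), `stage1` (list: `scaler`,
#'   `model`).
#' @export
train_ovr <- function(x_raw, labels, patients, target_class, k_inner = 5,
                      max_lv = 8, vip_threshold = 1, seed = 1L,
                      lv_rule = c("1se", "max")) {
  lv_rule <- match.arg(lv_rule)
  y <- ifelse(labels == target_class, 1, -1)
  if (length(unique(y)) < 2)
    stop("target class '", target_class, "' absent or universal in training rows")
  sel <- select_n_lv(x_raw, y, patients, k = k_inner, max_lv = max_lv,
                     seed = seed, rule = lv_rule)
  sc1 <- impute_and_scale(x_raw)
  a1 <- min(sel$n_lv, qr(sc1$train)$rank)
  m1 <- fit_pls(sc1$train, y, a1)
  vip <- vip_scores(m1)
  keep <- names(vip)[vip >= vip_threshold]
  if (!length(keep))
    stop("no feature reaches VIP >= ", vip_threshold,
         "; lower the threshold")
  sc2 <- impute_and_scale(x_raw[, keep, drop = FALSE])
  a2 <- min(a1, qr(sc2$train)$rank)
  m2 <- fit_pls(sc2$train, y, a2)
  structure(list(target_class = target_class, n_lv = a2, cv_curve = sel$curve,
                 cv_accuracy = sel$curve[sel$n_lv],
                 selected_features = keep, vip = vip, scaler = sc2$scaler,
                 model = m2,
                 stage1 = list(scaler = sc1$scaler, model = m1)),
            class = "ovr_model")
}

#' @export
print.ovr_model <- function(x, ...) {
  cat("<ovr_model> ", x$target_class, " vs rest: ", x$n_lv, " LV(s), ",
      length(x$selected_features), " VIP-selected feature(s), inner-CV accuracy ",
      sprintf("%.3f", x$cv_accuracy), "\n", sep = "")
  invisible(x)
}

#' Train the three-model one-vs-rest phenotype ensemble
#'
#' Fits one PLS-DA model per phenotype pole: hepatocellular versus
#' (cholestatic + recovered), cholestatic versus (hepatocellular +
#' recovered), and recovered versus (cholestatic + hepatocellular). Rows
#' whose label is not one of the three pole classes (mixed, unclassifiable)
#' are dropped from training, as are *all* rows of any patient with a
#' mixed-type sample.
#'
#' @param x_raw Raw-scale matrix of study samples x features.
#' @param labels Per-row clinical label.
#' @param patients Per-row patient id.
#' @inheritParams train_ovr
#' @return A `phenotype_ensemble`: list of the three `ovr_model`s (named
#'   `cholestatic`, `hepatocellular`, `recovered`) plus `classes`,
#'   `excluded_patients`, `training_samples`.
#' @export
train_ensemble <- function(x_raw, labels, patients, k_inner = 5, max_lv = 8,
                           vip_threshold = 1, seed = 1L,
                           lv_rule = c("1se", "max")) {
  lv_rule <- match.arg(lv_rule)
  classes <- c("cholestatic", "hepatocellular", "recovered")
  mixed_patients <- unique(patients[labels == "mixed"])
  keep <- labels %in% classes & !(patients %in% mixed_patients)
  if (!all(classes %in% labels[keep]))
    stop("training rows missing class(es): ",
         paste(setdiff(classes, labels[keep]), collapse = ", "))
  xr <- x_raw[keep, , drop = FALSE]
  lab <- labels[keep]; pat <- patients[keep]
  models <- lapply(classes, function(cl)
    train_ovr(xr, lab, pat, cl, k_inner = k_inner, max_lv = max_lv,
              vip_threshold = vip_threshold, seed = seed, lv_rule = lv_rule))
  names(models) <- classes
  structure(list(models = models, classes = classes,
                 excluded_patients = mixed_patients,
                 training_samples = rownames(xr) %||% which(keep)),
            class = "phenotype_ensemble")
}

#' @export
print.phenotype_ensemble <- function(x, ...) {
  cat("<phenotype_ensemble> three one-vs-rest PLS-DA models\n")
  for (m in x$models)
    cat(sprintf("  %-14s %d LV(s), %4d features, inner-CV accuracy %.3f\n",
                m$target_class, m$n_lv, length(m$selected_features),
                m$cv_accuracy))
  invisible(x)
}

#' Predict raw and membership-scale phenotype triples
#'
#' Applies the three one-vs-rest models to new samples. Each model returns an
#' unbounded predicted value on its `+1/-1` encoding; the membership scale
#' `(yhat + 1) / 2` re-expresses it as an approximate degree of class
#' membership in `[0, 1]`, which is what the ternary mapping consumes.
#'
#' @param object A `phenotype_ensemble`.
#' @param newdata Raw-scale matrix over at least the models' features.
#' @param ... Unused.
#' @return A list with `raw` (n x 3 matrix of encoded-scale predictions,
#'   columns C/H/R order `cholestatic`, `hepatocellular`, `recovered`),
#'   `membership` (same on the 0-1 scale), and `class` (argmax of the
#'   membership triple).
#' @export
predict.phenotype_ensemble <- function(object, newdata, ...) {
  raw <- sapply(object$models, function(m)
    predict(m$model, apply_scaler(m$scaler, newdata)))
  raw <- matrix(raw, ncol = 3,
                dimnames = list(rownames(newdata), object$classes))
  membership <- (raw + 1) / 2
  cls <- object$classes[max.col(membership, ties.method = "first")]
  list(raw = raw, membership = membership, class = cls)
}

#' Double (nested) cross-validation of the phenotype ensemble
#'
#' The outer loop holds out whole patients; inside each outer training
#' partition the full model-building recipe — imputation, scaling, complexity
#' selection by inner subject-wise CV, VIP feature selection, refitting — is
#' rerun from scratch, and the held-out patients are predicted exactly once.
#' Mixed-type and unclassifiable samples never enter any training partition;
#' their predictions are collected from the fold in which their patient was
#' held out (patients excluded from training everywhere are predicted by
#' every fold and averaged).
#'
#' @param x_raw Raw-scale matrix of study samples x features (rownames =
#'   sample ids).
#' @param labels Per-row clinical label.
#' @param patients Per-row patient id.
#' @param k_outer,k_inner Outer and inner fold counts.
#' @param seed Seed; outer and inner deals derive from it.
#' @param max_lv,vip_threshold,lv_rule Passed to [train_ovr()].
#' @return A `dcv_result`: list with `predictions` (data frame: `sample_id`,
#'   `patient_id`, `label`, `predicted`, `y_c`, `y_h`, `y_r` membership
#'   triple, `outer_fold`), `confusion` (3x3 table over the pole classes),
#'   `accuracy` (overall), `balanced_accuracy`, `per_class` (recall),
#'   `fold_details` (per fold: selected LV counts and feature counts).
#' @export
double_cv_evaluate <- function(x_raw, labels, patients, k_outer = 5,
                               k_inner = 5, seed = 1L, max_lv = 8,
                               vip_threshold = 1, lv_rule = c("1se", "max")) {
  lv_rule <- match.arg(lv_rule)
  x_raw <- as.matrix(x_raw)
  if (is.null(rownames(x_raw)))
    rownames(x_raw) <- paste0("S", seq_len(nrow(x_raw)))
  classes <- c("cholestatic", "hepatocellular", "recovered")
  mixed_patients <- unique(patients[labels == "mixed"])
  eligible <- labels %in% classes & !(patients %in% mixed_patients)
  elig_patients <- unique(patients[eligible])
  plan <- make_subject_folds(elig_patients, k_outer, seed)
  never_trained <- setdiff(unique(patients), elig_patients)

  pred_rows <- list(); fold_details <- list()
  acc_membership <- matrix(0, nrow(x_raw), 3,
                           dimnames = list(rownames(x_raw), classes))
  acc_count <- numeric(nrow(x_raw))
  for (f in seq_len(plan$k)) {
    test_pat <- c(plan$folds[[f]], never_trained)
    tr <- eligible & !(patients %in% test_pat)
    te <- patients %in% test_pat
    ens <- train_ensemble(x_raw[tr, , drop = FALSE], labels[tr], patients[tr],
                          k_inner = k_inner, max_lv = max_lv,
                          vip_threshold = vip_threshold,
                          seed = seed + f, lv_rule = lv_rule)
    pr <- predict(ens, x_raw[te, , drop = FALSE])
    te_idx <- which(te)
    acc_membership[te_idx, ] <- acc_membership[te_idx, ] + pr$membership
    acc_count[te_idx] <- acc_count[te_idx] + 1
    own <- patients[te] %in% plan$folds[[f]]
    pred_rows[[f]] <- data.frame(
      sample_id = rownames(x_raw)[te_idx][own],
      patient_id = patients[te_idx][own],
      label = labels[te_idx][own],
      predicted = pr$class[own],
      y_c = pr$membership[own, 1], y_h = pr$membership[own, 2],
      y_r = pr$membership[own, 3],
      outer_fold = f, stringsAsFactors = FALSE)
    fold_details[[f]] <- data.frame(
      outer_fold = f, class = classes,
      n_lv = vapply(ens$models, `[[`, 0L, "n_lv"),
      n_features = vapply(ens$models, function(m)
        length(m$selected_features), 0L),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  # patients outside every training partition: average over folds
  if (length(never_trained)) {
    idx <- which(patients %in% never_trained)
    mem <- acc_membership[idx, , drop = FALSE] / acc_count[idx]
    pred_rows[[length(pred_rows) + 1]] <- data.frame(
      sample_id = rownames(x_raw)[idx], patient_id = patients[idx],
      label = labels[idx],
      predicted = classes[max.col(mem, ties.method = "first")],
      y_c = mem[, 1], y_h = mem[, 2], y_r = mem[, 3],
      outer_fold = NA_integer_, stringsAsFactors = FALSE)
  }
  pred <- do.call(rbind, pred_rows)
  rownames(pred) <- NULL
  pole <- pred$label %in% classes
  confusion <- table(factor(pred$label[pole], classes),
                     factor(pred$predicted[pole], classes),
                     dnn = c("label", "predicted"))
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(predictions = pred, confusion = confusion,
                 accuracy = mean(pred$predicted[pole] == pred$label[pole]),
                 balanced_accuracy = mean(per_class),
                 per_class = per_class,
                 fold_details = do.call(rbind, fold_details)),
            class = "dcv_result")
}

#' @export
print.dcv_result <- function(x, ...) {
  cat("<dcv_result> pooled outer-test accuracy ",
      sprintf("%.3f", x$accuracy), ", balanced ",
      sprintf("%.3f", x$balanced_accuracy), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}
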