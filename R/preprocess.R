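#' Within-batch QC-based SVR drift correction (QC-SVRC)
#'
#' Removes smooth intensity drift over injection order within each analytical
#' batch, using the pooled-QC injections as the reference. For each (feature,
#' batch) with enough QC measurements, an epsilon-insensitive support vector
#' regression with a radial basis function kernel is fitted to QC intensity
#' versus injection order; every intensity in the batch is then rescaled by
#' `reference / trend(injection)`, where the reference level is the median QC
#' intensity. Missing values stay missing, zeros stay zero, and features or
#' batches that cannot be corrected pass through unchanged and are flagged.
#'
#' Hyperparameters follow common QC-SVRC practice: the insensitivity tube
#' `epsilon` is 10\% of the feature's median QC intensity; the penalty `C` is
#' chosen from `c_grid` times the median QC intensity by leave-one-out
#' cross-validated RMSE on the QCs; the kernel width `gamma` is the inverse
#' median pairwise squared injection-order distance among QCs.
#'
#' @param pt A `peak_table` on the raw (positive) intensity scale with QC
#'   rows annotated.
#' @param min_qc Minimum non-missing QC measurements per (feature, batch) to
#'   attempt correction (default 5).
#' @param c_grid Multipliers of the median QC intensity forming the penalty
#'   grid.
#' @param epsilon_frac `epsilon` as a fraction of the median QC intensity.
#' @param correct_blanks Also rescale blank rows (default `FALSE`).
#' @return A list with `peak_table` (corrected) and `report`, a data frame
#'   with one row per (feature, batch): `feature_id`, `batch`, `status` in
#'   `corrected` / `skipped_insufficient_qc` / `skipped_degenerate`,
#'   `qc_rsd_before`, `qc_rsd_after`, `cost`.
#' @export
qc_svrc_correct <- function(pt, min_qc = 5, c_grid = 10^(0:4),
                            epsilon_frac = 0.1, correct_blanks = FALSE) {
  validate_peak_table(pt)
  qc_rows_all <- which(pt$role == "qc")
  if (!length(qc_rows_all))
    stop("no QC samples in the peak table; either provide QC injections or ",
         "mark the table as already corrected (manifest `corrected: true`)")
  intens <- pt$intensities
  p <- ncol(intens)
  report <- list()
  for (b in unique(pt$batch)) {
    rows <- which(pt$batch == b)
    qc_rows <- intersect(rows, qc_rows_all)
    target_rows <- if (correct_blanks) rows else
      rows[pt$role[rows] != "blank"]
    io_all <- pt$injection_order[target_rows]
    io_qc <- pt$injection_order[qc_rows]
    for (j in seq_len(p)) {
      yq <- intens[qc_rows, j]
      ok <- !is.na(yq) & yq > 0
      status <- "corrected"; rsd_b <- NA_real_; rsd_a <- NA_real_; cost <- NA_real_
      if (sum(ok) < min_qc || length(unique(io_qc[ok])) < 3) {
        status <- "skipped_insufficient_qc"
      } else {
        x <- io_qc[ok]; y <- yq[ok]
        ref <- stats::median(y)
        rsd_b <- stats::sd(y) / mean(y)
        d2 <- as.numeric(stats::dist(x))^2
        gamma <- 1 / max(stats::median(d2), .Machine$double.eps)
        eps <- epsilon_frac * ref
        fit <- .svr_loo_fit(x, y, gamma, eps, c_grid * ref, ref)
        if (is.null(fit)) {
          status <- "skipped_degenerate"
        } else {
          trend <- .svr_predict(fit, io_all)
          trend_qc <- .svr_predict(fit, x)
          if (any(!is.finite(trend)) || any(trend <= 0)) {
            status <- "skipped_degenerate"
          } else {
            cost <- fit$cost
            fac <- ref / trend
            intens[target_rows, j] <- intens[target_rows, j] * fac
            yq_c <- y * ref / trend_qc
            rsd_a <- stats::sd(yq_c) / mean(yq_c)
          }
        }
      }
      report[[length(report) + 1]] <- data.frame(
        feature_id = pt$feature_ids[j], batch = b, status = status,
        qc_rsd_before = rsd_b, qc_rsd_after = rsd_a, cost = cost,
        stringsAsFactors = FALSE)
    }
  }
  out <- peak_table(intens, sample_ids = pt$sample_ids,
                    feature_ids = pt$feature_ids, batch = pt$batch,
                    injection_order = pt$injection_order, role = pt$role)
  list(peak_table = out, report = do.call(rbind, report))
}

# LOO-selected SVR of y on x; returns the refit on all points with the best
# cost, or NULL when every grid point fails. The response is normalised by
# `ref` before fitting — an exact reparametrisation (cost and epsilon scale
# linearly with the response), but libsvm's absolute stopping rule then
# converges in far fewer iterations at large costs. Grid evaluation uses a
# looser tolerance than the final refit.
.svr_loo_fit <- function(x, y, gamma, eps, costs, ref) {
  n <- length(x)
  yn <- y / ref
  epsn <- eps / ref
  costs_n <- costs / ref
  best <- NULL; best_mse <- Inf
  for (cst in costs_n) {
    m <- tryCatch(
      e1071::svm(x = matrix(x, ncol = 1), y = yn, type = "eps-regression",
                 kernel = "radial", gamma = gamma, cost = cst, epsilon = epsn,
                 scale = FALSE, cross = n, tolerance = 0.01),
      error = function(e) NULL)
    if (is.null(m)) next
    if (m$tot.MSE < best_mse) { best_mse <- m$tot.MSE; best <- cst }
  }
  if (is.null(best)) return(NULL)
  m <- tryCatch(
    e1071::svm(x = matrix(x, ncol = 1), y = yn, type = "eps-regression",
               kernel = "radial", gamma = gamma, cost = best, epsilon = epsn,
               scale = FALSE),
    error = function(e) NULL)
  if (is.null(m)) return(NULL)
  list(model = m, cost = best * ref, ref = ref)
}

.svr_predict <- function(fit, newx) {
  as.numeric(stats::predict(fit$model, matrix(newx, ncol = 1))) * fit$ref
}

#' Filter features on blank contamination and missingness
#'
#' Drops features whose mean study intensity does not exceed `blank_ratio`
#' times their mean blank intensity (background features), and features
#' missing in more than `max_missing` of the study samples. When the table
#' has no blank rows, the blank filter is skipped with a warning and only the
#' missingness filter applies.
#'
#' @param pt A `peak_table`.
#' @param blank_ratio Required ratio of mean study to mean blank intensity
#'   (default 3).
#' @param max_missing Maximum tolerated fraction of missing study values per
#'   feature (default 0.5).
#' @return A list with `peak_table` (kept features) and `dropped`, a data
#'   frame of `feature_id` and `reason`.
#' @export
filter_features <- function(pt, blank_ratio = 3, max_missing = 0.5) {
  validate_peak_table(pt)
  study <- pt$intensities[pt$role == "study", , drop = FALSE]
  reasons <- rep(NA_character_, ncol(study))
  miss_frac <- colMeans(is.na(study))
  reasons[miss_frac > max_missing] <- "missingness"
  if (any(pt$role == "blank")) {
    blank <- pt$intensities[pt$role == "blank", , drop = FALSE]
    ms <- colMeans(study, na.rm = TRUE)
    mb <- colMeans(blank, na.rm = TRUE)
    bg <- !is.na(mb) & !(is.na(ms)) & ms < blank_ratio * mb
    reasons[bg & is.na(reasons)] <- "blank"
  } else {
    warning("no blank rows; blank filter skipped", call. = FALSE)
  }
  keep <- is.na(reasons)
  if (!any(keep)) stop("all features dropped by filtering")
  dropped <- data.frame(feature_id = pt$feature_ids[!keep],
                        reason = reasons[!keep], stringsAsFactors = FALSE)
  list(peak_table = subset_peak_table(pt, features = which(keep)),
       dropped = dropped)
}

#' Impute, log-transform, and autoscale with train-derived parameters
#'
#' Missing values are imputed by half the minimum observed value of the
#' feature on the training matrix, then intensities are log10-transformed
#' and autoscaled (per-feature mean 0, SD 1). All parameters — imputation
#' values, means, SDs, excluded features — come from `train` only and are
#' applied unchanged to `apply`, so no information flows from test to train.
#' Zero-variance features on train are excluded and recorded.
#'
#' @param train Numeric matrix (samples x features), raw positive scale.
#' @param newdata Optional matrix with the same features to transform with
#'   the train parameters.
#' @return A list with `train` (scaled), `newdata` (scaled or `NULL`), and
#'   `scaler` (list: `features`, `impute`, `center`, `scale`, `excluded`).
#' @export
impute_and_scale <- function(train, newdata = NULL) {
  train <- as.matrix(train)
  if (is.null(colnames(train)))
    colnames(train) <- paste0("F", seq_len(ncol(train)))
  half_min <- apply(train, 2, function(v) {
    m <- suppressWarnings(min(v[!is.na(v) & v > 0]))
    if (!is.finite(m)) NA_real_ else m / 2
  })
  tr <- train
  for (j in seq_len(ncol(tr))) {
    v <- tr[, j]
    v[is.na(v)] <- half_min[j]
    v[v <= 0] <- half_min[j]   # measured zeros need positivity for the log
    tr[, j] <- v
  }
  bad_impute <- is.na(half_min)
  ltr <- log10(tr)
  ctr <- colMeans(ltr)
  sdv <- apply(ltr, 2, stats::sd)
  excluded <- which(bad_impute | !is.finite(sdv) | sdv < 1e-12)
  if (length(excluded))
    warning(length(excluded), " zero-variance or all-missing feature(s) excluded",
            call. = FALSE)
  keep <- setdiff(seq_len(ncol(train)), excluded)
  scaler <- list(features = colnames(train)[keep], impute = half_min[keep],
                 center = ctr[keep], scale = sdv[keep],
                 excluded = colnames(train)[excluded])
  out_train <- sweep(sweep(ltr[, keep, drop = FALSE], 2, ctr[keep]), 2,
                     sdv[keep], "/")
  out_new <- if (!is.null(newdata)) apply_scaler(scaler, newdata) else NULL
  list(train = out_train, newdata = out_new, scaler = scaler)
}

#' Apply a fitted scaler to a new matrix
#'
#' @param scaler Scaler state from [impute_and_scale()].
#' @param x Matrix on the raw scale containing at least the scaler's features
#'   (matched by column name when present).
#' @return The imputed, log10-transformed, autoscaled matrix restricted to
#'   the scaler's features.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    miss <- setdiff(scaler$features, colnames(x))
    if (length(miss))
      stop("matrix lacks scaler feature(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    x <- x[, scaler$features, drop = FALSE]
  } else if (ncol(x) != length(scaler$features)) {
    stop("unnamed matrix has ", ncol(x), " columns; scaler expects ",
         length(scaler$features))
  }
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    v[is.na(v) | v <= 0] <- scaler$impute[j]
    x[, j] <- v
  }
  sweep(sweep(log10(x), 2, scaler$center), 2, scaler$scale, "/")
}

#' Invert a scaler transform
#'
#' @param scaler Scaler state from [impute_and_scale()].
#' @param z Scaled matrix over the scaler's features.
#' @return Matrix on the raw intensity scale (imputed values included).
#' @export
unscale <- function(scaler, z) {
  z <- as.matrix(z)
  10^(sweep(sweep(z, 2, scaler$scale, "*"), 2, scaler$center, "+"))
}

#' Welch t-test screen with Benjamini-Hochberg correction
#'
#' Per-feature two-sample Welch t-test (unequal variances) between two groups
#' of samples, with FDR adjustment across features. Features with adjusted
#' p below `alpha` are flagged as selected.
#'
#' @param x Numeric matrix, samples x features (typically scaled).
#' @param group_a,group_b Row indices or rownames of the two groups, each of
#'   size at least 2.
#' @param alpha FDR level (default 0.05).
#' @return A data frame with `feature`, `t`, `p`, `q`, `selected`.
#' @export
univariate_screen <- function(x, group_a, group_b, alpha = 0.05) {
  x <- as.matrix(x)
  idx <- function(g) if (is.character(g)) match(g, rownames(x)) else g
  a <- idx(group_a); b <- idx(group_b)
  if (anyNA(a) || anyNA(b)) stop("unknown sample id(s) in group definition")
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 samples")
  xa <- x[a, , drop = FALSE]; xb <- x[b, , drop = FALSE]
  na <- colSums(!is.na(xa)); nb <- colSums(!is.na(xb))
  ma <- colMeans(xa, na.rm = TRUE); mb <- colMeans(xb, na.rm = TRUE)
  va <- apply(xa, 2, stats::var, na.rm = TRUE)
  vb <- apply(xb, 2, stats::var, na.rm = TRUE)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  tt[se2 == 0] <- 0
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  pv <- 2 * stats::pt(-abs(tt), df)
  pv[se2 == 0] <- 1
  qv <- stats::p.adjust(pv, method = "BH")
  data.frame(feature = colnames(x) %||% paste0("F", seq_len(ncol(x))),
             t = tt, p = pv, q = qv, selected = qv < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
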