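#' Run the full ternary phenotyping pipeline on a cohort
#'
#' Chains the stages in their canonical order: within-batch QC-SVRC drift
#' correction (skipped when the cohort is flagged as already corrected or has
#' no QC rows to correct with), blank/missingness feature filtering,
#' rule-based clinical labelling, training of the three one-vs-rest PLS-DA
#' models on the non-mixed patients, prediction of every study sample,
#' ternary mapping, residual-DILI flagging, and per-patient transition
#' annotation. Optionally an honest generalisation estimate via subject-wise
#' double cross-validation.
#'
#' @param cohort A `dili_cohort`.
#' @param thresholds [clinical_thresholds()] for the labelling.
#' @param corrected Set `TRUE` when the peak table is already drift-corrected
#'   (defaults to the cohort's manifest flag when present).
#' @param k_outer,k_inner Fold counts for the double CV and the inner
#'   complexity selection.
#' @param max_lv,vip_threshold,lv_rule Model-building parameters, see
#'   [train_ovr()].
#' @param seed Integer seed driving every fold deal.
#' @param double_cv Run [double_cv_evaluate()] as well (default `TRUE`).
#' @param min_qc,blank_ratio,max_missing Preprocessing parameters.
#' @return A `dili_pipeline` list: `cohort` (post-correction, post-filter),
#'   `correction_report`, `dropped_features`, `clinical` (calls + counts),
#'   `ensemble`, `predictions` (per-sample data frame with membership triple,
#'   ternary coordinates, clinical label, residual flag), `trajectories`,
#'   `transitions`, and `dcv` (when requested).
#' @export
run_ternary_pipeline <- function(cohort, thresholds = clinical_thresholds(),
                                 corrected = isTRUE(attr(cohort, "corrected")),
                                 k_outer = 5, k_inner = 5, max_lv = 8,
                                 vip_threshold = 1, lv_rule = "1se",
                                 seed = 1L, double_cv = TRUE, min_qc = 5,
                                 blank_ratio = 3, max_missing = 0.5) {
  stopifnot(inherits(cohort, "dili_cohort"))
  pt <- cohort$peak_table
  correction_report <- NULL
  if (!corrected) {
    corr <- qc_svrc_correct(pt, min_qc = min_qc)
    pt <- corr$peak_table
    correction_report <- corr$report
  }
  filt <- filter_features(pt, blank_ratio = blank_ratio,
                          max_missing = max_missing)
  pt <- filt$peak_table
  clinical <- classify_cohort(cohort, thresholds)
  rec <- cohort$records
  study <- pt$intensities[match(rec$sample_id, pt$sample_ids), , drop = FALSE]
  rownames(study) <- rec$sample_id
  labels <- clinical$calls$label[match(rec$sample_id,
                                       clinical$calls$sample_id)]
  ens <- train_ensemble(study, labels, rec$patient_id, k_inner = k_inner,
                        max_lv = max_lv, vip_threshold = vip_threshold,
                        seed = seed, lv_rule = lv_rule)
  pr <- predict(ens, study)
  coords <- to_ternary(pr$membership)
  coords$sample_id <- rec$sample_id
  flags <- lapply(seq_len(nrow(coords)), function(i)
    residual_dili_flag(coords[i, ], labels[i]))
  predictions <- data.frame(
    sample_id = rec$sample_id, patient_id = rec$patient_id,
    timepoint_index = rec$timepoint_index,
    label = labels, r_score = clinical$calls$r_score[
      match(rec$sample_id, clinical$calls$sample_id)],
    y_c = pr$membership[, 1], y_h = pr$membership[, 2],
    y_r = pr$membership[, 3],
    c = coords$c, h = coords$h, r = coords$r,
    degenerate = coords$degenerate,
    residual_level = vapply(flags, `[[`, "", "level"),
    residual_driver = vapply(flags, function(f)
      if (is.na(f$driver)) NA_character_ else f$driver, NA_character_),
    stringsAsFactors = FALSE)
  traj <- build_trajectories(coords, rec, clinical$calls)
  transitions <- lapply(traj, classify_transition)
  dcv <- if (double_cv)
    double_cv_evaluate(study, labels, rec$patient_id, k_outer = k_outer,
                       k_inner = k_inner, seed = seed, max_lv = max_lv,
                       vip_threshold = vip_threshold, lv_rule = lv_rule)
  else NULL
  structure(list(cohort = cohort, peak_table = pt,
                 correction_report = correction_report,
                 dropped_features = filt$dropped, clinical = clinical,
                 ensemble = ens, predictions = predictions,
                 trajectories = traj, transitions = transitions, dcv = dcv),
            class = "dili_pipeline")
}

#' @export
print.dili_pipeline <- function(x, ...) {
  cat("<dili_pipeline> ", nrow(x$predictions), " study samples, ",
      ncol(x$peak_table$intensities), " features after filtering\n", sep = "")
  cat("  clinical counts: ",
      paste(sprintf("%s=%d", names(x$clinical$counts), x$clinical$counts),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$dcv))
    cat("  double-CV balanced accuracy: ",
        sprintf("%.3f", x$dcv$balanced_accuracy), "\n", sep = "")
  flagged <- sum(x$predictions$residual_level != "none")
  cat("  residual-DILI flags among recovered samples: ", flagged, "\n",
      sep = "")
  invisible(x)
}

#' Serialise a phenotype ensemble to JSON
#'
#' Writes a versioned, self-contained JSON document holding the three
#' one-vs-rest models: selected features, scaler state, latent-variable
#' counts, weights, loadings, response loadings, regression coefficients, and
#' VIP scores. Matrices are stored as arrays at full double precision, so the
#' file is plain text and [read_ensemble()] reproduces predictions exactly.
#'
#' @param ensemble A `phenotype_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "phenotype_ensemble"))
  ser_model <- function(m) list(
    target_class = m$target_class, n_lv = m$n_lv,
    cv_accuracy = m$cv_accuracy, selected_features = m$selected_features,
    scaler = m$scaler,
    weights = m$model$weights, loadings = m$model$loadings,
    y_loadings = m$model$y_loadings, coef_by_lv = m$model$coef_by_lv,
    y_mean = m$model$y_mean, ssy = m$model$ssy,
    feature_ids = m$model$feature_ids, vip = unname(m$vip),
    vip_features = names(m$vip))
  doc <- list(format = "diliternary_ensemble", version = 1L,
              classes = ensemble$classes,
              excluded_patients = ensemble$excluded_patients,
              models = lapply(ensemble$models, ser_model))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a phenotype ensemble written by [write_ensemble()]
#'
#' @param path Path to the JSON document.
#' @return A `phenotype_ensemble` whose predictions match the saved model.
#' @export
read_ensemble <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "diliternary_ensemble"))
    stop("not an ensemble file: ", path)
  if (doc$version != 1L) stop("unsupported ensemble version: ", doc$version)
  de_model <- function(m) {
    as_mat <- function(x) {
      x <- as.matrix(x)
      dimnames(x) <- list(m$feature_ids, paste0("LV", seq_len(ncol(x))))
      x
    }
    pls <- structure(list(
      n_lv = m$n_lv, weights = as_mat(m$weights),
      loadings = as_mat(m$loadings), scores = NULL,
      y_loadings = m$y_loadings, coef_by_lv = as_mat(m$coef_by_lv),
      coefficients = as_mat(m$coef_by_lv)[, m$n_lv],
      y_mean = m$y_mean, ssy = m$ssy, feature_ids = m$feature_ids),
      class = "pls_model")
    scaler <- m$scaler
    structure(list(target_class = m$target_class, n_lv = m$n_lv,
                   cv_accuracy = m$cv_accuracy,
                   selected_features = m$selected_features,
                   vip = stats::setNames(m$vip, m$vip_features),
                   scaler = scaler, model = pls, stage1 = NULL),
              class = "ovr_model")
  }
  models <- lapply(doc$models, de_model)
  names(models) <- doc$classes
  structure(list(models = models, classes = doc$classes,
                 excluded_patients = doc$excluded_patients,
                 training_samples = NULL),
            class = "phenotype_ensemble")
}
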