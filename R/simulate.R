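#' Configuration for the synthetic DILI cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: longitudinal plasma samples nested in patients; three latent
#' phenotype poles — cholestatic (C), hepatocellular (H), recovered (R) —
#' with distinct metabolite-block signatures; mixed samples as convex
#' combinations of the poles; within-batch intensity drift over injection
#' order with interleaved pooled-QC injections; and clinical chemistry (ALT,
#' ALP, bilirubin) consistent with the latent mixture.
#'
#' On the log2 scale each feature is
#' `baseline + w_C * delta_C + w_H * delta_H + drift(injection) + noise`,
#' where `(w_C, w_H, w_R)` are the sample's nonnegative mixture weights
#' summing to one and the `delta` blocks are nonzero only on the informative
#' feature sets. The cholestatic block is shifted up (bile-acid-like
#' accumulation) except for a configurable fraction shifted down
#' (glycerophospholipid-like depression); the hepatocellular block likewise.
#' The recovered pole contributes no shift. Patient trajectories move the
#' weights toward the recovered vertex `(0, 0, 1)` at `recovery_rate` per
#' timepoint.
#'
#' @param n_patients Number of patients.
#' @param timepoints_min,timepoints_max Range of samples per patient (uniform).
#' @param class_mix Named proportions of `pure_c`, `pure_h`, `recovered`,
#'   `mixed` patients; must sum to 1.
#' @param n_features Total LC-MS features (default 828, the scale of a
#'   typical annotated plasma peak table).
#' @param n_informative_c,n_informative_h Sizes of the C and H signature
#'   blocks (disjoint).
#' @param effect_size Mean absolute log2 fold-change of informative features
#'   at a pure pole.
#' @param frac_down Fraction of each signature block shifted down rather
#'   than up.
#' @param n_batches Analytical batches; samples are split across batches in
#'   acquisition order.
#' @param drift_amplitude Maximum |log2 drift| at the end of a batch; each
#'   feature drifts linearly in injection order with its own random slope in
#'   `[-drift_amplitude, drift_amplitude]`.
#' @param qc_every Insert one pooled-QC injection every `qc_every` injections.
#' @param n_blanks Extraction blanks per batch (near-zero intensities).
#' @param missing_rate Fraction of study/QC intensity cells set missing
#'   completely at random.
#' @param noise_sd Residual SD on the log2 scale.
#' @param recovery_rate Per-timepoint pull of the mixture weights toward the
#'   recovered vertex, in `[0, 1]`.
#' @param mixed_alpha Dirichlet concentration (length 3, order C/H/R) for the
#'   initial weights of mixed patients.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 60, timepoints_min = 2, timepoints_max = 4,
                       class_mix = c(pure_c = 0.30, pure_h = 0.25,
                                     recovered = 0.25, mixed = 0.20),
                       n_features = 828, n_informative_c = 40,
                       n_informative_h = 40, effect_size = 1.5,
                       frac_down = 0.3, n_batches = 2, drift_amplitude = 0.3,
                       qc_every = 8, n_blanks = 2, missing_rate = 0.05,
                       noise_sd = 0.5, recovery_rate = 0.1,
                       mixed_alpha = c(4, 4, 2), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 1, timepoints_min >= 1,
            timepoints_max >= timepoints_min,
            abs(sum(class_mix) - 1) < 1e-8, all(class_mix >= 0),
            length(class_mix) == 4,
            effect_size >= 0, frac_down >= 0, frac_down <= 1,
            n_batches >= 1, drift_amplitude >= 0, qc_every >= 2,
            missing_rate >= 0, missing_rate < 1, noise_sd >= 0,
            recovery_rate >= 0, recovery_rate <= 1,
            length(mixed_alpha) == 3, all(mixed_alpha > 0))
  if (n_informative_c + n_informative_h > n_features)
    stop("informative blocks (", n_informative_c + n_informative_h,
         ") exceed n_features (", n_features, ")")
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a synthetic DILI cohort with ground truth
#'
#' Draws a cohort under the generative model described in [sim_config()] and
#' returns it together with the latent mixture weights of every study sample,
#' so that parameter-recovery of the full pipeline can be scored against
#' truth.
#'
#' Clinical chemistry is linked to the latent weights through
#' `ALT = ULN_ALT * (0.5 + 8 w_H + 0.8 w_C + e)` and
#' `ALP = ULN_ALP * (0.5 + 3 w_C + 0.8 w_H + e)` with `e ~ N(0, 0.1)`
#' truncated so the ratios stay positive, and
#' `BIL = ULN_BIL * (0.4 + 1.5 (w_C + w_H) + e)`. The cross-terms reflect
#' that both injury types elevate both enzymes to some degree; the constants
#' place the pure poles in their respective rule-based classes (R score at a
#' pure H pole about 6.5, at a pure C pole about 0.4) with probability well
#' above 0.95, while intermediate mixtures land in the mixed band or, as in
#' real cohorts, in whichever pure class the R score favours.
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (a `dili_cohort`), and `truth` (data frame:
#'   `sample_id`, `patient_id`, `timepoint_index`, `w_c`, `w_h`, `w_r`,
#'   `patient_class`) plus `informative_c` / `informative_h` feature-id sets
#'   as attributes of `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  p <- cf$n_features
  feature_ids <- sprintf("M%06.1fT%05.1f_%s",
                         stats::runif(p, 70, 1200), stats::runif(p, 0.5, 12),
                         sample(c("pos", "neg"), p, replace = TRUE))
  feature_ids <- make.unique(feature_ids, sep = "_")
  idx_c <- seq_len(cf$n_informative_c)
  idx_h <- seq(cf$n_informative_c + 1, length.out = cf$n_informative_h)

  # signature blocks: magnitudes ~ effect_size on log2 scale, sign mostly up
  block_delta <- function(idx) {
    d <- numeric(p)
    mag <- stats::rnorm(length(idx), cf$effect_size, cf$effect_size * 0.2)
    sgn <- ifelse(stats::runif(length(idx)) < cf$frac_down, -1, 1)
    d[idx] <- sgn * abs(mag)
    d
  }
  delta_c <- block_delta(idx_c)
  delta_h <- block_delta(idx_h)
  baseline <- stats::rnorm(p, mean = 14, sd = 2)   # log2 raw-intensity scale

  # patients: class, timepoints, initial weights, trajectory toward recovery
  n_by_class <- floor(cf$class_mix * cf$n_patients)
  rem <- cf$n_patients - sum(n_by_class)
  if (rem > 0) {
    top <- order(cf$class_mix * cf$n_patients - n_by_class, decreasing = TRUE)
    n_by_class[top[seq_len(rem)]] <- n_by_class[top[seq_len(rem)]] + 1
  }
  pclass <- sample(rep(c("pure_c", "pure_h", "recovered", "mixed"), n_by_class))
  pat_ids <- sprintf("P%03d", seq_len(cf$n_patients))

  rows <- list(); truth <- list()
  for (i in seq_len(cf$n_patients)) {
    w1 <- switch(pclass[i],
                 pure_c = c(1, 0, 0), pure_h = c(0, 1, 0),
                 recovered = c(0, 0, 1), mixed = rdirichlet1(cf$mixed_alpha))
    nt <- sample(seq(cf$timepoints_min, cf$timepoints_max), 1)
    for (t in seq_len(nt)) {
      shrink <- (1 - cf$recovery_rate)^(t - 1)
      w <- shrink * w1 + (1 - shrink) * c(0, 0, 1)
      rows[[length(rows) + 1]] <- list(patient = pat_ids[i], tp = t, w = w)
      truth[[length(truth) + 1]] <- data.frame(
        sample_id = sprintf("%s-t%d", pat_ids[i], t),
        patient_id = pat_ids[i], timepoint_index = t,
        w_c = w[1], w_h = w[2], w_r = w[3], patient_class = pclass[i],
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  n_study <- nrow(truth)

  # study-sample log2 profiles (before drift)
  W <- as.matrix(truth[, c("w_c", "w_h")])
  signal <- W %*% rbind(delta_c, delta_h)
  log_study <- sweep(signal, 2, baseline, "+") +
    matrix(stats::rnorm(n_study * p, 0, cf$noise_sd), n_study, p)
  rownames(log_study) <- truth$sample_id

  # pooled QC = mean study profile; build injection sequences with QCs/blanks
  qc_base <- colMeans(log_study)
  order_idx <- sample(n_study)   # acquisition order of study samples
  per_batch <- split(order_idx, cut(seq_len(n_study), cf$n_batches, labels = FALSE))

  all_ids <- character(); all_batch <- character(); all_inj <- integer()
  all_role <- character(); log_all <- NULL
  qc_n <- 0L; blank_n <- 0L
  for (b in seq_along(per_batch)) {
    bid <- sprintf("B%d", b)
    sidx <- per_batch[[b]]
    seq_ids <- character(); seq_role <- character(); seq_log <- list()
    # leading QC, then a QC after every qc_every study injections, QC at end
    add_qc <- function() {
      qc_n <<- qc_n + 1L
      seq_ids <<- c(seq_ids, sprintf("QC%03d", qc_n))
      seq_role <<- c(seq_role, "qc")
      seq_log[[length(seq_log) + 1]] <<-
        qc_base + stats::rnorm(p, 0, cf$noise_sd / 2)
    }
    for (k in seq_len(cf$n_blanks)) {
      blank_n <- blank_n + 1L
      seq_ids <- c(seq_ids, sprintf("BL%03d", blank_n))
      seq_role <- c(seq_role, "blank")
      seq_log[[length(seq_log) + 1]] <- stats::rnorm(p, 4, 1)
    }
    add_qc()
    for (j in seq_along(sidx)) {
      seq_ids <- c(seq_ids, truth$sample_id[sidx[j]])
      seq_role <- c(seq_role, "study")
      seq_log[[length(seq_log) + 1]] <- log_study[sidx[j], ]
      if (j %% cf$qc_every == 0 && j < length(sidx)) add_qc()
    }
    add_qc()
    nb <- length(seq_ids)
    # per-feature linear drift in log2 over injection order
    slope <- stats::runif(p, -cf$drift_amplitude, cf$drift_amplitude)
    frac <- if (nb > 1) (seq_len(nb) - 1) / (nb - 1) else rep(0, nb)
    drift <- outer(frac, slope)
    lg <- do.call(rbind, seq_log) + drift
    all_ids <- c(all_ids, seq_ids)
    all_batch <- c(all_batch, rep(bid, nb))
    all_inj <- c(all_inj, seq_len(nb))
    all_role <- c(all_role, seq_role)
    log_all <- rbind(log_all, lg)
  }
  intens <- 2^log_all
  # missing completely at random on study + QC cells
  if (cf$missing_rate > 0) {
    maskable <- which(all_role != "blank")
    cells <- length(maskable) * p
    nmiss <- stats::rbinom(1, cells, cf$missing_rate)
    if (nmiss > 0) {
      pick <- sample.int(cells, nmiss)
      ri <- maskable[(pick - 1) %% length(maskable) + 1]
      ci <- (pick - 1) %/% length(maskable) + 1
      intens[cbind(ri, ci)] <- NA_real_
    }
  }
  pt <- peak_table(intens, sample_ids = all_ids, feature_ids = feature_ids,
                   batch = all_batch, injection_order = all_inj,
                   role = all_role)

  # clinical chemistry linked to the latent weights
  th <- clinical_thresholds()
  eps <- function(n) pmax(stats::rnorm(n, 0, 0.1), -0.35)
  alt <- th$uln_alt * (0.5 + 8.0 * truth$w_h + 0.8 * truth$w_c + eps(n_study))
  alp <- th$uln_alp * (0.5 + 3.0 * truth$w_c + 0.8 * truth$w_h + eps(n_study))
  bil <- th$uln_bil * (0.4 + 1.5 * (truth$w_c + truth$w_h) + eps(n_study))
  rec <- data.frame(
    sample_id = truth$sample_id, patient_id = truth$patient_id,
    timepoint_index = truth$timepoint_index,
    days_from_onset = (truth$timepoint_index - 1) * 14,
    drug = "synthetic", alt = round(pmax(alt, 1), 1),
    alp = round(pmax(alp, 1), 1), bilirubin = round(pmax(bil, 0.05), 2),
    clinician_label = NA_character_, stringsAsFactors = FALSE)
  rec$clinician_label <- vapply(seq_len(n_study), function(i)
    classify_clinical(rec$alt[i], rec$alp[i], rec$bilirubin[i])$label,
    character(1))
  cohort <- join_cohort(pt, rec)
  attr(truth, "informative_c") <- feature_ids[idx_c]
  attr(truth, "informative_h") <- feature_ids[idx_h]
  list(cohort = cohort, truth = truth)
}

#' Impose multiplicative intensity drift on a peak table
#'
#' Test utility: multiplies each feature by a smooth monotone function of
#' injection order within each batch, equal to 1 at the batch start and to
#' `1 + s * amplitude` at the batch end, where `s` is a per-feature random
#' sign. `shape = "linear"` interpolates linearly; `"sigmoid"` uses a smooth
#' logistic ramp.
#'
#' @param pt A `peak_table` with QC rows annotated.
#' @param amplitude Relative drift at the end of a batch (>= 0).
#' @param seed Integer seed for the per-feature drift directions.
#' @param shape `"linear"` or `"sigmoid"`.
#' @return A `peak_table` with drifted intensities.
#' @export
corrupt_with_drift <- function(pt, amplitude, seed = 1L, shape = c("linear", "sigmoid")) {
  shape <- match.arg(shape)
  validate_peak_table(pt)
  stopifnot(amplitude >= 0)
  if (!any(pt$role == "qc"))
    stop("peak table has no QC rows; drift correction would be untestable")
  set.seed(seed)
  p <- ncol(pt$intensities)
  intens <- pt$intensities
  for (b in unique(pt$batch)) {
    rows <- which(pt$batch == b)
    io <- pt$injection_order[rows]
    frac <- if (max(io) > min(io)) (io - min(io)) / (max(io) - min(io)) else rep(0, length(io))
    if (shape == "sigmoid") {
      frac <- stats::plogis(8 * (frac - 0.5))
      frac <- (frac - min(frac)) / (max(frac) - min(frac))  # pin ends at 0/1
    }
    sgn <- sample(c(-1, 1), p, replace = TRUE)
    fac <- 1 + outer(frac, sgn * amplitude)
    intens[rows, ] <- intens[rows, , drop = FALSE] * fac
  }
  peak_table(intens, sample_ids = pt$sample_ids, feature_ids = pt$feature_ids,
             batch = pt$batch, injection_order = pt$injection_order,
             role = pt$role)
}
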