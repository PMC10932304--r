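#' Clinical chemistry thresholds for DILI phenotyping
#'
#' Upper limits of normal (ULN) used by the R score and the rule-based
#' classification: ALT 56 U/L, ALP 147 U/L, total bilirubin 1.2 mg/dL.
#'
#' @param uln_alt Upper limit of normal for alanine aminotransferase (U/L).
#' @param uln_alp Upper limit of normal for alkaline phosphatase (U/L).
#' @param uln_bil Upper limit of normal for total bilirubin (mg/dL).
#' @param hepatocellular_r R-score boundary for hepatocellular injury; calls
#'   use `R >= hepatocellular_r`. Default 5.
#' @param cholestatic_r R-score boundary for cholestatic injury; calls use
#'   `R < cholestatic_r`. Default 2.
#' @param recovered_requires_bil If `TRUE`, the recovered call additionally
#'   requires bilirubin below `uln_bil`. Off by default; both readings of the
#'   recovery rule are reported by [classify_cohort()].
#' @return A `clinical_thresholds` list.
#' @export
clinical_thresholds <- function(uln_alt = 56, uln_alp = 147, uln_bil = 1.2,
                                hepatocellular_r = 5, cholestatic_r = 2,
                                recovered_requires_bil = FALSE) {
  stopifnot(uln_alt > 0, uln_alp > 0, uln_bil > 0,
            hepatocellular_r > cholestatic_r)
  structure(list(uln_alt = uln_alt, uln_alp = uln_alp, uln_bil = uln_bil,
                 hepatocellular_r = hepatocellular_r,
                 cholestatic_r = cholestatic_r,
                 recovered_requires_bil = recovered_requires_bil),
            class = "clinical_thresholds")
}

#' R score of a DILI episode
#'
#' The R score is the ratio of the ALT elevation to the ALP elevation, each
#' expressed as a multiple of its upper limit of normal:
#' \deqn{R = \frac{ALT / ULN_{ALT}}{ALP / ULN_{ALP}}}
#' Values below 2 indicate cholestatic injury, values of 5 or more
#' hepatocellular injury, and the band between them mixed injury.
#'
#' @param alt ALT in U/L (nonnegative). Vectorised.
#' @param alp ALP in U/L (strictly positive). Vectorised.
#' @param thresholds A [clinical_thresholds()] object.
#' @return Numeric vector of R scores.
#' @export
r_score <- function(alt, alp, thresholds = clinical_thresholds()) {
  if (any(!is.na(alp) & alp == 0))
    stop("R score undefined: ALP of 0 U/L")
  if (any(!is.na(alt) & alt < 0) || any(!is.na(alp) & alp < 0))
    stop("ALT and ALP must be nonnegative")
  (alt / thresholds$uln_alt) / (alp / thresholds$uln_alp)
}

#' Rule-based clinical phenotype of one sample
#'
#' Applies the enzyme-threshold rules in a fixed order: recovered
#' (both ALT and ALP below their ULN), then hepatocellular (ALT at or above
#' ULN and R score at or above the hepatocellular boundary), then cholestatic
#' (ALP at or above ULN and R score below the cholestatic boundary), then
#' mixed (R score in the intermediate band with both enzymes at or above
#' their ULN). Samples matching none of the rules — for example an
#' intermediate R score with only one enzyme elevated — are reported as
#' `unclassifiable` rather than coerced into a class.
#'
#' @param alt,alp ALT and ALP in U/L; `NA` yields an `unclassifiable` call.
#' @param bilirubin Total bilirubin in mg/dL; only consulted when
#'   `thresholds$recovered_requires_bil` is `TRUE`.
#' @param thresholds A [clinical_thresholds()] object.
#' @return A list with `r_score`, `label` (one of `cholestatic`,
#'   `hepatocellular`, `mixed`, `recovered`, `unclassifiable`) and `reason`
#'   for unclassifiable calls.
#' @export
classify_clinical <- function(alt, alp, bilirubin = NA_real_,
                              thresholds = clinical_thresholds()) {
  if (is.na(alt) || is.na(alp))
    return(list(r_score = NA_real_, label = "unclassifiable",
                reason = "missing ALT or ALP"))
  r <- r_score(alt, alp, thresholds)
  th <- thresholds
  recovered <- alt < th$uln_alt && alp < th$uln_alp
  if (recovered && th$recovered_requires_bil)
    recovered <- !is.na(bilirubin) && bilirubin < th$uln_bil
  label <-
    if (recovered) "recovered"
    else if (alt >= th$uln_alt && r >= th$hepatocellular_r) "hepatocellular"
    else if (alp >= th$uln_alp && r < th$cholestatic_r) "cholestatic"
    else if (r >= th$cholestatic_r && r < th$hepatocellular_r &&
             alt >= th$uln_alt && alp >= th$uln_alp) "mixed"
    else "unclassifiable"
  reason <- if (label == "unclassifiable")
    "no rule matched (intermediate R score with only one enzyme elevated, or enzymes above ULN with an extreme R score)"
  else NA_character_
  list(r_score = r, label = label, reason = reason)
}

#' Read a per-sample clinical chemistry table
#'
#' Expects a delimited file with at least the columns `sample_id`,
#' `patient_id`, `timepoint`, `alt`, `alp`, `bilirubin` (case-insensitive;
#' `bil` is accepted for bilirubin). Optional columns: `days_from_onset`,
#' `drug`, `clinician_label`. Unparseable numeric cells become `NA` with a
#' warning.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A data frame of sample records, one row per sample, with columns
#'   `sample_id`, `patient_id`, `timepoint_index`, `days_from_onset`, `drug`,
#'   `alt`, `alp`, `bilirubin`, `clinician_label`.
#' @export
read_clinical_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0 && ncol(df) == 0) return(empty_clinical_table())
  names(df) <- tolower(names(df))
  if ("bil" %in% names(df) && !"bilirubin" %in% names(df))
    names(df)[names(df) == "bil"] <- "bilirubin"
  mandatory <- c("sample_id", "patient_id", "timepoint", "alt", "alp", "bilirubin")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(empty_clinical_table())
  num <- function(x, what) {
    y <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & x != "" & toupper(x) != "NA" & is.na(y)
    if (any(bad))
      warning(sum(bad), " unparseable ", what, " value(s) set to NA: ",
              paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
    y
  }
  tp <- df$timepoint
  tp_idx <- suppressWarnings(as.integer(sub("^t", "", tp, ignore.case = TRUE)))
  out <- data.frame(
    sample_id = df$sample_id,
    patient_id = df$patient_id,
    timepoint_index = tp_idx,
    days_from_onset = if ("days_from_onset" %in% names(df))
      num(df$days_from_onset, "days_from_onset") else NA_real_,
    drug = if ("drug" %in% names(df)) df$drug else NA_character_,
    alt = num(df$alt, "ALT"),
    alp = num(df$alp, "ALP"),
    bilirubin = num(df$bilirubin, "bilirubin"),
    clinician_label = if ("clinician_label" %in% names(df))
      df$clinician_label else NA_character_,
    stringsAsFactors = FALSE)
  validate_clinical_table(out)
  out
}

empty_clinical_table <- function() {
  data.frame(sample_id = character(), patient_id = character(),
             timepoint_index = integer(), days_from_onset = numeric(),
             drug = character(), alt = numeric(), alp = numeric(),
             bilirubin = numeric(), clinician_label = character(),
             stringsAsFactors = FALSE)
}

validate_clinical_table <- function(rec) {
  if (nrow(rec) == 0) return(invisible(rec))
  key <- paste(rec$patient_id, rec$timepoint_index)
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("duplicate (patient_id, timepoint) pairs: ", paste(dup, collapse = "; "))
  for (v in c("alt", "alp", "bilirubin"))
    if (any(rec[[v]] < 0, na.rm = TRUE))
      stop("negative ", v, " values present")
  if (any(!is.na(rec$timepoint_index) & rec$timepoint_index < 1))
    stop("timepoint_index must be >= 1")
  invisible(rec)
}

#' Classify every study sample of a cohort by the clinical rules
#'
#' Applies [classify_clinical()] to each record of a cohort (or a bare
#' clinical table) and tabulates the class counts. Two readings of the
#' recovery rule are reported: enzymes only (ALT and ALP below ULN), and
#' enzymes plus bilirubin below its ULN.
#'
#' @param x A `dili_cohort` from [join_cohort()], or a clinical-records data
#'   frame as returned by [read_clinical_table()].
#' @param thresholds A [clinical_thresholds()] object.
#' @return A list with `calls` (data frame: `sample_id`, `r_score`, `label`,
#'   `label_bil` for the bilirubin-inclusive variant) and `counts` (named
#'   vector over the five labels).
#' @export
classify_cohort <- function(x, thresholds = clinical_thresholds()) {
  rec <- if (inherits(x, "dili_cohort")) x$records else x
  labs <- c("cholestatic", "hepatocellular", "mixed", "recovered", "unclassifiable")
  if (is.null(rec) || nrow(rec) == 0) {
    counts <- stats::setNames(integer(length(labs)), labs)
    return(list(calls = data.frame(sample_id = character(), r_score = numeric(),
                                   label = character(), label_bil = character(),
                                   stringsAsFactors = FALSE),
                counts = counts))
  }
  th_bil <- thresholds; th_bil$recovered_requires_bil <- TRUE
  calls <- lapply(seq_len(nrow(rec)), function(i) {
    a <- classify_clinical(rec$alt[i], rec$alp[i], rec$bilirubin[i], thresholds)
    b <- classify_clinical(rec$alt[i], rec$alp[i], rec$bilirubin[i], th_bil)
    data.frame(sample_id = rec$sample_id[i], r_score = a$r_score,
               label = a$label, label_bil = b$label, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  counts <- stats::setNames(
    vapply(labs, function(l) sum(calls$label == l), integer(1)), labs)
  list(calls = calls, counts = counts)
}
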