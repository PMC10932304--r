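#' Join a peak table with its clinical records
#'
#' Matches study rows of the peak table to clinical records by `sample_id`.
#' QC and blank rows are carried through without records. Unmatched study
#' samples and unmatched clinical rows are reported, not dropped silently:
#' the returned cohort keeps only matched study samples plus all QC/blank
#' rows, and the `unmatched` element lists what fell out on either side.
#'
#' @param pt A `peak_table`.
#' @param records Clinical records data frame ([read_clinical_table()]).
#' @return A `dili_cohort`: list with `peak_table`, `records` (aligned 1:1
#'   with the study rows of `peak_table`, in peak-table order), and
#'   `unmatched` (list of `peak_samples` and `clinical_rows` IDs).
#' @export
join_cohort <- function(pt, records) {
  validate_peak_table(pt)
  validate_clinical_table(records)
  study_ids <- pt$sample_ids[pt$role == "study"]
  matched <- intersect(study_ids, records$sample_id)
  if (!length(matched))
    stop("no study sample of the peak table matches any clinical record")
  unmatched <- list(peak_samples = setdiff(study_ids, matched),
                    clinical_rows = setdiff(records$sample_id, matched))
  keep <- pt$role != "study" | pt$sample_ids %in% matched
  pt2 <- subset_peak_table(pt, samples = which(keep))
  study_order <- pt2$sample_ids[pt2$role == "study"]
  rec <- records[match(study_order, records$sample_id), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(peak_table = pt2, records = rec, unmatched = unmatched),
            class = "dili_cohort")
}

#' @export
print.dili_cohort <- function(x, ...) {
  cat("<dili_cohort> ", sum(x$peak_table$role == "study"), " study samples (",
      length(unique(x$records$patient_id)), " patients), ",
      sum(x$peak_table$role == "qc"), " QCs, ",
      sum(x$peak_table$role == "blank"), " blanks, ",
      ncol(x$peak_table$intensities), " features\n", sep = "")
  nu <- lengths(x$unmatched)
  if (any(nu > 0))
    cat("  unmatched: ", nu[["peak_samples"]], " peak-table sample(s), ",
        nu[["clinical_rows"]], " clinical row(s)\n", sep = "")
  invisible(x)
}

#' Read a cohort from a YAML manifest
#'
#' The manifest names the peak-table and clinical files and how to read them:
#' \preformatted{
#' peak_table: peaks.csv
#' clinical_table: clinical.csv
#' dialect: csv
#' orientation: samples_in_rows
#' corrected: false
#' }
#' Relative paths are resolved against the manifest's directory. The
#' `corrected` flag records whether the peak table has already been
#' drift-corrected; pipeline drivers skip [qc_svrc_correct()] when it is
#' `true`.
#'
#' @param path Path to the manifest.
#' @return A `dili_cohort` with attribute `"corrected"`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  for (f in c("peak_table", "clinical_table"))
    if (is.null(m[[f]])) stop("manifest missing field: ", f)
  dir <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  dialect <- if (is.null(m$dialect)) "csv" else m$dialect
  orientation <- if (is.null(m$orientation)) "samples_in_rows" else m$orientation
  pt <- read_peak_table(resolve(m$peak_table), dialect, orientation)
  rec <- read_clinical_table(resolve(m$clinical_table), dialect)
  ch <- join_cohort(pt, rec)
  attr(ch, "corrected") <- isTRUE(m$corrected)
  ch
}

#' Write a cohort to disk with a manifest
#'
#' Writes the peak table, the clinical table, and a YAML manifest pointing at
#' both, so that [read_cohort_manifest()] round-trips the cohort.
#'
#' @param cohort A `dili_cohort`.
#' @param dir Output directory (created if needed).
#' @param corrected Value for the manifest's `corrected` flag.
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, corrected = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_peak_table(cohort$peak_table, file.path(dir, "peaks.csv"), "csv")
  rec <- cohort$records
  names(rec)[names(rec) == "timepoint_index"] <- "timepoint"
  utils::write.csv(rec, file.path(dir, "clinical.csv"), row.names = FALSE,
                   na = "NA")
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(peak_table = "peaks.csv", clinical_table = "clinical.csv",
                        dialect = "csv", orientation = "samples_in_rows",
                        corrected = corrected), manifest)
  invisible(manifest)
}
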