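#' Construct a peak table
#'
#' A peak table holds the samples x features intensity matrix of a processed
#' untargeted LC-MS experiment, together with the per-sample acquisition
#' annotations the rest of the pipeline needs: analytical batch, injection
#' order within batch, and the role of each injection (study sample, pooled
#' quality-control, or extraction blank).
#'
#' @param intensities Numeric matrix, samples in rows, features in columns.
#'   Values must be nonnegative; `NA` marks a missing (undetected) peak and is
#'   distinct from a measured zero.
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to the matrix rownames).
#' @param feature_ids Character vector of unique feature identifiers, e.g.
#'   `"M123.4T56.7_pos"` tags (defaults to the matrix colnames).
#' @param batch Per-sample batch label (coerced to character).
#' @param injection_order Per-sample positive integer, unique within a batch.
#' @param role Per-sample role, one of `"study"`, `"qc"`, `"blank"`.
#'
#' @return An object of class `peak_table`: a list with elements
#'   `intensities`, `sample_ids`, `feature_ids`, `batch`, `injection_order`,
#'   `role`.
#' @export
peak_table <- function(intensities, sample_ids = rownames(intensities),
                       feature_ids = colnames(intensities),
                       batch = rep("B1", nrow(intensities)),
                       injection_order = seq_len(nrow(intensities)),
                       role = rep("study", nrow(intensities))) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(intensities)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(intensities)))
  rownames(intensities) <- sample_ids
  colnames(intensities) <- feature_ids
  pt <- structure(
    list(intensities = intensities,
         sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids),
         batch = as.character(batch),
         injection_order = as.integer(injection_order),
         role = as.character(role)),
    class = "peak_table")
  validate_peak_table(pt)
  pt
}

#' Validate a peak table
#'
#' Checks the structural invariants: matching dimensions, unique identifiers,
#' nonnegative intensities, positive injection orders unique within batch, and
#' recognised sample roles. Called by all constructors and readers.
#'
#' @param pt A `peak_table`.
#' @return `pt`, invisibly, if valid; otherwise an error naming the offending
#'   identifiers.
#' @export
validate_peak_table <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  n <- nrow(pt$intensities); p <- ncol(pt$intensities)
  if (length(pt$sample_ids) != n)
    stop("sample_ids length (", length(pt$sample_ids), ") != number of rows (", n, ")")
  if (length(pt$feature_ids) != p)
    stop("feature_ids length (", length(pt$feature_ids), ") != number of columns (", p, ")")
  dup_s <- unique(pt$sample_ids[duplicated(pt$sample_ids)])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  dup_f <- unique(pt$feature_ids[duplicated(pt$feature_ids)])
  if (length(dup_f))
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "))
  neg <- which(pt$intensities < 0)
  if (length(neg))
    stop("negative intensities in ", length(neg), " cell(s); first at [",
         paste(arrayInd(neg[1], dim(pt$intensities)), collapse = ","), "]")
  for (v in c("batch", "injection_order", "role"))
    if (length(pt[[v]]) != n) stop(v, " length != number of samples")
  if (anyNA(pt$injection_order) || any(pt$injection_order < 1))
    stop("injection_order must be positive integers")
  for (b in unique(pt$batch)) {
    io <- pt$injection_order[pt$batch == b]
    if (anyDuplicated(io))
      stop("injection_order not unique within batch ", b)
  }
  bad_role <- setdiff(unique(pt$role), c("study", "qc", "blank"))
  if (length(bad_role))
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "))
  invisible(pt)
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", nrow(x$intensities), " samples x ", ncol(x$intensities),
      " features\n", sep = "")
  cat("  roles: ", paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                         collapse = ", "), "\n", sep = "")
  cat("  batches: ", paste(unique(x$batch), collapse = ", "), "\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$intensities)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

#' Subset a peak table by sample and/or feature
#'
#' @param x A `peak_table`.
#' @param samples,features Index vectors (integer, logical, or identifier).
#' @return A `peak_table` restricted to the requested rows/columns.
#' @export
subset_peak_table <- function(x, samples = NULL, features = NULL) {
  si <- seq_along(x$sample_ids)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$sample_ids) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  fi <- seq_along(x$feature_ids)
  if (!is.null(features)) {
    fi <- if (is.character(features)) match(features, x$feature_ids) else fi[features]
    if (anyNA(fi)) stop("unknown feature id(s)")
  }
  peak_table(x$intensities[si, fi, drop = FALSE],
             sample_ids = x$sample_ids[si], feature_ids = x$feature_ids[fi],
             batch = x$batch[si], injection_order = x$injection_order[si],
             role = x$role[si])
}

#' Read a peak table from a delimited text file
#'
#' The on-disk layout is a rectangular table with annotation columns
#' `sample_id`, `batch`, `injection_order`, `role` followed by one column per
#' feature (orientation `"samples_in_rows"`, the default) or the transpose
#' with features in rows and one column per sample plus annotation rows
#' (orientation `"features_in_rows"`). Empty cells and the literal `NA` are
#' read as missing; zeros are measured zeros, not missing values.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"`.
#' @param orientation `"samples_in_rows"` or `"features_in_rows"`.
#' @return A validated `peak_table`.
#' @export
read_peak_table <- function(path, dialect = c("csv", "tsv"),
                            orientation = c("samples_in_rows", "features_in_rows")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (orientation == "features_in_rows") {
    # first column = feature id; annotation rows named in first column
    ids <- df[[1]]
    body <- as.matrix(df[, -1, drop = FALSE])
    ann_rows <- c("batch", "injection_order", "role")
    is_ann <- ids %in% ann_rows
    ann <- body[is_ann, , drop = FALSE]
    rownames(ann) <- ids[is_ann]
    mat <- body[!is_ann, , drop = FALSE]
    intens <- t(apply(mat, c(1, 2), as.numeric))
    df <- data.frame(sample_id = colnames(body), stringsAsFactors = FALSE)
    df$batch <- if ("batch" %in% rownames(ann)) ann["batch", ] else "B1"
    df$injection_order <- if ("injection_order" %in% rownames(ann))
      as.integer(ann["injection_order", ]) else seq_len(nrow(df))
    df$role <- if ("role" %in% rownames(ann)) ann["role", ] else "study"
    rownames(intens) <- df$sample_id
    colnames(intens) <- ids[!is_ann]
    return(peak_table(intens, sample_ids = df$sample_id,
                      feature_ids = colnames(intens), batch = df$batch,
                      injection_order = df$injection_order, role = df$role))
  }
  ann_cols <- intersect(c("sample_id", "batch", "injection_order", "role"), names(df))
  if (!"sample_id" %in% ann_cols) stop("missing mandatory column: sample_id")
  feat_cols <- setdiff(names(df), ann_cols)
  if (!length(feat_cols)) stop("no feature columns found")
  intens <- as.matrix(df[, feat_cols, drop = FALSE])
  storage.mode(intens) <- "double"
  peak_table(intens,
             sample_ids = as.character(df$sample_id),
             feature_ids = feat_cols,
             batch = if ("batch" %in% names(df)) df$batch else rep("B1", nrow(df)),
             injection_order = if ("injection_order" %in% names(df))
               df$injection_order else seq_len(nrow(df)),
             role = if ("role" %in% names(df)) df$role else rep("study", nrow(df)))
}

#' Write a peak table to a delimited text file
#'
#' Inverse of [read_peak_table()] for the `"samples_in_rows"` orientation.
#' Missing values are written as empty cells so the round trip preserves
#' missingness; finite values round-trip bit-identically via full-precision
#' decimal formatting.
#'
#' @param pt A `peak_table`.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(pt, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  validate_peak_table(pt)
  sep <- if (dialect == "csv") "," else "\t"
  num <- apply(pt$intensities, c(1, 2), function(v)
    if (is.na(v)) "" else format(v, digits = 17, scientific = TRUE))
  header <- paste(c("sample_id", "batch", "injection_order", "role",
                    pt$feature_ids), collapse = sep)
  rows <- vapply(seq_along(pt$sample_ids), function(i)
    paste(c(pt$sample_ids[i], pt$batch[i], pt$injection_order[i], pt$role[i],
            num[i, ]), collapse = sep), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
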