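#' Map a raw prediction triple onto the ternary simplex
#'
#' The three one-vs-rest models yield one membership-scale value per pole
#' (cholestatic, hepatocellular, recovered); individually they are unbounded.
#' The simplex mapping clips negative components to zero and divides by the
#' sum, so the result reads directly as percentages of each phenotype. A
#' triple whose clipped sum is zero carries no phenotype information and maps
#' to the barycentre `(1/3, 1/3, 1/3)` with `degenerate = TRUE`.
#'
#' @param y_c,y_h,y_r Raw predicted values for the cholestatic,
#'   hepatocellular, and recovered poles (vectorised; or pass an n x 3 matrix
#'   as `y_c`).
#' @return A data frame with columns `c`, `h`, `r` (nonnegative, summing to
#'   1) and `degenerate`.
#' @export
to_ternary <- function(y_c, y_h = NULL, y_r = NULL) {
  if (is.matrix(y_c) || is.data.frame(y_c)) {
    m <- as.matrix(y_c)
    stopifnot(ncol(m) == 3)
  } else {
    m <- cbind(y_c, y_h, y_r)
  }
  if (any(!is.finite(m))) stop("non-finite prediction triple")
  m[m < 0] <- 0
  s <- rowSums(m)
  deg <- s == 0
  m[deg, ] <- 1
  s[deg] <- 3
  out <- data.frame(c = m[, 1] / s, h = m[, 2] / s, r = m[, 3] / s,
                    degenerate = deg, row.names = NULL)
  if (!is.null(rownames(y_c)) && (is.matrix(y_c) || is.data.frame(y_c)))
    out$sample_id <- rownames(y_c)
  out
}

#' Softmax alternative to the clip-normalise simplex mapping
#'
#' Provided for comparison: `exp(y) / sum(exp(y))` never clips but compresses
#' extreme predictions.
#'
#' @inheritParams to_ternary
#' @return As [to_ternary()], with `degenerate` always `FALSE`.
#' @export
to_ternary_softmax <- function(y_c, y_h = NULL, y_r = NULL) {
  m <- if (is.matrix(y_c) || is.data.frame(y_c)) as.matrix(y_c) else
    cbind(y_c, y_h, y_r)
  if (any(!is.finite(m))) stop("non-finite prediction triple")
  e <- exp(m - apply(m, 1, max))
  s <- rowSums(e)
  data.frame(c = e[, 1] / s, h = e[, 2] / s, r = e[, 3] / s,
             degenerate = FALSE, row.names = NULL)
}

#' Flag residual DILI in clinically recovered samples
#'
#' A sample whose clinical chemistry says "recovered" but whose metabolome
#' still projects a substantial cholestatic or hepatocellular component is
#' flagged: `major` when the larger of the C and H coordinates reaches
#' `major`, `minor` when it reaches `minor`, `none` otherwise. Samples whose
#' clinical label is not recovered are never flagged.
#'
#' @param coord A ternary coordinate row (list or one-row data frame with
#'   `c`, `h`, `r`).
#' @param clinical_label The sample's rule-based clinical label.
#' @param minor,major Flag thresholds on the larger injury coordinate
#'   (defaults 0.20 and 0.40).
#' @return A list with `level` (`none`/`minor`/`major`) and `driver` (`C`,
#'   `H`, `both`, or `NA` when unflagged). The driver is `both` when the two
#'   injury coordinates are within 0.05 of each other.
#' @export
residual_dili_flag <- function(coord, clinical_label, minor = 0.20,
                               major = 0.40) {
  stopifnot(minor <= major)
  if (!identical(clinical_label, "recovered"))
    return(list(level = "none", driver = NA_character_))
  cc <- as.numeric(coord[["c"]]); hh <- as.numeric(coord[["h"]])
  top <- max(cc, hh)
  level <- if (top >= major) "major" else if (top >= minor) "minor" else "none"
  driver <- if (level == "none") NA_character_
  else if (abs(cc - hh) <= 0.05) "both" else if (cc > hh) "C" else "H"
  list(level = level, driver = driver)
}

#' Assemble per-patient phenotype trajectories
#'
#' @param coords Data frame with `sample_id`, `c`, `h`, `r`.
#' @param records Clinical records (must contain `sample_id`, `patient_id`,
#'   `timepoint_index`).
#' @param calls Optional clinical calls ([classify_cohort()]`$calls`) to
#'   attach labels.
#' @return Named list of `trajectory` objects, each a data frame ordered by
#'   timepoint with columns `sample_id`, `timepoint_index`, `c`, `h`, `r`,
#'   `label`.
#' @export
build_trajectories <- function(coords, records, calls = NULL) {
  df <- merge(records[, c("sample_id", "patient_id", "timepoint_index")],
              coords[, c("sample_id", "c", "h", "r")], by = "sample_id")
  df$label <- if (!is.null(calls))
    calls$label[match(df$sample_id, calls$sample_id)] else NA_character_
  out <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$timepoint_index), ]
    if (anyDuplicated(d$timepoint_index))
      stop("duplicate timepoints for patient ", d$patient_id[1])
    rownames(d) <- NULL
    structure(d, class = c("trajectory", "data.frame"))
  })
  out
}

#' Classify longitudinal phenotype transitions
#'
#' For each consecutive pair of timepoints the move on the simplex is
#' labelled: `toward_recovery` when the recovered coordinate gains at least
#' `delta`; `h_to_c` when the cholestatic coordinate gains at least `delta`
#' while the hepatocellular coordinate loses at least `delta`; `c_to_h` for
#' the reverse; `stable` otherwise. The whole-trajectory summary is the most
#' frequent non-stable step label, or `stable`.
#'
#' @param trajectory A `trajectory` from [build_trajectories()] (or any data
#'   frame with ordered `c`, `h`, `r` rows).
#' @param delta Minimum coordinate change to call a transition (default
#'   0.15).
#' @return A list with `steps` (data frame: `from`, `to`, `d_c`, `d_h`,
#'   `d_r`, `move`) and `summary`. A single-point trajectory yields empty
#'   steps and summary `"single_timepoint"`.
#' @export
classify_transition <- function(trajectory, delta = 0.15) {
  tr <- as.data.frame(trajectory)
  n <- nrow(tr)
  if (n < 2)
    return(list(steps = data.frame(), summary = "single_timepoint"))
  steps <- lapply(seq_len(n - 1), function(i) {
    dc <- tr$c[i + 1] - tr$c[i]
    dh <- tr$h[i + 1] - tr$h[i]
    dr <- tr$r[i + 1] - tr$r[i]
    move <- if (dr >= delta) "toward_recovery"
    else if (dc >= delta && dh <= -delta) "h_to_c"
    else if (dh >= delta && dc <= -delta) "c_to_h"
    else "stable"
    data.frame(from = i, to = i + 1, d_c = dc, d_h = dh, d_r = dr,
               move = move, stringsAsFactors = FALSE)
  })
  steps <- do.call(rbind, steps)
  moves <- steps$move[steps$move != "stable"]
  summary <- if (!length(moves)) "stable" else
    names(sort(table(moves), decreasing = TRUE))[1]
  list(steps = steps, summary = summary)
}

# affine map from simplex (c, h, r) to the plane: C at the left corner,
# H at the right corner, R at the apex
simplex_to_plane <- function(c, h, r) {
  data.frame(x = h + r / 2, y = r * sqrt(3) / 2)
}

#' Render a ternary phenotype plot
#'
#' Draws samples on the C/H/R simplex with the conventional colour scheme for
#' the rule-based clinical classes — green: cholestatic; orange:
#' hepatocellular; white: mixed; blue: recovered — and, when timepoints are
#' supplied, the collection order printed inside each marker. A companion TSV
#' with the plotted coordinates and labels is written next to the image.
#'
#' @param coords Data frame with `sample_id`, `c`, `h`, `r`, optionally
#'   `label` (clinical class) and `timepoint_index`.
#' @param path Output image path; the extension selects the device (`.svg`,
#'   `.png`, or `.pdf`). The TSV replaces the extension with `.tsv`.
#' @param title Optional plot title.
#' @return Invisibly, a list with the `ggplot` object and the TSV path.
#' @export
render_ternary <- function(coords, path, title = NULL) {
  if (nrow(coords) == 0) stop("no coordinates to plot")
  stopifnot(all(c("sample_id", "c", "h", "r") %in% names(coords)))
  xy <- simplex_to_plane(coords$c, coords$h, coords$r)
  df <- cbind(coords, xy)
  if (!"label" %in% names(df)) df$label <- "unclassifiable"
  pal <- c(cholestatic = "#2ca25f", hepatocellular = "#ff8c00",
           mixed = "#ffffff", recovered = "#3182bd",
           unclassifiable = "#bdbdbd")
  tri <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$label), shape = 21,
                        size = 5, colour = "grey30") +
    ggplot2::scale_fill_manual(values = pal, name = "clinical class") +
    ggplot2::annotate("text", x = c(-0.04, 1.04, 0.5),
                      y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                      label = c("C", "H", "R"), fontface = "bold") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
  if ("timepoint_index" %in% names(df))
    gg <- gg + ggplot2::geom_text(ggplot2::aes(label = .data$timepoint_index),
                                  size = 2.6)
  if (!is.null(title)) gg <- gg + ggplot2::ggtitle(title)
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext, svg = grDevices::svg, png = function(f, width, height)
    grDevices::png(f, width = width, height = height, units = "in", res = 150),
    pdf = grDevices::pdf,
    stop("unsupported image extension: .", ext))
  dev(path, width = 6, height = 5.5)
  print(gg)
  grDevices::dev.off()
  tsv <- sub(paste0("\\.", ext, "$"), ".tsv", path)
  out_cols <- intersect(c("sample_id", "c", "h", "r", "label",
                          "timepoint_index", "degenerate"), names(df))
  tab <- df[, out_cols, drop = FALSE]
  for (v in c("c", "h", "r")) tab[[v]] <- round(tab[[v]], 6)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(plot = gg, tsv = tsv))
}
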