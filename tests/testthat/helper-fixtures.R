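# Shared fixture builders. Everything is generated in code so that the test
# tree stays plain text; sizes are kept small except where a check needs the
# cohort-scale structure.

toy_peak_table <- function(n = 3, p = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n * p, 1000, 100)), n, p,
              dimnames = list(paste0("S", seq_len(n)), paste0("F", seq_len(p))))
  peak_table(m)
}

# peak table with interleaved QCs in one batch and low measurement noise,
# suitable for drift-correction checks
qc_peak_table <- function(n_study = 40, p = 25, qc_every = 5, noise = 0.03,
                          seed = 99) {
  set.seed(seed)
  base <- runif(p, 5e3, 5e4)
  ids <- character(); roles <- character(); rowsm <- list()
  qn <- 0L
  add <- function(role) {
    if (role == "qc") { qn <<- qn + 1L; id <- sprintf("QC%02d", qn) }
    else id <- sprintf("S%03d", length(ids) + 1L)
    ids <<- c(ids, id); roles <<- c(roles, role)
    rowsm[[length(rowsm) + 1]] <<- base * exp(rnorm(p, 0, noise)) *
      if (role == "qc") 1 else exp(rnorm(p, 0, 0.3))
  }
  add("qc")
  for (i in seq_len(n_study)) {
    add("study")
    if (i %% qc_every == 0) add("qc")
  }
  add("qc")
  m <- do.call(rbind, rowsm)
  rownames(m) <- ids
  colnames(m) <- paste0("F", seq_len(p))
  peak_table(m, role = roles)
}

toy_clinical_csv <- function(path, rows) {
  writeLines(c("sample_id,patient_id,timepoint,alt,alp,bilirubin", rows), path)
  path
}

# small, fast simulation settings for structural checks
small_config <- function(seed = 1, ...) {
  defaults <- list(n_patients = 24, n_features = 120, n_informative_c = 15,
                   n_informative_h = 15, drift_amplitude = 0,
                   missing_rate = 0.02, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

qc_rsd <- function(pt) {
  qc <- pt$intensities[pt$role == "qc", , drop = FALSE]
  apply(qc, 2, function(v) stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE))
}
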