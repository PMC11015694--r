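#' Write an epoch set to the fixture CSV format
#'
#' One CSV per subject: columns `trial_id`, `stimulus_label`, `correct`,
#' `channel`, then one column per time sample labelled with its time in ms.
#' Each trial occupies one row per channel. Amplitudes are written with 17
#' significant digits so the file round-trips bit-exactly through
#' [read_epochs()].
#'
#' @param epochs An [epoch_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$amplitudes)
  n_tr <- d[1]; n_ch <- d[2]
  header <- c("trial_id", "stimulus_label", "correct", "channel",
              format(epochs$time_axis, trim = TRUE, scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  for (i in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      vals <- sprintf("%.17g", epochs$amplitudes[i, ch, ])
      writeLines(paste(c(i, epochs$stimulus_label[i],
                         tolower(epochs$correct[i]), epochs$channels[ch],
                         vals), collapse = ","), con)
    }
  }
  invisible(path)
}

#' Read an epoch set
#'
#' `format = "fixture"` reads the per-subject CSV written by
#' [write_epochs()]. `format = "edf"` reads a continuous EDF+ recording with
#' annotation events and routes it through [segment()] onto the canonical
#' epoch grid.
#'
#' @param path Input file path.
#' @param format `"fixture"` or `"edf"`.
#' @param subject_id Identifier for the resulting epoch set (defaults to the
#'   file name without extension).
#' @param span Epoch limits in ms (EDF mode).
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path, format = c("fixture", "edf"),
                        subject_id = NULL, span = c(-200, 800)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  if (format == "edf") {
    rec <- read_edf(path)
    if (!all(c("Fp1", "Fp2") %in% rownames(rec$signals)))
      stop("EDF file ", path, " is missing channel Fp1 or Fp2")
    return(segment(rec$signals[c("Fp1", "Fp2"), , drop = FALSE], rec$events,
                   sampling_rate = rec$sampling_rate, span = span,
                   subject_id = subject_id))
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("trial_id", "stimulus_label", "correct", "channel")
  if (!all(meta_cols %in% names(df)))
    stop("fixture file ", path, " lacks required columns: ",
         paste(setdiff(meta_cols, names(df)), collapse = ", "))
  t_axis <- as.numeric(setdiff(names(df), meta_cols))
  if (anyNA(t_axis))
    stop("fixture file ", path, " has non-numeric sample column labels")
  channels <- unique(df$channel)
  trial_ids <- unique(df$trial_id)
  amp <- array(NA_real_, dim = c(length(trial_ids), length(channels),
                                 length(t_axis)))
  vals <- as.matrix(df[, !(names(df) %in% meta_cols), drop = FALSE])
  ti <- match(df$trial_id, trial_ids)
  ci <- match(df$channel, channels)
  for (r in seq_len(nrow(df))) amp[ti[r], ci[r], ] <- vals[r, ]
  lab <- df$stimulus_label[!duplicated(df$trial_id)]
  corr <- as.logical(df$correct[!duplicated(df$trial_id)])
  epoch_set(amp, t_axis, lab, corr, subject_id = subject_id,
            channels = channels)
}

#' Write a cohort to disk
#'
#' Emits the subject metadata table (`metadata.csv`) and one fixture epoch
#' CSV per subject (`epochs/<subject_id>.csv`) under `dir`.
#'
#' @param cohort An `erp_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort_metadata(cohort), file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  for (s in cohort)
    write_epochs(s$epochs,
                 file.path(dir, "epochs", paste0(s$profile$subject_id, ".csv")))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `metadata.csv` and `epochs/*.csv` (or
#'   `epochs/*.edf` with `format = "edf"`).
#' @param format Epoch file format.
#' @return An `erp_cohort`-style list of `list(profile, epochs)`.
#' @export
read_cohort <- function(dir, format = c("fixture", "edf")) {
  format <- match.arg(format)
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  ext <- if (format == "edf") ".edf" else ".csv"
  cohort <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    snsb <- c(attention = row$attention, language = row$language,
              visuospatial = row$visuospatial, memory = row$memory,
              frontal = row$frontal)
    prof <- subject_profile(row$subject_id, row$group, row$age, row$sex,
                            row$education, row$mmse, snsb)
    ep <- read_epochs(file.path(dir, "epochs", paste0(row$subject_id, ext)),
                      format = format, subject_id = row$subject_id)
    list(profile = prof, epochs = ep)
  })
  structure(cohort, class = "erp_cohort")
}
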