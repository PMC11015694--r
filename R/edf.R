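# Minimal EDF/EDF+C support: continuous signals plus annotation-based
# events, enough to round-trip two-channel recordings for epoching. 16-bit
# quantization applies (physical range +-1000 uV), so amplitude round trips
# are exact only to ~0.03 uV.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a continuous recording to an EDF+ file
#'
#' Stores the channels as 16-bit signals (physical range +-1000 uV, 1-second
#' data records) and the events as EDF+ annotations. Behaviorally incorrect
#' events are written with a `"/err"` suffix on the annotation label, which
#' [read_edf()] maps back to `correct = FALSE`.
#'
#' @param continuous Channels x samples numeric matrix (uV), row names =
#'   channel labels.
#' @param sampling_rate Hz (integer).
#' @param events Data frame with `onset_ms`, `label`, optional `correct`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(continuous, sampling_rate, events, path) {
  stopifnot(is.matrix(continuous), sampling_rate == round(sampling_rate))
  if (is.null(events$correct)) events$correct <- TRUE
  n_ch <- nrow(continuous)
  channels <- rownames(continuous)
  if (is.null(channels)) channels <- paste0("CH", seq_len(n_ch))
  n_samp <- ncol(continuous)
  nr <- as.integer(sampling_rate)            # samples per 1 s record
  n_rec <- ceiling(n_samp / nr)
  pad <- n_rec * nr - n_samp
  if (pad > 0) continuous <- cbind(continuous, matrix(0, n_ch, pad))

  pmin <- -1000; pmax <- 1000; dmin <- -32768L; dmax <- 32767L
  digital <- round((continuous - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  digital[] <- pmin(pmax(digital, dmin), dmax)

  # annotation TALs per record: a timestamp TAL then events in that record
  ann <- lapply(seq_len(n_rec) - 1, function(r) {
    buf <- c(charToRaw(paste0("+", r, "\x14\x14")), as.raw(0))
    sel <- events$onset_ms >= r * 1000 & events$onset_ms < (r + 1) * 1000
    for (i in which(sel)) {
      lab <- events$label[i]
      if (!isTRUE(events$correct[i])) lab <- paste0(lab, "/err")
      tal <- sprintf("+%.4f\x14%s\x14", events$onset_ms[i] / 1000, lab)
      buf <- c(buf, charToRaw(tal), as.raw(0))
    }
    buf
  })
  ann_bytes <- max(vapply(ann, length, integer(1)))
  ann_nr <- as.integer(ceiling(ann_bytes / 2))

  ns <- n_ch + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, width, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("EDF+C", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)

  labels <- c(channels, "EDF Annotations")
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                     # transducer
  for (i in seq_len(ns)) wr(if (i <= n_ch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) pmin else -1, 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) pmax else 1, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                     # prefiltering
  for (i in seq_len(ns)) wr(if (i <= n_ch) nr else ann_nr, 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * nr + 1):(r * nr)
    for (ch in seq_len(n_ch))
      writeBin(as.integer(digital[ch, cols]), con, size = 2,
               endian = "little")
    buf <- ann[[r]]
    buf <- c(buf, raw(2 * ann_nr - length(buf)))
    writeBin(buf, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, reconstructs the continuous signals in physical units
#' and collects annotation events. Only uniform-rate ordinary signals plus
#' an optional `EDF Annotations` signal are supported.
#'
#' @param path EDF file path.
#' @return List: `signals` (channels x samples matrix, uV, row names from
#'   the header), `sampling_rate` (Hz), `events` (data frame `onset_ms`,
#'   `label`, `correct`).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                               # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)        # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  if (length(unique(nr[sig_idx])) > 1)
    stop("non-uniform sampling across signals is not supported")
  sampling_rate <- nr[sig_idx[1]] / rec_dur

  signals <- matrix(0, length(sig_idx), n_rec * nr[sig_idx[1]])
  rownames(signals) <- labels[sig_idx]
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2 * nr[i]))
      } else {
        d <- readBin(con, "integer", nr[i], size = 2, endian = "little")
        j <- match(i, sig_idx)
        cols <- ((r - 1) * nr[i] + 1):(r * nr[i])
        signals[j, cols] <- (d - dmin[i]) / (dmax[i] - dmin[i]) *
          (pmax[i] - pmin[i]) + pmin[i]
      }
    }
  }

  events <- parse_edf_annotations(ann_raw)
  list(signals = signals, sampling_rate = sampling_rate, events = events)
}

# Split the concatenated annotation bytes into TALs and extract labelled
# events; timestamp-only TALs (empty label) are dropped.
parse_edf_annotations <- function(ann_raw) {
  out <- data.frame(onset_ms = numeric(0), label = character(0),
                    correct = logical(0), stringsAsFactors = FALSE)
  if (!length(ann_raw)) return(out)
  zero <- ann_raw == as.raw(0)
  grp <- cumsum(c(TRUE, zero[-length(zero)]))
  chunks <- split(ann_raw[!zero], grp[!zero])
  for (ch in chunks) {
    txt <- rawToChar(ch)
    parts <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    onset <- as.numeric(strsplit(parts[1], "\x15", fixed = TRUE)[[1]][1])
    for (lab in parts[-1]) {
      if (!nzchar(lab)) next
      correct <- !grepl("/err$", lab)
      out <- rbind(out, data.frame(
        onset_ms = onset * 1000, label = sub("/err$", "", lab),
        correct = correct, stringsAsFactors = FALSE))
    }
  }
  out[order(out$onset_ms), , drop = FALSE]
}
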