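#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts one epoch per event from a continuous multichannel series. The epoch
#' grid spans `span` ms around each event onset on the recording's sampling
#' grid; sample `k` of a trial holds the continuous value at
#' `onset + span[1] + (k - 1) * step` ms. Events whose epoch would extend
#' beyond either end of the recording are skipped with a warning.
#'
#' @param continuous Numeric matrix, channels x samples, in uV. Row names
#'   give channel names (default `Fp1`, `Fp2`). Sample `s` is at time
#'   `(s - 1) * 1000 / sampling_rate` ms from recording start.
#' @param events Data frame with columns `onset_ms`, `label` (`"target"` or
#'   `"standard"`) and optionally `correct` (logical, default `TRUE`).
#' @param sampling_rate Hz; must match the recording.
#' @param span Epoch limits in ms (half-open, see [erp_time_axis()]).
#' @param subject_id Identifier carried into the result.
#' @return An [epoch_set()] with one trial per retained event.
#' @export
segment <- function(continuous, events, sampling_rate = 250,
                    span = c(-200, 800), subject_id = "subject") {
  if (is.null(dim(continuous)) || nrow(continuous) < 1)
    stop("`continuous` must be a channels x samples matrix")
  channels <- rownames(continuous)
  if (is.null(channels)) channels <- c("Fp1", "Fp2")[seq_len(nrow(continuous))]
  if (is.null(events$correct)) events$correct <- TRUE
  step <- 1000 / sampling_rate
  t_axis <- erp_time_axis(sampling_rate, span)
  nT <- length(t_axis)
  n_samp <- ncol(continuous)

  keep <- logical(nrow(events))
  starts <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    onset_idx <- round(events$onset_ms[i] / step) + 1
    first <- onset_idx + round(span[1] / step)
    last <- first + nT - 1
    if (first < 1 || last > n_samp) {
      warning(sprintf(
        "event %d at %g ms skipped: epoch [%g, %g] ms outside recording",
        i, events$onset_ms[i], events$onset_ms[i] + span[1],
        events$onset_ms[i] + span[2]))
      next
    }
    keep[i] <- TRUE
    starts[i] <- first
  }
  idx <- which(keep)
  amp <- array(0, dim = c(length(idx), nrow(continuous), nT))
  for (j in seq_along(idx)) {
    rng <- starts[idx[j]] + 0:(nT - 1)
    amp[j, , ] <- continuous[, rng, drop = FALSE]
  }
  epoch_set(amp, t_axis, events$label[idx], events$correct[idx],
            subject_id = subject_id, channels = channels)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the pre-stimulus
#' baseline window `[-200, 0)` ms. After correction that mean is zero to
#' numerical tolerance; applying the correction twice is a no-op.
#'
#' @param epochs An [epoch_set()].
#' @param window Baseline limits in ms, half-open `[window[1], window[2])`.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  sel <- epochs$time_axis >= window[1] & epochs$time_axis < window[2]
  if (!any(sel))
    stop("no samples in the baseline window [", window[1], ", ", window[2],
         ") ms")
  amp <- epochs$amplitudes
  d <- dim(amp)
  m <- amp[, , sel, drop = FALSE]
  dim(m) <- c(d[1] * d[2], sum(sel))
  base <- rowMeans(m)                  # trial x channel means, column-major
  epochs$amplitudes <- amp - base      # broadcasts over samples
  epochs
}

#' Retain behaviorally correct trials
#'
#' Keeps targets that were accurately identified and standards that received
#' no response (the `correct` flag), dropping the rest.
#'
#' @param epochs An [epoch_set()].
#' @return The filtered `epoch_set`.
#' @export
select_correct_trials <- function(epochs) {
  subset_trials(epochs, epochs$correct)
}

#' Reject artifact trials by amplitude threshold
#'
#' A trial is clean iff every sample on every channel satisfies
#' `|amplitude| <= threshold` (joint rule, the default). With
#' `rule = "per_channel"` the per-channel masks are additionally returned
#' (a channel is clean if its own samples are bounded); the returned epoch
#' subset still uses the joint rule so channels stay paired.
#'
#' @param epochs An [epoch_set()].
#' @param threshold Rejection threshold in uV; default 100.
#' @param rule `"joint"` or `"per_channel"`.
#' @return A list: `epochs` (clean subset), `keep` (joint per-trial logical
#'   mask) and `keep_by_channel` (trials x channels logical matrix).
#' @export
reject_artifact_trials <- function(epochs, threshold = 100,
                                   rule = c("joint", "per_channel")) {
  rule <- match.arg(rule)
  stopifnot(threshold > 0)
  d <- dim(epochs$amplitudes)
  over <- abs(epochs$amplitudes) > threshold
  dim(over) <- c(d[1] * d[2], d[3])
  keep_by_channel <- matrix(rowSums(over) == 0, nrow = d[1],
                            dimnames = list(NULL, epochs$channels))
  keep <- apply(keep_by_channel, 1, all)
  list(epochs = subset_trials(epochs, keep), keep = keep,
       keep_by_channel = keep_by_channel)
}

# Centered moving average with shrinking windows at the edges; x is a
# trials x samples matrix. Exact (cumulative-sum) implementation; the
# row-wise cumulative sums are computed as one BLAS multiply.
moving_average_rows <- function(x, order) {
  h <- (order - 1) / 2
  n <- ncol(x)
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  ones <- matrix(1, n, n)
  ones[lower.tri(ones)] <- 0          # upper-triangular incl. diagonal
  cs <- cbind(0, x %*% ones)
  (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(x))
}

#' Smooth single-trial waveforms with a centered moving average
#'
#' Applies an `order`-point centered moving-average filter to every trial and
#' channel. At the epoch edges the window shrinks to the available samples
#' (no padding or reflection), so constant signals pass through unchanged.
#'
#' @param epochs An [epoch_set()].
#' @param order Odd window length in samples; default 9.
#' @return The smoothed `epoch_set`.
#' @export
smooth_trials <- function(epochs, order = 9) {
  if (order %% 2 == 0) stop("smoothing order must be odd, got ", order)
  if (order < 1 || order > length(epochs$time_axis))
    stop("smoothing order must be in [1, number of samples]")
  if (order == 1) return(epochs)
  amp <- epochs$amplitudes
  for (ch in seq_along(epochs$channels)) {
    m <- matrix(amp[, ch, ], nrow = dim(amp)[1])
    amp[, ch, ] <- moving_average_rows(m, order)
  }
  epochs$amplitudes <- amp
  epochs
}

#' Decide subject inclusion from clean-trial counts
#'
#' Applies the two trial-count screens: a subject is excluded with reason
#' `no_clean_trials` if any condition x channel cell has zero clean trials,
#' else with reason `below_half_clean` if any cell's clean fraction (clean
#' over all trials of that condition) is below `min_clean_fraction`; exactly
#' at the threshold counts as included.
#'
#' @param counts Data frame with columns `condition`, `channel`, `n_total`,
#'   `n_correct`, `n_clean`.
#' @param min_clean_fraction Default 0.5.
#' @return A list of class `preprocess_report`: `counts` (with
#'   `clean_fraction` added), `included`, `exclusion_reason`.
#' @export
assess_inclusion <- function(counts, min_clean_fraction = 0.5) {
  stopifnot(all(c("condition", "channel", "n_total", "n_correct",
                  "n_clean") %in% names(counts)))
  if (any(counts$n_clean > counts$n_correct) ||
      any(counts$n_correct > counts$n_total))
    stop("inconsistent counts: need n_clean <= n_correct <= n_total")
  counts$clean_fraction <- counts$n_clean / counts$n_total
  reason <- "none"
  if (any(counts$n_clean == 0)) {
    reason <- "no_clean_trials"
  } else if (any(counts$clean_fraction < min_clean_fraction)) {
    reason <- "below_half_clean"
  }
  structure(list(counts = counts, included = reason == "none",
                 exclusion_reason = reason),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report> included:", x$included,
      if (!x$included) paste0("(", x$exclusion_reason, ")") else "", "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Run the full preprocessing chain on one subject's epochs
#'
#' Fixed stage order: baseline correction, behavioral-correctness selection,
#' amplitude-threshold artifact rejection, moving-average smoothing. Returns
#' the clean smoothed epochs together with the inclusion report. (Segmentation,
#' when starting from a continuous recording, precedes this chain — see
#' [segment()].)
#'
#' @param epochs An [epoch_set()] of raw epochs.
#' @param threshold Artifact rejection threshold in uV.
#' @param smoothing_order Moving-average length (odd).
#' @param min_clean_fraction Minimum clean fraction per condition x channel.
#' @param baseline_window Baseline limits in ms.
#' @return A list: `epochs` (clean, smoothed), `report`
#'   (a `preprocess_report`).
#' @export
preprocess_epochs <- function(epochs, threshold = 100, smoothing_order = 9,
                              min_clean_fraction = 0.5,
                              baseline_window = c(-200, 0)) {
  bl <- baseline_correct(epochs, baseline_window)
  corr <- select_correct_trials(bl)
  rej <- reject_artifact_trials(corr, threshold)

  counts <- do.call(rbind, lapply(c("target", "standard"), function(cond) {
    in_cond_all <- epochs$stimulus_label == cond
    in_cond_corr <- corr$stimulus_label == cond
    do.call(rbind, lapply(seq_along(epochs$channels), function(ch) {
      data.frame(condition = cond, channel = epochs$channels[ch],
                 n_total = sum(in_cond_all),
                 n_correct = sum(in_cond_corr),
                 n_clean = sum(rej$keep_by_channel[in_cond_corr, ch]),
                 stringsAsFactors = FALSE)
    }))
  }))
  report <- assess_inclusion(counts, min_clean_fraction)
  list(epochs = smooth_trials(rej$epochs, smoothing_order), report = report)
}
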