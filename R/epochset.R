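#' Canonical epoch time axis
#'
#' Builds the uniform sample grid for an epoch spanning `span` milliseconds
#' around stimulus onset at the given sampling rate. The grid is half-open:
#' it starts at `span[1]` and stops one sample short of `span[2]`, so that a
#' 1000 ms span at 250 Hz yields exactly 250 samples and 0 ms (stimulus
#' onset) falls on the grid.
#'
#' @param sampling_rate Sampling frequency in Hz. Default 250.
#' @param span Length-2 numeric, epoch limits in ms relative to stimulus
#'   onset. Default `c(-200, 800)`.
#' @return Numeric vector of sample times in ms.
#' @export
#' @examples
#' t <- erp_time_axis()
#' length(t)   # 250
#' t[51]       # 0 (stimulus onset on-grid)
erp_time_axis <- function(sampling_rate = 250, span = c(-200, 800)) {
  stopifnot(length(span) == 2, span[1] < span[2], sampling_rate > 0)
  step <- 1000 / sampling_rate
  seq(from = span[1], to = span[2] - step, by = step)
}

#' Construct an epoch set
#'
#' An `epoch_set` holds single-trial epoched EEG for one subject: a
#' trials x channels x samples amplitude array (microvolts), the common time
#' axis (ms), a per-trial stimulus label (`"target"` or `"standard"`), and a
#' per-trial behavioral-correctness flag.
#'
#' @param amplitudes Numeric array, trials x channels x samples, in uV.
#' @param time_axis Numeric vector of sample times in ms; must be strictly
#'   increasing with a constant step and match `dim(amplitudes)[3]`.
#' @param stimulus_label Character/factor vector, one of `"target"`,
#'   `"standard"` per trial.
#' @param correct Logical vector per trial; `TRUE` for behaviorally correct
#'   trials (targets identified; standards with no response).
#' @param subject_id Identifier string.
#' @param channels Ordered channel names; default `c("Fp1", "Fp2")`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(amplitudes, time_axis, stimulus_label, correct,
                      subject_id = "subject", channels = c("Fp1", "Fp2")) {
  if (length(dim(amplitudes)) != 3)
    stop("`amplitudes` must be a trials x channels x samples array")
  n_trials <- dim(amplitudes)[1]
  stimulus_label <- as.character(stimulus_label)
  correct <- as.logical(correct)
  x <- structure(
    list(
      subject_id = as.character(subject_id),
      channels = channels,
      time_axis = as.numeric(time_axis),
      amplitudes = amplitudes,
      stimulus_label = stimulus_label,
      correct = correct
    ),
    class = "epoch_set"
  )
  validate_epoch_set(x)
}

#' Validate an epoch set
#'
#' Checks the structural invariants: dimensions consistent, uniform strictly
#' increasing time axis, stimulus onset on-grid, finite amplitudes, labels in
#' the allowed set.
#'
#' @param x An `epoch_set`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_epoch_set <- function(x) {
  d <- dim(x$amplitudes)
  if (d[2] != length(x$channels))
    stop("channel dimension (", d[2], ") does not match channels (",
         length(x$channels), ")")
  if (d[3] != length(x$time_axis))
    stop("sample dimension (", d[3], ") does not match time axis length (",
         length(x$time_axis), ")")
  if (d[1] != length(x$stimulus_label) || d[1] != length(x$correct))
    stop("per-trial metadata length does not match trial dimension")
  if (length(x$time_axis) >= 2) {
    steps <- diff(x$time_axis)
    if (any(steps <= 0)) stop("time axis must be strictly increasing")
    if (max(steps) - min(steps) > 1e-9 * max(abs(x$time_axis), 1))
      stop("time axis must have a constant sampling step")
  }
  if (!all(x$stimulus_label %in% c("target", "standard")))
    stop("stimulus labels must be 'target' or 'standard'")
  if (anyNA(x$correct)) stop("correctness flags must be TRUE/FALSE")
  if (!all(is.finite(x$amplitudes)))
    stop("amplitudes must be finite")
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$amplitudes)
  cat("<epoch_set> subject", x$subject_id, "\n")
  cat(sprintf("  %d trials (%d target, %d standard; %d correct) x %s x %d samples\n",
              d[1], sum(x$stimulus_label == "target"),
              sum(x$stimulus_label == "standard"), sum(x$correct),
              paste(x$channels, collapse = "/"), d[3]))
  cat(sprintf("  time axis [%g, %g] ms, step %g ms\n",
              x$time_axis[1], x$time_axis[length(x$time_axis)],
              if (d[3] > 1) x$time_axis[2] - x$time_axis[1] else NA))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x An `epoch_set`.
#' @return Integer count.
#' @export
n_trials <- function(x) dim(x$amplitudes)[1]

#' Subset an epoch set by trial
#'
#' @param x An `epoch_set`.
#' @param keep Logical or integer index over trials.
#' @return A new `epoch_set` with the selected trials (labels and flags
#'   carried along).
#' @export
subset_trials <- function(x, keep) {
  amp <- x$amplitudes[keep, , , drop = FALSE]
  epoch_set(amp, x$time_axis, x$stimulus_label[keep], x$correct[keep],
            subject_id = x$subject_id, channels = x$channels)
}

# Extract the trials x samples matrix for one condition and channel.
# Returns a matrix with 0 or more rows; errors on unknown channel/condition.
condition_matrix <- function(x, condition, channel) {
  ci <- match(channel, x$channels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  if (!condition %in% c("target", "standard"))
    stop("unknown condition: ", condition)
  sel <- x$stimulus_label == condition
  m <- x$amplitudes[sel, ci, , drop = FALSE]
  matrix(m, nrow = sum(sel), ncol = dim(x$amplitudes)[3])
}
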