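#' Analysis windows for the P200 and P300 components
#'
#' The two post-stimulus windows over which RVC measures are extracted:
#' 150-300 ms (P2) and 300-600 ms (P3).
#'
#' @return Named list of length-2 numeric windows in ms.
#' @export
component_windows <- function() {
  list(P2 = c(150, 300), P3 = c(300, 600))
}

#' Compute the response variance curve (RVC)
#'
#' The RVC is the across-trial sample variance of the single-trial amplitudes
#' at each time point — the pointwise variance of the individual trials
#' around the average ERP. The unbiased (n - 1 denominator) estimator is
#' used.
#'
#' @param epochs An [epoch_set()] of clean trials.
#' @param condition `"target"` or `"standard"`.
#' @param channel `"Fp1"` or `"Fp2"`.
#' @return An object of class `rvc_curve`: `subject_id`, `condition`,
#'   `channel`, `time_axis` (ms), `variance` (uV^2 per sample), `n_trials`.
#' @export
#' @examples
#' t <- erp_time_axis()
#' amp <- array(rnorm(3 * 2 * length(t)), dim = c(3, 2, length(t)))
#' es <- epoch_set(amp, t, rep("target", 3), rep(TRUE, 3))
#' rvc <- compute_rvc(es, "target", "Fp1")
compute_rvc <- function(epochs, condition, channel) {
  m <- condition_matrix(epochs, condition, channel)
  n <- nrow(m)
  if (n < 2)
    stop(structure(
      class = c("rvcerp_insufficient_data", "error", "condition"),
      list(message = sprintf(
        "subject %s: %d clean %s trial(s) on %s; need >= 2 for an RVC",
        epochs$subject_id, n, condition, channel), call = NULL)))
  mu <- colMeans(m)
  v <- colSums(sweep(m, 2, mu)^2) / (n - 1)
  structure(list(subject_id = epochs$subject_id, condition = condition,
                 channel = channel, time_axis = epochs$time_axis,
                 variance = pmax(v, 0), n_trials = n),
            class = "rvc_curve")
}

#' Build an RVC object from an explicit curve
#'
#' Mostly useful for testing measure extraction against closed-form shapes.
#'
#' @param time_axis Sample times in ms.
#' @param variance Non-negative variance values, uV^2.
#' @param ... Passed on: `subject_id`, `condition`, `channel`, `n_trials`.
#' @return An `rvc_curve`.
#' @export
rvc_curve <- function(time_axis, variance, ...) {
  extra <- list(...)
  stopifnot(length(time_axis) == length(variance), all(variance >= 0))
  structure(c(list(time_axis = as.numeric(time_axis),
                   variance = as.numeric(variance)),
              list(subject_id = extra$subject_id %||% "synthetic",
                   condition = extra$condition %||% "target",
                   channel = extra$channel %||% "Fp1",
                   n_trials = extra$n_trials %||% 2L)),
            class = "rvc_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rvc_curve <- function(x, ...) {
  cat(sprintf("<rvc_curve> %s / %s / %s: %d trials, %d samples, peak %.3g uV^2\n",
              x$subject_id, x$condition, x$channel, x$n_trials,
              length(x$variance), max(x$variance)))
  invisible(x)
}

# Trapezoidal integral of y over x (both vectors, x increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Extract the four variability measures from an RVC window
#'
#' Over the in-window samples (inclusive of samples at both window
#' endpoints):
#' * **AMPV** — the maximum variance (uV^2);
#' * **LATV** — the time of that maximum, earliest sample on ties (ms);
#' * **AUCV** — the trapezoidal area of the variance over the window
#'   (uV^2 ms);
#' * **FALV** — the 50% fractional-area latency: the time at which the
#'   cumulative trapezoidal area reaches half of AUCV, linearly interpolated
#'   between samples (ms). Undefined (`NA`) when AUCV is zero.
#'
#' @param rvc An `rvc_curve`.
#' @param window Length-2 numeric, window limits in ms.
#' @return Named list with elements `AMPV`, `LATV`, `FALV`, `AUCV`.
#' @export
extract_window_measures <- function(rvc, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  sel <- rvc$time_axis >= window[1] & rvc$time_axis <= window[2]
  if (sum(sel) < 2)
    stop("window [", window[1], ", ", window[2],
         "] ms contains fewer than 2 samples")
  t <- rvc$time_axis[sel]
  v <- rvc$variance[sel]

  i_max <- which.max(v)           # earliest index on exact ties
  ampv <- v[i_max]
  latv <- t[i_max]
  aucv <- trapz(t, v)

  if (aucv <= 0) {
    falv <- NA_real_
  } else {
    seg <- diff(t) * (v[-1] + v[-length(v)]) / 2
    cum <- c(0, cumsum(seg))
    target <- aucv / 2
    k <- which(cum >= target)[1]  # first sample where cumulative area crosses
    if (k == 1) {
      falv <- t[1]
    } else {
      falv <- t[k - 1] + (target - cum[k - 1]) / (cum[k] - cum[k - 1]) *
        (t[k] - t[k - 1])
    }
  }
  list(AMPV = ampv, LATV = latv, FALV = falv, AUCV = aucv)
}

#' Check for a discernible RVC peak in a window
#'
#' `TRUE` iff the in-window maximum is attained strictly inside the window
#' (not at either boundary sample) and is a strict local maximum relative to
#' its grid neighbours. Curves rising or falling monotonically through the
#' window, or flat plateaus, fail the check.
#'
#' @param rvc An `rvc_curve`.
#' @param window Length-2 numeric window in ms.
#' @return Logical.
#' @export
check_discernible_peak <- function(rvc, window) {
  sel <- rvc$time_axis >= window[1] & rvc$time_axis <= window[2]
  v <- rvc$variance[sel]
  if (length(v) < 3) return(FALSE)
  i <- which.max(v)
  if (i == 1 || i == length(v)) return(FALSE)
  v[i] > v[i - 1] && v[i] > v[i + 1]
}

#' Average a measure across the two prefrontal channels
#'
#' The consolidation step: measures (not waveforms) from Fp1 and Fp2 are
#' averaged arithmetically. If either channel's value is missing the result
#' is missing.
#'
#' @param m_fp1,m_fp2 Numeric measure values.
#' @return Their arithmetic mean, or `NA` if either is missing/non-finite.
#' @export
average_channel_measures <- function(m_fp1, m_fp2) {
  out <- (m_fp1 + m_fp2) / 2
  out[!is.finite(m_fp1) | !is.finite(m_fp2)] <- NA_real_
  out
}

#' Flag extreme values with Tukey fences
#'
#' A value is extreme when it falls outside `[Q1 - k IQR, Q3 + k IQR]`
#' (quartiles of the finite values, default `k = 3`). Used cohort-wide to
#' drop subjects with extreme variability values. A degenerate distribution
#' (IQR = 0) yields no flags, with a warning.
#'
#' @param x Numeric vector of one measure across subjects.
#' @param k Fence multiplier, default 3.
#' @return Logical vector of flags (`NA` values are never flagged).
#' @export
flag_extreme_values <- function(x, k = 3) {
  finite <- is.finite(x)
  if (sum(finite) < 4)
    stop("need at least 4 finite values to estimate fences")
  q <- stats::quantile(x[finite], c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) {
    warning("degenerate distribution (IQR = 0); no extreme-value flags")
    return(rep(FALSE, length(x)))
  }
  flags <- x < q[1] - k * iqr | x > q[2] + k * iqr
  flags[!finite] <- FALSE
  flags
}

#' Per-subject tidy measure table
#'
#' Computes RVCs and window measures for every condition x channel x window
#' combination of one subject's clean epochs, then appends channel-averaged
#' (`channel = "avg"`) rows. The discernible-peak flag is carried per curve;
#' averaged rows are flagged discernible only if both channels are.
#'
#' @param epochs Clean (preprocessed) [epoch_set()].
#' @param windows Named list of windows, default [component_windows()].
#' @return Data frame with columns `subject_id`, `window`, `condition`,
#'   `channel`, `AMPV`, `LATV`, `FALV`, `AUCV`, `discernible_peak`,
#'   `n_trials`.
#' @export
subject_measures <- function(epochs, windows = component_windows()) {
  rows <- list()
  for (cond in c("target", "standard")) {
    curves <- lapply(c("Fp1", "Fp2"), function(ch)
      compute_rvc(epochs, cond, ch))
    names(curves) <- c("Fp1", "Fp2")
    for (w in names(windows)) {
      win <- windows[[w]]
      per_ch <- lapply(curves, function(cv) {
        m <- extract_window_measures(cv, win)
        m$discernible_peak <- check_discernible_peak(cv, win)
        m$n_trials <- cv$n_trials
        m
      })
      for (ch in names(per_ch)) {
        m <- per_ch[[ch]]
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = epochs$subject_id, window = w, condition = cond,
          channel = ch, AMPV = m$AMPV, LATV = m$LATV, FALV = m$FALV,
          AUCV = m$AUCV, discernible_peak = m$discernible_peak,
          n_trials = m$n_trials, stringsAsFactors = FALSE)
      }
      avg <- lapply(c("AMPV", "LATV", "FALV", "AUCV"), function(nm)
        average_channel_measures(per_ch$Fp1[[nm]], per_ch$Fp2[[nm]]))
      names(avg) <- c("AMPV", "LATV", "FALV", "AUCV")
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = epochs$subject_id, window = w, condition = cond,
        channel = "avg", AMPV = avg$AMPV, LATV = avg$LATV, FALV = avg$FALV,
        AUCV = avg$AUCV,
        discernible_peak = per_ch$Fp1$discernible_peak &&
          per_ch$Fp2$discernible_peak,
        n_trials = min(per_ch$Fp1$n_trials, per_ch$Fp2$n_trials),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
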