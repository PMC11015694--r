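#' Normalized hemispheric asymmetry index
#'
#' `(Fp2 - Fp1) / (Fp2 + Fp1)` for a non-negative variability measure.
#' Dividing by the channel sum bounds the index to `[-1, 1]` and tempers the
#' influence of overall magnitude on the degree of negativity. Positive
#' values indicate larger trial-to-trial variability over the right
#' prefrontal site.
#'
#' The index is antisymmetric under channel swap and invariant to scaling
#' both channels by a common positive factor. When both inputs are zero the
#' index is undefined and `NA` is returned with a warning.
#'
#' @param value_fp2,value_fp1 Non-negative measure values (vectorized).
#' @return Dimensionless index in `[-1, 1]` (or `NA`).
#' @export
#' @examples
#' asymmetry_index(3, 1)   # 0.5
#' asymmetry_index(2, 2)   # 0
asymmetry_index <- function(value_fp2, value_fp1) {
  if (any(value_fp2 < 0 | value_fp1 < 0, na.rm = TRUE))
    stop("asymmetry_index requires non-negative channel values")
  s <- value_fp2 + value_fp1
  out <- (value_fp2 - value_fp1) / s
  zero <- is.finite(s) & s == 0
  if (any(zero)) {
    warning("asymmetry undefined where Fp2 + Fp1 = 0; returning NA")
    out[zero] <- NA_real_
  }
  out
}

#' Asymmetry table from a per-channel measure table
#'
#' For each subject x window x condition present in a [subject_measures()]
#' table, computes the asymmetry index of AMPV, AUCV, LATV and FALV from the
#' Fp2 and Fp1 rows. Latency measures are times within the positive analysis
#' windows, so all four inputs are non-negative as required.
#'
#' @param measures Data frame from [subject_measures()] (may hold many
#'   subjects).
#' @return Data frame: `subject_id`, `window`, `condition`, `AMPV_Asym`,
#'   `AUCV_Asym`, `LATV_Asym`, `FALV_Asym`.
#' @export
asymmetry_measures <- function(measures) {
  f1 <- measures[measures$channel == "Fp1", ]
  f2 <- measures[measures$channel == "Fp2", ]
  key <- function(d) paste(d$subject_id, d$window, d$condition, sep = "\r")
  f2 <- f2[match(key(f1), key(f2)), ]
  out <- data.frame(subject_id = f1$subject_id, window = f1$window,
                    condition = f1$condition, stringsAsFactors = FALSE)
  for (nm in c("AMPV", "AUCV", "LATV", "FALV")) {
    out[[paste0(nm, "_Asym")]] <-
      suppressWarnings(asymmetry_index(f2[[nm]], f1[[nm]]))
  }
  out
}
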