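#' Group summary helper
#'
#' Accepts either a raw numeric vector or a summary triple and returns the
#' canonical `c(mean, sd, n)` form. A summary triple is a named numeric
#' vector or list with elements `mean`, `sd`, `n` — this entry path allows
#' published summary statistics to be used directly and gives results
#' identical to the raw-vector path on matching inputs.
#'
#' @param x Numeric vector, or named vector/list with `mean`, `sd`, `n`.
#' @return Numeric `c(mean, sd, n)`.
#' @export
as_group_summary <- function(x) {
  nm <- names(x)
  if (!is.null(nm) && all(c("mean", "sd", "n") %in% nm)) {
    out <- c(as.numeric(x[["mean"]]), as.numeric(x[["sd"]]),
             as.numeric(x[["n"]]))
  } else {
    x <- as.numeric(x)
    out <- c(mean(x), stats::sd(x), length(x))
  }
  if (out[3] < 2) stop("each group needs n >= 2")
  if (out[2] < 0) stop("group SD must be >= 0")
  out
}

#' Two-sample t-test from raw data or summary statistics
#'
#' Student's t uses the pooled variance with `n_a + n_b - 2` degrees of
#' freedom; Welch's t uses per-group variances with Welch-Satterthwaite
#' degrees of freedom. With `variant = "auto"` an F-test of variance
#' equality at alpha = 0.05 selects Welch when it rejects, Student
#' otherwise.
#'
#' Degenerate inputs: zero variance in both groups gives statistic 0 when
#' the means agree and a flagged infinite statistic when they differ.
#'
#' @param group_a,group_b Raw numeric vectors or summary triples (see
#'   [as_group_summary()]).
#' @param variant `"student"`, `"welch"` or `"auto"`.
#' @param variable Label carried into the result.
#' @return A `group_comparison` list: `variable`, `test`, `statistic`, `df`,
#'   `p_value`, and `groups` (the two `c(mean, sd, n)` summaries).
#' @export
#' @examples
#' two_sample_t(c(mean = 72.06, sd = 6.36, n = 878),
#'              c(mean = 73.82, sd = 6.54, n = 390), variant = "student")
two_sample_t <- function(group_a, group_b,
                         variant = c("auto", "student", "welch"),
                         variable = "x") {
  variant <- match.arg(variant)
  a <- as_group_summary(group_a)
  b <- as_group_summary(group_b)
  ma <- a[1]; sa <- a[2]; na <- a[3]
  mb <- b[1]; sb <- b[2]; nb <- b[3]

  if (variant == "auto") {
    if (sa == 0 || sb == 0) {
      variant <- "student"
    } else {
      f <- sa^2 / sb^2
      p_f <- 2 * min(stats::pf(f, na - 1, nb - 1),
                     stats::pf(f, na - 1, nb - 1, lower.tail = FALSE))
      variant <- if (p_f < 0.05) "welch" else "student"
    }
  }
  if (variant == "student") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * sa^2 + (nb - 1) * sb^2) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(sa^2 / na + sb^2 / nb)
    df <- (sa^2 / na + sb^2 / nb)^2 /
      ((sa^2 / na)^2 / (na - 1) + (sb^2 / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    stat <- if (ma == mb) 0 else sign(ma - mb) * Inf
    if (!is.finite(stat))
      warning("zero variance with unequal means: infinite t statistic")
    if (variant == "welch" || !is.finite(df)) df <- na + nb - 2
  } else {
    stat <- (ma - mb) / se
  }
  p <- if (is.finite(stat)) 2 * stats::pt(-abs(stat), df) else 0
  structure(list(variable = variable, test = variant, statistic = stat,
                 df = df, p_value = p,
                 groups = list(a = c(mean = ma, sd = sa, n = na),
                               b = c(mean = mb, sd = sb, n = nb))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s, statistic = %.4g, df = %.4g, p = %.4g\n",
              x$variable, x$test, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' The classic Pearson statistic `sum((O - E)^2 / E)` without continuity
#' correction, df = 1.
#'
#' @param table 2x2 matrix of counts (e.g. sex by group).
#' @param variable Label carried into the result.
#' @return A `group_comparison` with `test = "chi_squared"`.
#' @export
#' @examples
#' pearson_chi2(matrix(c(492, 386, 196, 194), nrow = 2))
pearson_chi2 <- function(table, variable = "x") {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-squared undefined: a table margin is zero")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - expected)^2 / expected)
  structure(list(variable = variable, test = "chi_squared", statistic = stat,
                 df = 1, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 groups = list(observed = table, expected = expected)),
            class = "group_comparison")
}

#' Logistic regression of MCI status on a variability measure
#'
#' Fits the three-tier nested models relating one measure to MCI status
#' (MCI = 1, CN = 0) by maximum likelihood:
#' * tier 1 — crude: `mci ~ measure`;
#' * tier 2 — adjusted for demographics: `+ age + sex + education`
#'   (sex coded male = 1, female = 0);
#' * tier 3 — additionally adjusted for MMSE.
#'
#' By default the predictor is z-scored on the analysis cohort, so the odds
#' ratio is per SD of the measure and invariant to its physical units; set
#' `scaling = "raw"` for per-unit odds ratios. Confidence intervals are 95%
#' Wald intervals.
#'
#' @param data Data frame with columns `group` (`"CN"`/`"MCI"`), the
#'   `measure` column, and (tiers 2-3) `age`, `sex` (`"F"`/`"M"`),
#'   `education`, `mmse`. Rows with missing values in the used columns are
#'   dropped and counted.
#' @param measure Name of the predictor column.
#' @param tier 1, 2 or 3.
#' @param scaling `"z_scored"` (default) or `"raw"`.
#' @return A `logistic_model_result` list: `predictor`, `tier`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `n_used`,
#'   `predictor_scaling`.
#' @export
fit_mci_logistic <- function(data, measure, tier = 1,
                             scaling = c("z_scored", "raw")) {
  scaling <- match.arg(scaling)
  stopifnot(tier %in% 1:3, measure %in% names(data))
  covars <- switch(tier, NULL, c("age", "sex", "education"),
                   c("age", "sex", "education", "mmse"))
  used <- c("group", measure, covars)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("missing columns for tier ", tier, ": ",
         paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  if (length(unique(d$group)) < 2)
    stop("outcome has a single class; cannot fit logistic model")

  d$mci <- as.integer(d$group == "MCI")
  x <- d[[measure]]
  if (scaling == "z_scored") {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("measure has zero variance; cannot z-score")
    x <- (x - mean(x)) / s
  }
  d$.x <- x
  if (!is.null(covars)) d$sex_male <- as.integer(d$sex == "M")
  rhs <- c(".x", if (tier >= 2) c("age", "sex_male", "education"),
           if (tier >= 3) "mmse")
  fml <- stats::as.formula(paste("mci ~", paste(rhs, collapse = " + ")))
  fit <- stats::glm(fml, data = d, family = stats::binomial())
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation)")
  co <- summary(fit)$coefficients
  beta <- co[".x", "Estimate"]; se <- co[".x", "Std. Error"]
  if (abs(beta) > 15)
    stop("implausible coefficient magnitude: likely complete separation")
  z <- stats::qnorm(0.975)
  structure(list(predictor = measure, tier = tier,
                 odds_ratio = exp(beta),
                 ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                 p_value = co[".x", "Pr(>|z|)"], n_used = nrow(d),
                 predictor_scaling = scaling, beta = beta, se = se),
            class = "logistic_model_result")
}

#' @export
print.logistic_model_result <- function(x, ...) {
  cat(sprintf(
    "<logistic_model_result> %s (tier %d, %s): OR = %.3f [%.3f, %.3f], p = %.4g, n = %d\n",
    x$predictor, x$tier, x$predictor_scaling, x$odds_ratio, x$ci_low,
    x$ci_high, x$p_value, x$n_used))
  invisible(x)
}

#' Group-characterization table
#'
#' Runs the standard descriptive comparisons between CN and MCI on a subject
#' metadata table: t-tests (variant selectable, default `auto`) for the
#' continuous variables and a Pearson chi-squared test for sex.
#'
#' @param metadata Data frame with `group`, `age`, `sex`, `education`,
#'   `mmse` and the five SNSB domain columns.
#' @param variant t-test variant passed to [two_sample_t()].
#' @return List of `group_comparison` objects, one per variable.
#' @export
group_characteristics <- function(metadata, variant = "auto") {
  cn <- metadata[metadata$group == "CN", ]
  mci <- metadata[metadata$group == "MCI", ]
  vars <- c("age", "education", "mmse", "attention", "language",
            "visuospatial", "memory", "frontal")
  vars <- intersect(vars, names(metadata))
  out <- lapply(vars, function(v)
    two_sample_t(cn[[v]], mci[[v]], variant = variant, variable = v))
  names(out) <- vars
  tab <- rbind(table(factor(cn$sex, c("F", "M"))),
               table(factor(mci$sex, c("F", "M"))))
  out$sex <- pearson_chi2(t(tab), variable = "sex")
  out
}
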