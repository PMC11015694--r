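#' Pipeline run configuration
#'
#' Collects every option of the end-to-end analysis. In `"synthetic"` mode a
#' cohort is generated from `generator` (its seed is overridden by `seed`);
#' in `"fixture"`/`"edf"` mode per-subject epoch files and a metadata table
#' are read from `input_dir` (see [write_cohort()] for the layout).
#'
#' @param mode `"synthetic"`, `"fixture"` or `"edf"`.
#' @param generator A [generator_config()] (synthetic mode); defaults to
#'   `generator_config()`.
#' @param input_dir Input directory (file modes).
#' @param threshold Artifact rejection threshold, uV.
#' @param smoothing_order Moving-average length (odd samples).
#' @param min_clean_fraction Minimum clean-trial fraction per condition x
#'   channel.
#' @param windows Named list of analysis windows (ms), default
#'   [component_windows()].
#' @param fence_k Tukey fence multiplier for the extreme-value screen.
#' @param peak_rule Apply the discernible-peak exclusion (default `TRUE`).
#' @param t_variant t-test variant for group comparisons
#'   (`"auto"`/`"student"`/`"welch"`).
#' @param scaling Predictor scaling for logistic models
#'   (`"z_scored"`/`"raw"`).
#' @param logistic Fit the three-tier logistic models (default `TRUE`).
#' @param output_dir If non-`NULL`, [write_outputs()] is called on the
#'   result.
#' @param seed Integer master seed.
#' @param verbose Emit per-subject log messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "fixture", "edf"),
                       generator = NULL, input_dir = NULL,
                       threshold = 100, smoothing_order = 9,
                       min_clean_fraction = 0.5,
                       windows = component_windows(),
                       fence_k = 3, peak_rule = TRUE,
                       t_variant = "auto", scaling = "z_scored",
                       logistic = TRUE, output_dir = NULL, seed = 1L,
                       verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode != "synthetic") {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("input_dir must be an existing directory in ", mode, " mode")
  }
  structure(list(mode = mode, generator = generator, input_dir = input_dir,
                 threshold = threshold, smoothing_order = smoothing_order,
                 min_clean_fraction = min_clean_fraction, windows = windows,
                 fence_k = fence_k, peak_rule = peak_rule,
                 t_variant = t_variant, scaling = scaling,
                 logistic = logistic, output_dir = output_dir,
                 seed = as.integer(seed), verbose = verbose),
        class = "run_config")
}

measure_names <- c("AMPV", "LATV", "FALV", "AUCV")

# wide column name for one analyzed cell
wide_name <- function(window, condition, measure, suffix = "") {
  paste0(window, "_", condition, "_", measure, suffix)
}

#' Run the end-to-end variability analysis
#'
#' Executes the full chain: cohort ingestion (synthetic or files) ->
#' preprocessing (baseline, correct-trial selection, artifact rejection,
#' smoothing) -> inclusion screens (clean-trial counts, discernible RVC
#' peaks, cohort extreme-value fences) -> RVC window measures and channel
#' averaging -> asymmetry indices -> group statistics and the three-tier
#' logistic models. Deterministic under a fixed `seed`.
#'
#' Each excluded subject carries exactly one primary exclusion reason, the
#' first that applies in the order: `no_clean_trials`, `below_half_clean`,
#' `no_discernible_peak`, `extreme_variability`.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: `subjects` (inclusion ledger),
#'   `measures` (tidy per-channel table), `asymmetry`, `analysis` (wide
#'   per-subject table joined to metadata), `stats` (demographic
#'   comparisons, measure tests, logistic tiers), `config`, `seed`,
#'   `version`, `log` (character lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines[[length(log_lines) + 1]] <<- msg
    if (config$verbose) message(msg)
  }

  if (config$mode == "synthetic") {
    gen <- config$generator
    if (is.null(gen)) gen <- generator_config()
    gen$seed <- config$seed
    cohort <- generate_cohort(gen)
  } else {
    cohort <- read_cohort(config$input_dir, format = config$mode)
  }
  metadata <- cohort_metadata(cohort)
  n_sub <- length(cohort)
  say("INFO ingested %d subjects (%s mode)", n_sub, config$mode)

  ledger <- data.frame(subject_id = metadata$subject_id,
                       group = metadata$group, included = TRUE,
                       exclusion_reason = "none", stringsAsFactors = FALSE)
  measures_list <- list()

  for (i in seq_len(n_sub)) {
    s <- cohort[[i]]
    pp <- preprocess_epochs(s$epochs, threshold = config$threshold,
                            smoothing_order = config$smoothing_order,
                            min_clean_fraction = config$min_clean_fraction)
    if (!pp$report$included) {
      ledger$included[i] <- FALSE
      ledger$exclusion_reason[i] <- pp$report$exclusion_reason
      say("INFO subject %s excluded: %s", s$profile$subject_id,
          pp$report$exclusion_reason)
      next
    }
    meas <- tryCatch(subject_measures(pp$epochs, config$windows),
                     rvcerp_insufficient_data = function(e) NULL)
    if (is.null(meas)) {
      ledger$included[i] <- FALSE
      ledger$exclusion_reason[i] <- "no_clean_trials"
      say("INFO subject %s excluded: insufficient clean trials for an RVC",
          s$profile$subject_id)
      next
    }
    if (config$peak_rule &&
        !all(meas$discernible_peak[meas$channel != "avg"])) {
      ledger$included[i] <- FALSE
      ledger$exclusion_reason[i] <- "no_discernible_peak"
      say("INFO subject %s excluded: no discernible RVC peak",
          s$profile$subject_id)
      next
    }
    measures_list[[s$profile$subject_id]] <- meas
  }

  measures <- do.call(rbind, measures_list)
  rownames(measures) <- NULL
  asym <- if (!is.null(measures)) asymmetry_measures(measures) else NULL

  # wide per-subject table of channel-averaged measures + asymmetry
  analysis <- metadata[metadata$subject_id %in% names(measures_list), ,
                       drop = FALSE]
  if (!is.null(measures)) {
    avg <- measures[measures$channel == "avg", ]
    for (w in unique(avg$window)) for (cond in unique(avg$condition)) {
      sub <- avg[avg$window == w & avg$condition == cond, ]
      idx <- match(analysis$subject_id, sub$subject_id)
      for (m in measure_names)
        analysis[[wide_name(w, cond, m)]] <- sub[[m]][idx]
      asub <- asym[asym$window == w & asym$condition == cond, ]
      aidx <- match(analysis$subject_id, asub$subject_id)
      for (m in measure_names)
        analysis[[wide_name(w, cond, m, "_Asym")]] <-
          asub[[paste0(m, "_Asym")]][aidx]
    }
  }

  # cohort-level extreme-value screen on the channel-averaged measures
  meas_cols <- grep("_(AMPV|LATV|FALV|AUCV)$", names(analysis), value = TRUE)
  if (nrow(analysis) >= 4 && length(meas_cols)) {
    extreme <- rep(FALSE, nrow(analysis))
    for (cl in meas_cols) {
      flags <- tryCatch(flag_extreme_values(analysis[[cl]], config$fence_k),
                        error = function(e) rep(FALSE, nrow(analysis)))
      extreme <- extreme | flags
    }
    if (any(extreme)) {
      for (sid in analysis$subject_id[extreme]) {
        j <- match(sid, ledger$subject_id)
        ledger$included[j] <- FALSE
        ledger$exclusion_reason[j] <- "extreme_variability"
        say("INFO subject %s excluded: extreme variability value", sid)
      }
      analysis <- analysis[!extreme, , drop = FALSE]
      keep_ids <- analysis$subject_id
      measures <- measures[measures$subject_id %in% keep_ids, , drop = FALSE]
      asym <- asym[asym$subject_id %in% keep_ids, , drop = FALSE]
    }
  }

  say("INFO %d of %d subjects included", sum(ledger$included), n_sub)

  stats <- NULL
  if (!is.null(analysis) && length(unique(analysis$group)) == 2 &&
      min(table(analysis$group)) >= 2) {
    stats <- list()
    stats$group_characteristics <-
      group_characteristics(analysis, variant = config$t_variant)

    cn <- analysis[analysis$group == "CN", ]
    mci <- analysis[analysis$group == "MCI", ]
    all_cols <- c(meas_cols, grep("_Asym$", names(analysis), value = TRUE))
    tests <- lapply(all_cols, function(cl) {
      x <- cn[[cl]][is.finite(cn[[cl]])]
      y <- mci[[cl]][is.finite(mci[[cl]])]
      tt <- two_sample_t(x, y, variant = config$t_variant, variable = cl)
      data.frame(measure = cl, test = tt$test, statistic = tt$statistic,
                 df = tt$df, p_value = tt$p_value,
                 mean_cn = mean(x), sd_cn = stats::sd(x), n_cn = length(x),
                 mean_mci = mean(y), sd_mci = stats::sd(y),
                 n_mci = length(y), stringsAsFactors = FALSE)
    })
    stats$measure_tests <- do.call(rbind, tests)

    if (config$logistic) {
      fits <- list()
      for (cl in all_cols) for (tier in 1:3) {
        fit <- tryCatch(
          fit_mci_logistic(analysis, cl, tier = tier,
                           scaling = config$scaling),
          error = function(e) {
            say("WARN logistic fit failed for %s tier %d: %s", cl, tier,
                conditionMessage(e))
            NULL
          })
        if (!is.null(fit))
          fits[[length(fits) + 1]] <- data.frame(
            measure = cl, tier = tier, odds_ratio = fit$odds_ratio,
            ci_low = fit$ci_low, ci_high = fit$ci_high,
            p_value = fit$p_value, n_used = fit$n_used,
            predictor_scaling = fit$predictor_scaling,
            stringsAsFactors = FALSE)
      }
      stats$logistic <- do.call(rbind, fits)
    }
  } else {
    say("WARN group statistics skipped: fewer than 2 included subjects per group")
  }

  report <- structure(
    list(subjects = ledger, measures = measures, asymmetry = asym,
         analysis = analysis, stats = stats, config = config,
         seed = config$seed,
         version = as.character(utils::packageVersion("rvcerp")),
         log = log_lines),
    class = "run_report")
  if (!is.null(config$output_dir)) write_outputs(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", nrow(x$subjects), "subjects;",
      sum(x$subjects$included), "included\n")
  tab <- table(x$subjects$exclusion_reason)
  for (r in names(tab)) if (r != "none")
    cat(sprintf("  excluded (%s): %d\n", r, tab[[r]]))
  if (!is.null(x$stats$measure_tests)) {
    sig <- sum(x$stats$measure_tests$p_value < 0.05)
    cat(sprintf("  measure tests: %d of %d significant at 0.05\n", sig,
                nrow(x$stats$measure_tests)))
  }
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Deterministic file set under `outdir`: `measures.csv` (tidy per-channel
#' measures), `asymmetry.csv`, `analysis.csv` (wide per-subject table),
#' `stats.json`, `run_report.json` (inclusion ledger, config echo, version,
#' seed) and `rvcerp.log`.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param outdir Output directory, created if needed.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(measures = file.path(outdir, "measures.csv"),
             asymmetry = file.path(outdir, "asymmetry.csv"),
             analysis = file.path(outdir, "analysis.csv"),
             stats = file.path(outdir, "stats.json"),
             report = file.path(outdir, "run_report.json"),
             log = file.path(outdir, "rvcerp.log"))
  utils::write.csv(report$measures, paths["measures"], row.names = FALSE)
  utils::write.csv(report$asymmetry, paths["asymmetry"], row.names = FALSE)
  utils::write.csv(report$analysis, paths["analysis"], row.names = FALSE)

  stats_out <- list()
  if (!is.null(report$stats)) {
    stats_out$group_characteristics <- lapply(
      report$stats$group_characteristics, function(g)
        list(variable = g$variable, test = g$test, statistic = g$statistic,
             df = g$df, p_value = g$p_value))
    stats_out$measure_tests <- report$stats$measure_tests
    stats_out$logistic <- report$stats$logistic
  }
  jsonlite::write_json(stats_out, paths["stats"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  reasons <- table(report$subjects$exclusion_reason)
  cfg <- report$config
  cfg$generator <- NULL  # echoed separately below if present
  jsonlite::write_json(
    list(subjects = report$subjects,
         totals = list(n = nrow(report$subjects),
                       included = sum(report$subjects$included),
                       excluded = sum(!report$subjects$included),
                       by_reason = as.list(reasons)),
         config = unclass(cfg),
         generator = if (!is.null(report$config$generator))
           unclass(report$config$generator),
         version = report$version, seed = report$seed),
    paths["report"], auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE)
  writeLines(report$log, paths["log"])
  invisible(paths)
}
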