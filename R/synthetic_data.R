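#' Configuration for the synthetic oddball cohort generator
#'
#' Describes every knob of the generative model: cohort sizes, the oddball
#' trial structure (64 rare targets + 256 standards by default), the sampling
#' grid, per-group evoked-component parameters (P2 and P3 Gaussian bumps),
#' per-group trial-to-trial jitter, background noise, hemispheric imbalance,
#' artifact and behavioral-error rates, and per-group demographic
#' distributions. All randomness downstream is controlled by `seed`.
#'
#' Trial-level generative model, per trial i, channel and component c:
#' \deqn{x_i(t) = \sum_c (A_c + dA_{c,i}) \exp\{-(t - \mu_c - dL_{c,i})^2 / (2 w_c^2)\} + \epsilon(t)}
#' with `dA ~ N(0, amp_sd)`, `dL ~ N(0, lat_sd)` drawn once per trial and
#' shared between channels; on Fp2 both deviations are multiplied by
#' `right_channel_jitter_scale`, so a scale above 1 yields larger
#' trial-to-trial variance on the right channel and hence positive asymmetry
#' indices. `epsilon` is white Gaussian noise of SD `noise_sd` (or 1/f noise
#' of matched SD when `noise_type = "pink"`), independent per channel.
#'
#' Component amplitudes take `amp * target_gain` on target trials, modelling
#' the larger P300 evoked by rare attended stimuli.
#'
#' @param n_cn,n_mci Number of cognitively-normal and MCI-like subjects.
#' @param n_target_trials,n_standard_trials Trials per subject per condition.
#' @param sampling_rate Hz.
#' @param epoch_span Epoch limits in ms (half-open grid, see
#'   [erp_time_axis()]).
#' @param components Per-group (`CN`, `MCI`) list of per-component (`P2`,
#'   `P3`) parameters: `amp` (uV), `lat` (ms), `width` (Gaussian SD, ms),
#'   `target_gain` (unitless multiplier on target trials).
#' @param trial_jitter Per-group list: `amp_sd` (uV) and `lat_sd` (ms), the
#'   SDs of the trial-level amplitude and latency deviations.
#' @param between_subject Subject-level heterogeneity: `amp_sd` (uV) and
#'   `lat_sd` (ms) are the SDs of each subject's mean component amplitude
#'   and latency around the group values; `jitter_cv` is the coefficient of
#'   variation of a mean-preserving lognormal multiplier on each subject's
#'   trial-jitter SDs; `rscale_sd` is the SD of each subject's right-channel
#'   jitter scale around the group value. Set all four to 0 for homogeneous
#'   subjects whose trial-level jitter equals the group `trial_jitter`
#'   exactly.
#' @param noise_sd Background noise SD in uV.
#' @param noise_type `"white"` (default) or `"pink"` (1/f spectrum, same
#'   marginal SD).
#' @param right_channel_jitter_scale Named per-group numeric; factor applied
#'   to the trial deviations on Fp2.
#' @param artifact_rate Per-trial probability of an injected super-threshold
#'   (> 100 uV) artifact sample.
#' @param behavioral_error_rate Per-trial probability the trial is flagged
#'   behaviorally incorrect.
#' @param demographics Per-group list of distribution parameters:
#'   `age = c(mean, sd)`, `female_prop`, `education = c(mean, sd)`,
#'   `mmse = c(mean, sd)` and `snsb`, a list of five `c(mean, sd)` domain
#'   entries (attention, language, visuospatial, memory, frontal).
#'   Defaults follow the cohort's published group summaries.
#' @param seed Integer master seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_cn = 100,
                             n_mci = 100,
                             n_target_trials = 64,
                             n_standard_trials = 256,
                             sampling_rate = 250,
                             epoch_span = c(-200, 800),
                             components = NULL,
                             trial_jitter = NULL,
                             between_subject = list(amp_sd = 1.5,
                                                    lat_sd = 15,
                                                    jitter_cv = 0.3,
                                                    rscale_sd = 0.15),
                             noise_sd = 3,
                             noise_type = c("white", "pink"),
                             right_channel_jitter_scale = c(CN = 1.1, MCI = 1.3),
                             artifact_rate = 0.02,
                             behavioral_error_rate = 0.05,
                             demographics = NULL,
                             seed = 1L) {
  noise_type <- match.arg(noise_type)
  if (is.null(components)) {
    base <- list(
      P2 = list(amp = 5, lat = 200, width = 25, target_gain = 1.2),
      P3 = list(amp = 8, lat = 450, width = 50, target_gain = 1.5)
    )
    components <- list(CN = base, MCI = base)
  }
  if (is.null(trial_jitter)) {
    trial_jitter <- list(
      CN  = list(amp_sd = 1.0, lat_sd = 20),
      MCI = list(amp_sd = 1.5, lat_sd = 30)
    )
  }
  if (is.null(demographics)) demographics <- default_demographics()
  cfg <- structure(
    list(
      n_cn = as.integer(n_cn), n_mci = as.integer(n_mci),
      n_target_trials = as.integer(n_target_trials),
      n_standard_trials = as.integer(n_standard_trials),
      sampling_rate = sampling_rate, epoch_span = epoch_span,
      components = components, trial_jitter = trial_jitter,
      between_subject = between_subject,
      noise_sd = noise_sd, noise_type = noise_type,
      right_channel_jitter_scale = right_channel_jitter_scale,
      artifact_rate = artifact_rate,
      behavioral_error_rate = behavioral_error_rate,
      demographics = demographics,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
}

# Group summaries (mean, sd) used as default demographic distributions.
default_demographics <- function() {
  list(
    CN = list(
      age = c(72.06, 6.36), female_prop = 0.56,
      education = c(10.83, 4.36), mmse = c(27.68, 1.90),
      snsb = list(attention = c(9.71, 2.19), language = c(0.21, 0.28),
                  visuospatial = c(0.54, 0.37), memory = c(0.30, 0.58),
                  frontal = c(0.23, 0.57))
    ),
    MCI = list(
      age = c(73.82, 6.54), female_prop = 0.50,
      education = c(11.14, 4.48), mmse = c(26.31, 2.68),
      snsb = list(attention = c(8.54, 1.94), language = c(-0.09, 0.47),
                  visuospatial = c(0.25, 1.89), memory = c(-0.44, 0.63),
                  frontal = c(-0.24, 0.70))
    )
  )
}

#' Validate a generator configuration
#'
#' @param cfg A `generator_config`.
#' @return `cfg` or an error naming the offending field.
#' @export
validate_generator_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid generator config field `", field, "`: ",
                          why, call. = FALSE)
  }
  chk(cfg$n_cn > 0, "n_cn", "must be > 0")
  chk(cfg$n_mci > 0, "n_mci", "must be > 0")
  chk(cfg$n_target_trials > 0, "n_target_trials", "must be > 0")
  chk(cfg$n_standard_trials > 0, "n_standard_trials", "must be > 0")
  chk(cfg$sampling_rate > 0, "sampling_rate", "must be > 0")
  chk(length(cfg$epoch_span) == 2 && cfg$epoch_span[1] <= -200 &&
        cfg$epoch_span[2] >= 800, "epoch_span",
      "must contain [-200, 800] ms")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  bs <- cfg$between_subject
  chk(!is.null(bs$amp_sd) && bs$amp_sd >= 0 &&
        !is.null(bs$lat_sd) && bs$lat_sd >= 0 &&
        !is.null(bs$jitter_cv) && bs$jitter_cv >= 0 &&
        !is.null(bs$rscale_sd) && bs$rscale_sd >= 0, "between_subject",
      "amp_sd, lat_sd, jitter_cv and rscale_sd must all be >= 0")
  chk(cfg$artifact_rate >= 0 && cfg$artifact_rate <= 1, "artifact_rate",
      "must be in [0, 1]")
  chk(cfg$behavioral_error_rate >= 0 && cfg$behavioral_error_rate <= 1,
      "behavioral_error_rate", "must be in [0, 1]")
  for (g in c("CN", "MCI")) {
    chk(!is.null(cfg$components[[g]]), "components", paste("missing group", g))
    chk(!is.null(cfg$trial_jitter[[g]]), "trial_jitter",
        paste("missing group", g))
    chk(cfg$trial_jitter[[g]]$amp_sd >= 0, "trial_jitter",
        paste(g, "amp_sd must be >= 0"))
    chk(cfg$trial_jitter[[g]]$lat_sd >= 0, "trial_jitter",
        paste(g, "lat_sd must be >= 0"))
    s <- cfg$right_channel_jitter_scale[[g]]
    chk(!is.null(s) && s >= 0, "right_channel_jitter_scale",
        paste(g, "must be >= 0"))
    p2 <- cfg$components[[g]]$P2; p3 <- cfg$components[[g]]$P3
    chk(!is.null(p2) && !is.null(p3), "components",
        paste(g, "must define P2 and P3"))
    chk(p2$lat >= 150 && p2$lat <= 300, "components",
        paste(g, "P2 latency must lie in the 150-300 ms window"))
    chk(p3$lat >= 300 && p3$lat <= 600, "components",
        paste(g, "P3 latency must lie in the 300-600 ms window"))
  }
  cfg
}

#' Construct a subject profile
#'
#' @param subject_id Identifier.
#' @param group `"CN"` or `"MCI"`.
#' @param age Years (> 0).
#' @param sex `"F"` or `"M"`.
#' @param education Years of education.
#' @param mmse Mini-Mental State Examination score, 0-30.
#' @param snsb Named numeric vector of the five cognitive-domain scores
#'   (attention, language, visuospatial, memory, frontal).
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group, age, sex, education, mmse, snsb) {
  stopifnot(group %in% c("CN", "MCI"), sex %in% c("F", "M"),
            age > 0, mmse >= 0, mmse <= 30)
  structure(list(subject_id = as.character(subject_id), group = group,
                 age = age, sex = sex, education = education, mmse = mmse,
                 snsb = snsb),
            class = "subject_profile")
}

# Draw one group's demographics for n subjects. Assumes the RNG state is set.
draw_demographics <- function(n, group, dem, id_prefix) {
  rnorm2 <- function(p) rnorm(n, p[1], p[2])
  age <- pmax(55, rnorm2(dem$age))
  sex <- ifelse(runif(n) < dem$female_prop, "F", "M")
  edu <- pmax(0, rnorm2(dem$education))
  mmse <- pmin(30, pmax(0, round(rnorm2(dem$mmse))))
  snsb <- lapply(dem$snsb, rnorm2)
  lapply(seq_len(n), function(i) {
    subject_profile(
      subject_id = sprintf("%s%04d", id_prefix, i), group = group,
      age = age[i], sex = sex[i], education = edu[i], mmse = mmse[i],
      snsb = vapply(snsb, `[`, numeric(1), i)
    )
  })
}

# 1/f ("pink") noise with unit SD, via frequency-domain shaping.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  f <- c(1, seq_len(n - 1))          # avoid dividing by zero at DC
  spec <- stats::fft(white) / sqrt(pmin(f, n - f + 1))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Simulate one subject's oddball epochs
#'
#' Generates the full trial set (targets + standards, in randomized
#' presentation order) for one subject under the generative model described
#' in [generator_config()]. Artifact trials receive one sample set to
#' +-150 uV (guaranteed beyond the 100 uV rejection threshold); behavioral
#' error trials are flagged `correct = FALSE`.
#'
#' @param profile A `subject_profile` (its `group` selects the parameter set).
#' @param config A `generator_config`.
#' @param subject_seed Integer seed for this subject's trial-level randomness.
#' @return An [epoch_set()].
#' @export
simulate_subject_epochs <- function(profile, config, subject_seed) {
  g <- profile$group
  comps <- config$components[[g]]
  jit <- config$trial_jitter[[g]]
  rscale <- config$right_channel_jitter_scale[[g]]
  t_axis <- erp_time_axis(config$sampling_rate, config$epoch_span)
  nT <- length(t_axis)
  n_trials <- config$n_target_trials + config$n_standard_trials

  set.seed(subject_seed)
  labels <- sample(c(rep("target", config$n_target_trials),
                     rep("standard", config$n_standard_trials)))
  is_target <- labels == "target"

  # subject-level draws: mean component amplitude/latency and a lognormal
  # multiplier on the trial-jitter SDs (mean-preserving)
  bs <- config$between_subject
  windows <- component_windows()
  subj <- lapply(names(comps), function(nm) {
    comp <- comps[[nm]]
    w <- windows[[nm]] %||% c(comp$lat - 100, comp$lat + 100)
    amp_s <- max(0.1, comp$amp + rnorm(1, 0, bs$amp_sd))
    lat_s <- min(max(comp$lat + rnorm(1, 0, bs$lat_sd), w[1] + 10),
                 w[2] - 10)
    modifyList(comp, list(amp = amp_s, lat = lat_s))
  })
  names(subj) <- names(comps)
  jfac <- if (bs$jitter_cv > 0)
    exp(rnorm(2, -bs$jitter_cv^2 / 2, bs$jitter_cv)) else c(1, 1)
  amp_sd_s <- jit$amp_sd * jfac[1]
  lat_sd_s <- jit$lat_sd * jfac[2]
  rscale <- max(0, rscale + rnorm(1, 0, bs$rscale_sd))

  amp <- array(0, dim = c(n_trials, 2, nT))
  for (comp in subj) {
    dA <- rnorm(n_trials, 0, amp_sd_s)
    dL <- rnorm(n_trials, 0, lat_sd_s)
    base_amp <- comp$amp * ifelse(is_target, comp$target_gain, 1)
    for (ch in 1:2) {
      s <- if (ch == 2) rscale else 1
      a_i <- base_amp + s * dA
      mu_i <- comp$lat + s * dL
      # trials x samples Gaussian bump, scaled per trial
      bump <- exp(-(outer(mu_i, t_axis, "-"))^2 / (2 * comp$width^2))
      amp[, ch, ] <- amp[, ch, ] + a_i * bump
    }
  }
  if (config$noise_sd > 0) {
    if (config$noise_type == "white") {
      amp <- amp + array(rnorm(length(amp), 0, config$noise_sd), dim = dim(amp))
    } else {
      for (i in seq_len(n_trials)) for (ch in 1:2)
        amp[i, ch, ] <- amp[i, ch, ] + config$noise_sd * pink_noise(nT)
    }
  }

  artifact <- runif(n_trials) < config$artifact_rate
  for (i in which(artifact)) {
    ch <- sample(1:2, 1)
    k <- sample(nT, 1)
    amp[i, ch, k] <- sample(c(-150, 150), 1)
  }
  correct <- runif(n_trials) >= config$behavioral_error_rate

  epoch_set(amp, t_axis, labels, correct,
            subject_id = profile$subject_id)
}

#' Generate a synthetic cohort
#'
#' Draws demographics for `n_cn` + `n_mci` subjects and simulates each
#' subject's epoch set. Fully deterministic given `config$seed`: the master
#' seed drives the demographic draws and one derived sub-seed per subject.
#'
#' @param config A `generator_config`.
#' @return A list of class `erp_cohort`; each element is
#'   `list(profile = subject_profile, epochs = epoch_set)`. The generating
#'   config is attached as attribute `"config"`.
#' @export
#' @examples
#' cfg <- generator_config(n_cn = 2, n_mci = 2, seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort[[1]]$epochs
generate_cohort <- function(config) {
  config <- validate_generator_config(config)
  set.seed(config$seed)
  profiles <- c(
    draw_demographics(config$n_cn, "CN", config$demographics$CN, "CN"),
    draw_demographics(config$n_mci, "MCI", config$demographics$MCI, "MCI")
  )
  n <- length(profiles)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cohort <- lapply(seq_len(n), function(i) {
    list(profile = profiles[[i]],
         epochs = simulate_subject_epochs(profiles[[i]], config,
                                          subject_seeds[i]))
  })
  structure(cohort, class = "erp_cohort", config = config)
}

#' Cohort metadata table
#'
#' Flattens the subject profiles of a cohort into the standard metadata
#' table: subject_id, group, age, sex, education, mmse and the five SNSB
#' domain columns.
#'
#' @param cohort An `erp_cohort` (or plain list of `profile`/`epochs` pairs).
#' @return A `data.frame` with one row per subject.
#' @export
cohort_metadata <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    p <- s$profile
    data.frame(subject_id = p$subject_id, group = p$group, age = p$age,
               sex = p$sex, education = p$education, mmse = p$mmse,
               attention = p$snsb[["attention"]],
               language = p$snsb[["language"]],
               visuospatial = p$snsb[["visuospatial"]],
               memory = p$snsb[["memory"]],
               frontal = p$snsb[["frontal"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
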