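test_that("segmentation slices the continuous recording sample-exactly", {
  rec <- ramp_recording(3000)            # 12 s at 250 Hz
  ev <- data.frame(onset_ms = 2000, label = "target")
  es <- segment(rec, ev)
  # onset index 501; epoch starts 50 samples earlier
  expect_equal(es$amplitudes[1, 1, ], 451:700)
  expect_equal(es$amplitudes[1, 2, ], -(451:700))
  expect_equal(es$time_axis, seq(-200, 796, by = 4))
})

test_that("events without full epoch context are skipped with a warning", {
  rec <- ramp_recording(1000)
  ev <- data.frame(onset_ms = c(100, 2000), label = "standard")
  expect_warning(es <- segment(rec, ev), "skipped")
  expect_equal(n_trials(es), 1)          # only the 2000 ms event fits
})

test_that("an oddball block of 320 events yields 320 trials", {
  rec <- ramp_recording(250 * 400)       # 400 s
  onsets <- 1000 + (0:319) * 1200
  ev <- data.frame(onset_ms = onsets,
                   label = rep(c("target", rep("standard", 4)), 64))
  es <- segment(rec, ev)
  expect_equal(n_trials(es), 320)
  expect_equal(sum(es$stimulus_label == "target"), 64)
})

test_that("baseline correction removes the pre-stimulus mean and is idempotent", {
  t_axis <- erp_time_axis()
  # constant trial at 7 uV -> all zeros
  const <- matrix_epochs(matrix(7, 1, 250), t_axis)
  expect_equal(max(abs(baseline_correct(const)$amplitudes)), 0)
  # ramp trial t/100: subtracts the mean of the pre-stimulus samples
  ramp <- matrix_epochs(matrix(t_axis / 100, 1, 250), t_axis)
  pre_mean <- mean(t_axis[t_axis < 0] / 100)   # -1.02 by hand
  expect_equal(pre_mean, -1.02)
  bc <- baseline_correct(ramp)
  expect_equal(bc$amplitudes[1, 1, ], t_axis / 100 - pre_mean)
  # idempotent, and baseline mean is 0 afterwards (random input)
  set.seed(1)
  rnd <- matrix_epochs(matrix(rnorm(5 * 250, 3), 5, 250), t_axis)
  once <- baseline_correct(rnd)
  sel <- t_axis >= -200 & t_axis < 0
  expect_lt(max(abs(apply(once$amplitudes[, , sel], c(1, 2), mean))), 1e-12)
  expect_equal(baseline_correct(once)$amplitudes, once$amplitudes)
})

test_that("baseline correction errors when the window has no samples", {
  es <- matrix_epochs(matrix(1, 1, 10), seq(0, 36, by = 4))
  expect_error(baseline_correct(es), "baseline")
})

test_that("correct-trial selection keeps the documented counts", {
  t_axis <- erp_time_axis()
  n <- 320
  lab <- c(rep("target", 64), rep("standard", 256))
  corr <- rep(TRUE, n)
  corr[sample(1:64, 4)] <- FALSE          # 4 missed targets
  corr[64 + sample(1:256, 6)] <- FALSE    # 6 false alarms
  es <- matrix_epochs(matrix(0, n, 250), t_axis, label = lab, correct = corr)
  kept <- select_correct_trials(es)
  expect_equal(sum(kept$stimulus_label == "target"), 60)
  expect_equal(sum(kept$stimulus_label == "standard"), 250)
  # all-correct input is the identity
  all_ok <- matrix_epochs(matrix(1, 5, 250), t_axis)
  expect_identical(select_correct_trials(all_ok)$amplitudes, all_ok$amplitudes)
})

test_that("artifact rejection applies the +-100 uV rule per trial", {
  t_axis <- erp_time_axis()
  fp1 <- matrix(0, 4, 250)
  fp2 <- matrix(0, 4, 250)
  fp2[2, 100] <- 101                       # one sample just over, on Fp2
  es <- matrix_epochs(fp1, t_axis, fp2 = fp2)
  rej <- reject_artifact_trials(es, 100)
  expect_equal(rej$keep, c(TRUE, FALSE, TRUE, TRUE))
  expect_false(rej$keep_by_channel[2, "Fp2"])
  expect_true(rej$keep_by_channel[2, "Fp1"])

  # exactly one trial exceeding -100 -> 3 of 4 kept
  fp1b <- matrix(0, 4, 250); fp1b[3, 7] <- -100.5
  rej2 <- reject_artifact_trials(matrix_epochs(fp1b, t_axis), 100)
  expect_equal(sum(rej2$keep), 3)

  # bounded trials all kept; infinite threshold is the identity
  set.seed(2)
  bounded <- matrix_epochs(matrix(runif(4 * 250, -50, 50), 4, 250), t_axis)
  expect_true(all(reject_artifact_trials(bounded, 100)$keep))
  wild <- matrix_epochs(matrix(rnorm(4 * 250, 0, 200), 4, 250), t_axis)
  expect_true(all(reject_artifact_trials(wild, Inf)$keep))
})

test_that("rejection count matches a brute-force oracle on random instances", {
  set.seed(42)
  t_axis <- erp_time_axis()
  for (rep in 1:10) {
    m <- matrix(rnorm(20 * 250, 0, 60), 20, 250)
    es <- matrix_epochs(m, t_axis)
    oracle <- vapply(seq_len(20), function(i) all(abs(m[i, ]) <= 100),
                     logical(1))
    expect_identical(reject_artifact_trials(es, 100)$keep, oracle)
  }
})

test_that("moving-average smoothing matches hand-computed cases", {
  t_axis <- erp_time_axis()
  # constant signal unchanged (including edges)
  const <- matrix_epochs(matrix(3, 2, 250), t_axis)
  expect_equal(smooth_trials(const, 9)$amplitudes, const$amplitudes)
  # interior impulse of 9 uV spreads to nine samples of 1 uV
  imp <- matrix(0, 1, 250); imp[1, 100] <- 9
  sm <- smooth_trials(matrix_epochs(imp, t_axis), 9)$amplitudes[1, 1, ]
  expect_equal(sm[96:104], rep(1, 9))
  expect_equal(sum(sm != 0), 9)
  # edge shrinkage: impulse at the first sample
  imp2 <- matrix(0, 1, 250); imp2[1, 1] <- 10
  sm2 <- smooth_trials(matrix_epochs(imp2, t_axis), 9)$amplitudes[1, 1, ]
  expect_equal(sm2[1], 10 / 5)            # window [1, 5]
  expect_equal(sm2[5], 10 / 9)            # full window [1, 9]
  # even order rejected
  expect_error(smooth_trials(const, 8), "odd")
})

test_that("smoothing reduces white-noise variance across seeds", {
  t_axis <- erp_time_axis()
  for (seed in 1:5) {
    set.seed(seed)
    es <- matrix_epochs(matrix(rnorm(10 * 250), 10, 250), t_axis)
    sm <- smooth_trials(es, 9)
    expect_lt(var(as.vector(sm$amplitudes)), var(as.vector(es$amplitudes)))
  }
})

test_that("inclusion decision follows the clean-trial rules at the boundary", {
  base <- expand.grid(condition = c("target", "standard"),
                      channel = c("Fp1", "Fp2"), stringsAsFactors = FALSE)
  base$n_total <- 100; base$n_correct <- 100; base$n_clean <- 100
  expect_true(assess_inclusion(base)$included)

  zero <- base; zero$n_clean[zero$condition == "standard" &
                               zero$channel == "Fp1"] <- 0
  r <- assess_inclusion(zero)
  expect_false(r$included)
  expect_equal(r$exclusion_reason, "no_clean_trials")

  low <- base; low$n_clean[low$condition == "target" &
                             low$channel == "Fp2"] <- 49
  r2 <- assess_inclusion(low)
  expect_false(r2$included)
  expect_equal(r2$exclusion_reason, "below_half_clean")

  half <- base; half$n_clean[1] <- 50     # exactly 50% stays included
  expect_true(assess_inclusion(half)$included)

  bad <- base; bad$n_clean[1] <- 101
  expect_error(assess_inclusion(bad), "inconsistent")
})

test_that("preprocess_epochs runs the chain in order and reports counts", {
  cfg <- tiny_config(n_target_trials = 16, n_standard_trials = 32,
                     artifact_rate = 0.2, behavioral_error_rate = 0.1)
  es <- generate_cohort(cfg)[[1]]$epochs
  pp <- preprocess_epochs(es)
  expect_s3_class(pp$report, "preprocess_report")
  cnt <- pp$report$counts
  expect_equal(nrow(cnt), 4)
  expect_true(all(cnt$n_clean <= cnt$n_correct))
  expect_true(all(cnt$n_correct <= cnt$n_total))
  expect_equal(unique(cnt$n_total[cnt$condition == "target"]), 16)
  # surviving epochs are baseline-corrected and bounded
  sel <- pp$epochs$time_axis < 0
  expect_true(all(abs(pp$epochs$amplitudes) <= 100))
})
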