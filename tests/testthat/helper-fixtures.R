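# Shared fixture builders. Everything is generated in code; no stored data.

# Small, fast generator config for structural tests.
tiny_config <- function(n_cn = 2, n_mci = 2, n_target_trials = 8,
                        n_standard_trials = 16, noise_sd = 1,
                        artifact_rate = 0, behavioral_error_rate = 0,
                        seed = 123, ...) {
  generator_config(
    n_cn = n_cn, n_mci = n_mci, n_target_trials = n_target_trials,
    n_standard_trials = n_standard_trials, noise_sd = noise_sd,
    artifact_rate = artifact_rate,
    behavioral_error_rate = behavioral_error_rate, seed = seed, ...
  )
}

# Deterministic (noise- and jitter-free) config: every same-condition trial
# is identical.
degenerate_config <- function(...) {
  generator_config(
    n_cn = 1, n_mci = 1, n_target_trials = 4, n_standard_trials = 6,
    trial_jitter = list(CN = list(amp_sd = 0, lat_sd = 0),
                        MCI = list(amp_sd = 0, lat_sd = 0)),
    between_subject = list(amp_sd = 0, lat_sd = 0, jitter_cv = 0,
                           rscale_sd = 0),
    noise_sd = 0, artifact_rate = 0, behavioral_error_rate = 0,
    seed = 5, ...
  )
}

# Epoch set built from an explicit trials x samples matrix, duplicated on
# both channels unless fp2 is given.
matrix_epochs <- function(fp1, time_axis, label = "target", correct = TRUE,
                          fp2 = fp1, subject_id = "S1") {
  n <- nrow(fp1)
  amp <- array(0, dim = c(n, 2, ncol(fp1)))
  amp[, 1, ] <- fp1
  amp[, 2, ] <- fp2
  epoch_set(amp, time_axis, rep_len(label, n), rep_len(correct, n),
            subject_id = subject_id)
}

# Continuous two-channel ramp recording: Fp1 holds the sample index (1-based)
# and Fp2 its negative, so segmented values encode positions exactly.
ramp_recording <- function(n_samples) {
  rec <- rbind(Fp1 = seq_len(n_samples), Fp2 = -seq_len(n_samples))
  rec
}
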