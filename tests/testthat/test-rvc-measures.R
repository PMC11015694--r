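test_that("the RVC is the unbiased pointwise across-trial variance", {
  t_axis <- seq(0, 36, by = 4)
  m <- matrix(0, 3, length(t_axis))
  m[, 5] <- c(1, 2, 3)
  es <- matrix_epochs(m, t_axis)
  rvc <- compute_rvc(es, "target", "Fp1")
  expect_equal(rvc$variance[5], 1.0)       # var({1,2,3}) with n-1
  expect_equal(rvc$variance[-5], rep(0, length(t_axis) - 1))
  expect_equal(rvc$n_trials, 3)

  # identical trials -> zero curve
  same <- matrix_epochs(matrix(rep(sin(t_axis), 4), 4, byrow = TRUE), t_axis)
  expect_equal(max(compute_rvc(same, "target", "Fp1")$variance), 0)
})

test_that("fewer than two clean trials raises the insufficient-data error", {
  es <- matrix_epochs(matrix(0, 2, 10), seq(0, 36, 4),
                      label = c("target", "standard"))
  expect_error(compute_rvc(es, "target", "Fp1"),
               class = "rvcerp_insufficient_data")
})

test_that("RVC matches a brute-force per-timepoint oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:12, 1); ns <- sample(5:30, 1)
    m <- matrix(rnorm(n * ns, sd = 10), n, ns)
    es <- matrix_epochs(m, seq(0, by = 4, length.out = ns))
    expect_equal(compute_rvc(es, "target", "Fp1")$variance,
                 apply(m, 2, var), tolerance = 1e-12)
  }
})

test_that("triangular and constant curves give closed-form measures", {
  # symmetric triangle on [150, 300] peaking at 4 uV^2 at 225 ms
  t <- seq(150, 300, by = 5)
  tri <- rvc_curve(t, 4 * pmax(0, 1 - abs(t - 225) / 75))
  m <- extract_window_measures(tri, c(150, 300))
  expect_equal(m$AMPV, 4)
  expect_equal(m$LATV, 225)
  expect_equal(m$AUCV, 0.5 * 150 * 4)      # triangle area = 300
  expect_equal(m$FALV, 225)                # symmetric mass

  # constant curve c over a window of length L
  const <- rvc_curve(t, rep(2, length(t)))
  mc <- extract_window_measures(const, c(150, 300))
  expect_equal(mc$AMPV, 2)
  expect_equal(mc$LATV, 150)               # earliest-time tie rule
  expect_equal(mc$FALV, 225)               # window midpoint
  expect_equal(mc$AUCV, 2 * 150)
})

test_that("FALV is reported missing when the window area is zero", {
  t <- seq(150, 300, by = 5)
  z <- rvc_curve(t, rep(0, length(t)))
  m <- extract_window_measures(z, c(150, 300))
  expect_true(is.na(m$FALV))
  expect_equal(m$AUCV, 0)
})

test_that("window membership is inclusive and needs >= 2 samples", {
  t <- seq(0, 796, by = 4)
  v <- seq_along(t)
  cv <- rvc_curve(t, v)
  m <- extract_window_measures(cv, c(300, 600))
  expect_equal(m$LATV, 600)                # inclusive right endpoint
  expect_error(extract_window_measures(cv, c(300, 301)), "fewer than 2")
})

test_that("peak discernibility requires a strict interior maximum", {
  t <- seq(150, 300, by = 5)
  expect_false(check_discernible_peak(rvc_curve(t, seq_along(t)),
                                      c(150, 300)))  # monotone -> edge max
  bump <- exp(-(t - 220)^2 / 500)
  expect_true(check_discernible_peak(rvc_curve(t, bump), c(150, 300)))
  expect_false(check_discernible_peak(rvc_curve(t, rep(1, length(t))),
                                      c(150, 300)))  # plateau
})

test_that("channel averaging is the arithmetic mean with NA propagation", {
  expect_equal(average_channel_measures(2, 4), 3)
  expect_equal(average_channel_measures(5, 5), 5)
  expect_true(is.na(average_channel_measures(NA_real_, 4)))
  expect_equal(average_channel_measures(c(1, NA), c(3, 3)), c(2, NA))
})

test_that("extreme-value fences flag exactly the planted outlier", {
  set.seed(10)
  x <- rnorm(50, 10, 1)
  expect_false(any(flag_extreme_values(x)))     # tight unimodal sample
  x[17] <- 100 * median(x)
  flags <- flag_extreme_values(x)
  expect_identical(which(flags), 17L)
  expect_warning(f0 <- flag_extreme_values(rep(1, 10)), "IQR")
  expect_false(any(f0))
  expect_error(flag_extreme_values(c(1, 2, 3)), "4 finite")
})

test_that("RVC is invariant to common waveforms and scales quadratically", {
  set.seed(11)
  t_axis <- erp_time_axis()
  m <- matrix(rnorm(8 * 250, sd = 3), 8, 250)
  es <- matrix_epochs(m, t_axis)
  base <- compute_rvc(es, "target", "Fp1")

  # shift invariance: add one fixed waveform to every trial
  wave <- 10 * sin(t_axis / 50)
  shifted <- matrix_epochs(sweep(m, 2, wave, `+`), t_axis)
  expect_equal(compute_rvc(shifted, "target", "Fp1")$variance, base$variance)

  # scaling: trials x c -> RVC x c^2, AMPV/AUCV x c^2, latencies unchanged
  c2 <- 2.5
  scaled <- matrix_epochs(c2 * m, t_axis)
  sc <- compute_rvc(scaled, "target", "Fp1")
  expect_equal(sc$variance, c2^2 * base$variance)
  w <- c(150, 300)
  m0 <- extract_window_measures(base, w)
  m1 <- extract_window_measures(sc, w)
  expect_equal(m1$AMPV, c2^2 * m0$AMPV)
  expect_equal(m1$AUCV, c2^2 * m0$AUCV)
  expect_equal(m1$LATV, m0$LATV)
  expect_equal(m1$FALV, m0$FALV)
})

test_that("window measures agree with a 10x oversampled numerical oracle", {
  set.seed(12)
  t <- seq(150, 300, by = 4)
  for (i in 1:10) {
    # random smooth positive curve from a few Gaussian bumps
    v <- rep(0.5, length(t))
    for (b in 1:3)
      v <- v + runif(1, 0.5, 3) *
        exp(-(t - runif(1, 170, 280))^2 / (2 * runif(1, 15, 40)^2))
    cv <- rvc_curve(t, v)
    m <- extract_window_measures(cv, c(150, 300))

    # dense linear-interpolation oracle over the in-window sample range
    td <- seq(min(t), max(t), length.out = 10 * length(t))
    vd <- approx(t, v, td)$y
    auc_d <- sum(diff(td) * (vd[-1] + vd[-length(vd)]) / 2)
    cum <- c(0, cumsum(diff(td) * (vd[-1] + vd[-length(vd)]) / 2))
    falv_d <- td[which(cum >= auc_d / 2)[1]]
    expect_equal(m$AUCV, auc_d, tolerance = 0.01)
    expect_lt(abs(m$FALV - falv_d), 4)      # within one grid step
  }
})

test_that("subject_measures builds the tidy table with averaged rows", {
  cohort <- generate_cohort(tiny_config(n_target_trials = 16,
                                        n_standard_trials = 32))
  pp <- preprocess_epochs(cohort[[1]]$epochs)
  tab <- subject_measures(pp$epochs)
  expect_equal(nrow(tab), 2 * 2 * 3)        # window x condition x channel+avg
  expect_setequal(unique(tab$channel), c("Fp1", "Fp2", "avg"))
  avg <- tab[tab$channel == "avg" & tab$window == "P2" &
               tab$condition == "target", ]
  f1 <- tab[tab$channel == "Fp1" & tab$window == "P2" &
              tab$condition == "target", ]
  f2 <- tab[tab$channel == "Fp2" & tab$window == "P2" &
              tab$condition == "target", ]
  expect_equal(avg$AMPV, (f1$AMPV + f2$AMPV) / 2)
  expect_true(all(tab$AMPV >= 0))
  expect_true(all(tab$LATV >= 150 & tab$LATV <= 600))
  expect_true(all(tab$AUCV <= tab$AMPV * ifelse(tab$window == "P2", 150, 300)
                  + 1e-9))
})
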