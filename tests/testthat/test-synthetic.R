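noiseless_cfg <- function(seed = 7, ...)
  synthetic_config(nominal_speed = 1.25, seed = seed,
                   noise = list(marker = 0, angle = 0, grf = 0,
                                torque_frac = 0), ...)

noiseless_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_trial(noiseless_cfg())
    cache
  }
})

test_that("the same seed reproduces a trial exactly", {
  cfg <- synthetic_config(nominal_speed = 1.0, n_strides = 32, seed = 99)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(t1$kin, t2$kin)
  expect_identical(t1$grf, t2$grf)
  expect_identical(t1$truth$steps, t2$truth$steps)
  cfg2 <- synthetic_config(nominal_speed = 1.0, n_strides = 32, seed = 100)
  t3 <- generate_trial(cfg2)
  expect_false(identical(t1$kin$com_x, t3$kin$com_x))
  expect_equal(t1$truth$k_true, t3$truth$k_true)
})

test_that("the configured stride count appears in the force channels", {
  tr <- noiseless_trial()
  gr <- tr$meta$grf_rate
  ev_L <- detect_gait_events(zero_lag_lowpass(tr$grf$grf_y_L, gr, 18), gr)
  ev_R <- detect_gait_events(zero_lag_lowpass(tr$grf$grf_y_R, gr, 18), gr)
  expect_length(ev_L$heel_strikes, 35)
  expect_length(ev_R$heel_strikes, 35)
  rec <- analyze_trial(tr)
  expect_equal(nrow(rec), 30)
})

test_that("the pipeline recovers the generator's ground truth on noiseless data", {
  tr <- noiseless_trial()
  rec <- analyze_trial(tr)
  truth <- tr$truth$steps
  j <- vapply(rec$t_hs, function(t) which.min(abs(truth$t_hs - t)), integer(1))
  expect_lt(max(abs(rec$s_expt / truth$s[j] - 1)), 0.02)
  expect_lt(max(abs(rec$v_expt / truth$v[j] - 1)), 0.02)
  expect_lt(max(abs(rec$b_expt - truth$b[j])), 0.01)
  expect_lt(max(abs(rec$tau_expt / truth$tau[j - 1] - 1)), 0.02)
  expect_lt(max(abs(rec$k_expt / tr$truth$k_true - 1)), 0.02)
  expect_lt(max(abs(rec$T_expt / truth$T[j] - 1)), 0.02)
  expect_lt(max(abs(rec$F_expt / truth$F[j] - 1)), 0.03)
  expect_gt(min(rec$r2_k), 0.999)
  ## leg length reconstructed by Pythagoras matches the generator's
  expect_lt(max(abs(rec$l_expt / tr$truth$leg_length - 1)), 0.005)
})

test_that("estimator dispersion grows with the torque noise level", {
  sds <- vapply(c(0.45, 0.9), function(frac) {
    cfg <- synthetic_config(nominal_speed = 1.25, seed = 17, n_strides = 32,
                            noise = list(torque_frac = frac))
    sd(analyze_trial(generate_trial(cfg))$k_expt)
  }, numeric(1))
  expect_gt(sds[2], sds[1])
})

test_that("nondimensional step metrics are invariant to unit rescaling", {
  tr <- noiseless_trial()
  rec <- analyze_trial(tr)
  dimless <- c("s_expt", "v_expt", "b_expt", "theta_dot_minus_expt",
               "dt_ds_expt", "tau_expt", "k_expt", "T_expt", "F_expt")

  ## mass rescaling: masses, torques and forces scale together
  f <- 1.7
  tr_m <- tr
  tr_m$meta$subject_mass <- tr$meta$subject_mass * f
  for (ch in c("hip_torque_L", "hip_torque_R"))
    tr_m$kin[[ch]] <- tr$kin[[ch]] * f
  for (ch in c("grf_x_L", "grf_y_L", "grf_x_R", "grf_y_R"))
    tr_m$grf[[ch]] <- tr$grf[[ch]] * f
  rec_m <- analyze_trial(tr_m)
  for (v in dimless)
    expect_equal(rec_m[[v]], rec[[v]], tolerance = 1e-6)

  ## length rescaling: lengths x kappa^2, times x kappa, rates and filter
  ## cut-offs follow the time unit
  kap <- 1.1
  tr_l <- tr
  tr_l$kin$time <- tr$kin$time * kap
  tr_l$grf$time <- tr$grf$time * kap
  tr_l$meta$kinematic_rate <- tr$meta$kinematic_rate / kap
  tr_l$meta$grf_rate <- tr$meta$grf_rate / kap
  for (ch in c("heel_x_L", "heel_x_R", "toe_x_L", "toe_x_R", "com_x", "com_y"))
    tr_l$kin[[ch]] <- tr$kin[[ch]] * kap^2
  for (ch in c("hip_torque_L", "hip_torque_R"))
    tr_l$kin[[ch]] <- tr$kin[[ch]] * kap^2
  rec_l <- analyze_trial(tr_l, kin_cutoff = 6 / kap, grf_cutoff = 18 / kap)
  for (v in dimless)
    expect_equal(rec_l[[v]], rec[[v]], tolerance = 1e-6)
})

test_that("trials round-trip through the directory format", {
  tr <- noiseless_trial()
  dir <- file.path(tempdir(), "cw-trial")
  write_trial(tr, dir)
  tr2 <- read_trial(dir)
  expect_equal(tr2$kin$com_x, tr$kin$com_x, tolerance = 1e-10)
  expect_equal(tr2$grf$grf_y_L, tr$grf$grf_y_L, tolerance = 1e-10)
  expect_equal(tr2$meta$subject_mass, tr$meta$subject_mass)
  expect_equal(tr2$truth$k_true, tr$truth$k_true)
  expect_equal(tr2$truth$steps$s, tr$truth$steps$s, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
  expect_error(read_trial(file.path(tempdir(), "no-such-dir")),
               "meta.yaml")
})
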