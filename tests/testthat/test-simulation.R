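test_that("integration is deterministic and respects the decay contract", {
  p0 <- mepd_params(Kp = 0)
  tr <- integrate_model("mepd", mepd = p0, init = c(0.4, 0.4, 0.4),
                        t_span = c(0, 10))
  # all populations decay toward the silent state
  expect_lt(sqrt(sum(tr$states[nrow(tr$states), ]^2)), 1e-4)
  # bit-identical reproduction
  tr2 <- integrate_model("mepd", mepd = p0, init = c(0.4, 0.4, 0.4),
                         t_span = c(0, 10))
  expect_identical(tr$states, tr2$states)
  expect_identical(tr$times, tr2$times)
})

test_that("integrator agrees with an independent RK4 on a short window", {
  p <- mepd_params(Kp = 2.3)
  tr <- integrate_model("mepd", mepd = p, init = c(0.3, 0.3, 0.3),
                        t_span = c(0, 5))
  ref <- rk4_ref(function(x) mepd_rhs_ref(x, p), c(0.3, 0.3, 0.3), 5, 5e-5)
  expect_equal(unname(tr$states[nrow(tr$states), ]), ref, tolerance = 1e-6)
  q <- kndy_params()
  trk <- integrate_model("kndy", kndy = q, init = c(0.1, 0.1, 1),
                         t_span = c(0, 2))
  refk <- rk4_ref(function(x) kndy_rhs_ref(x, q), c(0.1, 0.1, 1), 2, 2e-5)
  expect_equal(unname(trk$states[nrow(trk$states), ]), refk,
               tolerance = 1e-6)
})

test_that("state-space invariants hold along trajectories", {
  # MePD activities never exceed 1 when started inside (-Inf, 1]^3
  set.seed(11)
  for (i in 1:5) {
    init <- runif(3, -0.5, 1)
    tr <- integrate_model("mepd", mepd = mepd_params(Kp = runif(1, 0, 14)),
                          init = init, t_span = c(0, 20))
    expect_lt(max(tr$states), 1 + 1e-9)
  }
  # KNDy concentrations and firing rate stay non-negative
  trk <- integrate_model("kndy", t_span = c(0, 300))
  expect_gt(min(trk$states), -1e-9)
  trc <- integrate_model("coupled", mepd = mepd_params(Kp = 2.3),
                         t_span = c(0, 300))
  expect_gt(min(trc$states[, c("D", "N", "v")]), -1e-9)
})

test_that("Kp = 2.3 sustains an oscillation past the transient", {
  tr <- integrate_model("mepd", mepd = mepd_params(Kp = 2.3),
                        t_span = c(0, 30))
  po <- post_transient(tr)
  expect_gt(diff(range(po$states[, "Gl"])), 0.05)
  expect_gt(diff(range(po$states[, "Ge"])), 0.05)
})

test_that("mean_outputs implements the normalized time averages", {
  # constant synthetic trace: averages are the constants themselves
  tt <- seq(0, 10, by = 0.01)
  traj <- structure(list(
    times = tt,
    states = cbind(Gl = rep(0.7, length(tt)), Gi = rep(0.1, length(tt)),
                   Ge = rep(0.2, length(tt))),
    transient_end = 0, model = "mepd", meta = list()),
    class = "mk_trajectory")
  os <- mean_outputs(traj)
  expect_equal(os$mean_mepd, 0.5, tolerance = 1e-14)
  # linearity: mean_mepd == mean_glut - mean_gaba to 1e-12 on a real run
  tr <- integrate_model("mepd", mepd = mepd_params(Kp = 2.3),
                        t_span = c(0, 30))
  os2 <- mean_outputs(tr)
  expect_equal(os2$mean_mepd, os2$mean_glut - os2$mean_gaba,
               tolerance = 1e-12)
  # window shorter than two samples is an error
  expect_error(mean_outputs(tr, window = c(10, 10.0001)), "2 samples")
  # grid-step convergence: halving dt_out changes the averages below 1e-6
  tr_h <- integrate_model("mepd", mepd = mepd_params(Kp = 2.3),
                          t_span = c(0, 30), dt_out = 0.001)
  os_h <- mean_outputs(tr_h)
  expect_lt(abs(os2$mean_mepd - os_h$mean_mepd), 1e-6)
  expect_lt(abs(os2$mean_glut - os_h$mean_glut), 1e-6)
})

test_that("the isolated KNDy network is a pulsing relaxation oscillator", {
  tr <- integrate_model("kndy", t_span = c(0, 600))
  ps <- detect_pulses(tr)
  expect_identical(ps$classification, "pulsatile")
  expect_gt(ps$n_pulses, 10)
  # IPI in the tens of minutes, the physiological LH pulse scale
  expect_gt(ps$mean_ipi, 5)
  expect_lt(ps$mean_ipi, 60)
  # mean IPI agrees with the period measured by zero crossings
  po <- post_transient(tr)
  per <- period_by_zero_crossings(po$times, po$states[, "v"])
  expect_lt(abs(ps$mean_ipi - per), tr$meta$dt_out + 1e-6)
})

test_that("trajectory CSV export round-trips through the trace reader", {
  tr <- integrate_model("kndy", t_span = c(0, 50), dt_out = 0.05)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tf)
  df <- utils::read.csv(tf)
  expect_identical(names(df), c("time", "D", "N", "v"))
  expect_equal(df$v, unname(signif(tr$states[, "v"], 12)))
})
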