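test_that("phi matches its closed form, is zero at rest and saturates", {
  # zero at F = 0, exactly, over a grid of slopes and thresholds
  for (a in c(0.5, 1.3, 2, 5))
    for (th in c(0.5, 3.7, 4, 8))
      expect_identical(phi(a, 0, th), 0)
  # half-maximum point
  expect_equal(phi(2, 3.7, 3.7), 0.5 - 1 / (1 + exp(7.4)), tolerance = 1e-15)
  # saturation limit
  expect_equal(phi(1.3, 700, 4), 1 - 1 / (1 + exp(1.3 * 4)), tolerance = 1e-12)
  # strictly increasing in F
  for (a in c(0.7, 2)) for (th in c(1, 3.7)) {
    v <- phi(a, seq(-10, 10, by = 0.25), th)
    expect_true(all(diff(v) > 0))
    expect_true(all(v < 1 - 1 / (1 + exp(a * th)) + 1e-12))
  }
  # derivative helper agrees with finite differences
  expect_equal(phi_slope(2, 1.3, 3.7),
               (phi(2, 1.3 + 1e-6, 3.7) - phi(2, 1.3 - 1e-6, 3.7)) / 2e-6,
               tolerance = 1e-8)
  expect_error(phi(2, NaN, 3.7), "non-finite")
  expect_error(phi(-1, 0, 3.7), "positive")
})

test_that("mepd_inputs implements the linear input sums", {
  p <- mepd_params(Kp = 2.3)
  # zero activity leaves only the kisspeptin drive
  expect_equal(unname(mepd_inputs(c(0, 0, 0), p)),
               c(0.9 * 2.3, 0.1 * 2.3, 0), tolerance = 1e-15)
  # full suppression removes all state dependence
  ps <- mepd_params(Kp = 2.3, beta1 = 1, beta2 = 1)
  expect_equal(unname(mepd_inputs(c(0.8, 0.3, 0.6), ps)),
               c(0.9 * 2.3, 0.1 * 2.3, 0), tolerance = 1e-15)
  # hand-evaluated fixture at Table defaults
  expect_equal(unname(mepd_inputs(c(0.5, 0.2, 0.1), p)),
               c(4.07, 8.23, 15), tolerance = 1e-12)
  expect_equal(unname(mepd_inputs(c(0.5, 0.2, 0.1), p)),
               mepd_inputs_ref(c(0.5, 0.2, 0.1), p), tolerance = 1e-14)
})

test_that("mepd_rhs agrees with the independent scalar implementation", {
  p <- mepd_params(Kp = 2.3)
  # origin is an equilibrium without input
  expect_equal(mepd_rhs(c(0, 0, 0), mepd_params(Kp = 0)), rep(0, 3))
  # refractory factor forces dGl/dT = -delta at Gl = 1
  expect_equal(mepd_rhs(c(1, 0.4, 0.2), p)[1], -p$delta, tolerance = 1e-14)
  # duplicate-implementation oracle on random states and parameters
  set.seed(42)
  for (i in 1:25) {
    x <- runif(3)
    pp <- mepd_params(Kp = runif(1, 0, 14), alpha = runif(1),
                      beta1 = runif(1), beta2 = runif(1))
    expect_equal(mepd_rhs(x, pp), mepd_rhs_ref(x, pp), tolerance = 1e-13)
  }
  # arbitrary-time form is the minutes form divided by delta
  expect_equal(mepd_rhs(c(0.3, 0.3, 0.3), p, time_scaled = FALSE) * p$delta,
               mepd_rhs(c(0.3, 0.3, 0.3), p), tolerance = 1e-14)
})

test_that("analytic Jacobian matches finite differences", {
  set.seed(7)
  for (i in 1:100) {
    x <- runif(3)
    p <- mepd_params(Kp = runif(1, 0, 10), alpha = runif(1),
                     beta1 = runif(1, 0, 0.9), beta2 = runif(1, 0, 0.9))
    J <- mepd_jacobian(x, p)
    Jn <- num_jac(function(z) mepd_rhs(z, p), x)
    expect_equal(J, Jn, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # full suppression decouples the populations
  p1 <- mepd_params(Kp = 3, beta1 = 1, beta2 = 1)
  J <- mepd_jacobian(c(0.2, 0.3, 0.1), p1)
  expect_equal(J[upper.tri(J) | lower.tri(J)], rep(0, 6))
  # the origin is locally stable without kisspeptin drive
  ev <- eigen(mepd_jacobian(c(0, 0, 0), mepd_params(Kp = 0)),
              only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))
})

test_that("kndy_rhs honours the half-saturation landmarks", {
  q <- kndy_params()
  # dynorphin production at v = K_v1 is half-maximal: k_D / 2 = 2
  d <- kndy_rhs(c(0, 0, q$K_v1), q)
  expect_equal(d[1], q$k_D / 2 - q$d_D * 0, tolerance = 1e-12)
  expect_equal(q$k_D / 2, 2)
  # NKB production with v = K_v2, D = K_D: k_N / 4 = 10
  d <- kndy_rhs(c(q$K_D, 0, q$K_v2), q)
  expect_equal(d[2], q$k_N / 4, tolerance = 1e-12)
  # at the origin the synaptic input reduces to the basal level
  d0 <- kndy_rhs(c(0, 0, 0), q)
  expect_equal(d0[3], q$v0 / (1 + exp(q$k * (-q$I0 + q$m))), tolerance = 1e-12)
  # oracle agreement with external drive
  set.seed(3)
  for (i in 1:20) {
    x <- c(runif(1, 0, 2), runif(1, 0, 10), runif(1, 0, 2500))
    ext <- runif(2)
    expect_equal(kndy_rhs(x, q, ext, coupling_params("glut_stim")),
                 kndy_rhs_ref(x, q, ext, 1.5, 0.5), tolerance = 1e-12)
  }
})

test_that("coupled_rhs is one-way MePD -> KNDy", {
  pm <- mepd_params(Kp = 2.3)
  pk <- kndy_params()
  x <- c(0.4, 0.2, 0.3, 0.5, 2, 800)
  d <- coupled_rhs(x, pm, pk)
  # MePD block ignores the KNDy state entirely
  expect_equal(d[1:3], mepd_rhs(x[1:3], pm))
  d2 <- coupled_rhs(c(x[1:3], 9, 9, 9), pm, pk)
  expect_equal(d2[1:3], d[1:3])
  # KNDy block sees the instantaneous (Gl, Ge)
  expect_equal(d[4:6], kndy_rhs(x[4:6], pk, ext = c(x[1], x[3])))
  # zero weights reduce to the isolated KNDy system
  d0 <- coupled_rhs(x, pm, pk, coupling_params(j_l = 0, j_e = 0))
  expect_equal(d0[4:6], kndy_rhs(x[4:6], pk, ext = c(0, 0),
                                 coupling_params(j_l = 0, j_e = 0)))
})

test_that("parameter objects validate, serialize and modify", {
  expect_error(mepd_params(alpha = 1.2), "alpha")
  expect_error(mepd_params(Kp = -1), "Kp")
  expect_error(mepd_params(delta = 0), "delta")
  expect_error(kndy_params(v0 = -5), "v0")
  expect_error(coupling_params(j_l = -1), "non-negative")
  expect_error(set_params(mepd_params(), nonsense = 1), "unknown")
  expect_equal(coupling_params("glut_stim")$j_l, 1.5)
  expect_equal(coupling_params("gaba_stim")$j_e, 1.5)
  p <- set_params(mepd_params(), Kp = 2.3, beta1 = 0.25)
  expect_equal(p$Kp, 2.3)
  expect_equal(p$beta1, 0.25)
  # JSON round trips preserve every field exactly
  tf <- withr::local_tempfile(fileext = ".json")
  write_params(p, tf)
  expect_equal(read_params(tf), p)
  qf <- withr::local_tempfile(fileext = ".json")
  write_params(kndy_params(), qf)
  expect_equal(read_params(qf), kndy_params())
})

test_that("coupled dynamics at an MePD equilibrium equal an I0-shifted KNDy", {
  # with the MePD at a stable fixed point, one-way coupling is equivalent
  # to the isolated KNDy system with basal input I0 + j_l*Gl - j_e*Ge
  pm <- mepd_params(Kp = 0.8)  # below the Hopf point: stable equilibrium
  pk <- kndy_params()
  eq <- find_equilibrium(pm, c(0.01, 0.01, 0.01))
  shift <- 1 * eq[["Gl"]] - 1 * eq[["Ge"]]
  tr1 <- integrate_model("coupled", mepd = pm, kndy = pk,
                         init = c(eq, 0.2, 0.5, 10), t_span = c(0, 80))
  tr2 <- integrate_model("kndy", kndy = set_params(pk, I0 = pk$I0 + shift),
                         init = c(0.2, 0.5, 10), t_span = c(0, 80))
  expect_equal(tr1$states[, c("D", "N", "v")], tr2$states,
               tolerance = 1e-6)
})
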