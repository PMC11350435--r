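test_that("find_equilibrium honours the Newton contract", {
  p0 <- mepd_params(Kp = 0)
  eq <- find_equilibrium(p0, c(0, 0, 0))
  expect_equal(as.numeric(eq), c(0, 0, 0))
  expect_lt(attr(eq, "residual"), 1e-12)
  # the focus inside the Kp = 2.3 limit cycle is unstable
  p <- mepd_params(Kp = 2.3)
  eq2 <- find_equilibrium(p, c(0.12, 0.05, 0.35))
  expect_lt(max(abs(mepd_rhs(eq2, p))), 1e-12)
  ev <- eigen(mepd_jacobian(eq2, p), only.values = TRUE)$values
  expect_true(any(Im(ev) != 0 & Re(ev) > 0))
})

test_that("equilibrium branches satisfy their residual and fold contracts", {
  br <- continue_equilibria(mepd_params(), "Kp", c(0, 20),
                            guess = c(0, 0, 0))
  pts <- br$points
  # every accepted point is an equilibrium to 1e-10
  res <- apply(pts, 1, function(r) {
    max(abs(mepd_rhs(unname(r[c("Gl", "Gi", "Ge")]),
                     set_params(mepd_params(), Kp = max(r[["param"]], 0)))))
  })
  expect_lt(max(res), 1e-10)
  # fold count equals the number of det(J) sign changes along the branch
  det_sign_changes <- sum(diff(sign(pts$det_test)) != 0)
  folds <- sum(diff(sign(diff(pts$param))) != 0)
  expect_identical(folds, det_sign_changes)
  # branch reaches both a low-activity and a high-activity segment
  expect_lt(pts$Gl[1], 0.01)
  expect_gt(max(pts$Gl), 0.45)
})

test_that("branch continuation is robust to halving the initial step", {
  b1 <- continue_equilibria(mepd_params(), "Kp", c(0, 3), guess = c(0, 0, 0))
  b2 <- continue_equilibria(mepd_params(), "Kp", c(0, 3), guess = c(0, 0, 0),
                            h0 = 0.005)
  hb1 <- detect_codim1(b1)
  hb2 <- detect_codim1(b2)
  expect_identical(length(hb1), length(hb2))
  expect_lt(abs(hb1[[1]]$value - hb2[[1]]$value), 1e-6)
})

test_that("codimension-one detection finds the HB and the SN pair", {
  br <- continue_equilibria(mepd_params(), "Kp", c(0, 20),
                            guess = c(0, 0, 0))
  bps <- detect_codim1(br)
  kinds <- vapply(bps, `[[`, character(1), "kind")
  vals <- vapply(bps, `[[`, numeric(1), "value")
  # one Hopf bifurcation near Kp = 1.4
  expect_identical(sum(kinds == "HB"), 1L)
  expect_lt(abs(vals[kinds == "HB"] - 1.4), 0.05)
  # the Hopf point satisfies its eigenvalue contract
  hb <- bps[[which(kinds == "HB")]]
  ip <- which(Im(hb$eigenvalues) != 0)
  expect_lt(max(abs(Re(hb$eigenvalues[ip]))), 1e-8)
  expect_gt(min(abs(Im(hb$eigenvalues[ip]))), 1e-6)
  # extending past the Table range: two saddle-nodes bound a bistable window
  expect_identical(sum(kinds == "SN"), 2L)
  sn <- sort(vals[kinds == "SN"])
  expect_true(all(sn > 14) && all(sn < 20) && diff(sn) > 0.5)
  # complete GABA-interaction suppression removes the Hopf bifurcation
  br1 <- continue_equilibria(mepd_params(beta1 = 1), "Kp", c(0, 14),
                             guess = c(0, 0, 0))
  k1 <- vapply(detect_codim1(br1), `[[`, character(1), "kind")
  expect_false(any(k1 == "HB"))
})

test_that("limit-cycle branch: onset frequency, stability, monotone period", {
  br <- continue_equilibria(mepd_params(), "Kp", c(0, 3), guess = c(0, 0, 0))
  hb <- detect_codim1(br)[[1]]
  lc <- continue_limit_cycle(hb, mepd_params(), range = c(1.42, 2.6))
  pts <- lc$points
  # the period at the Hopf end approaches the normal-form value 2*pi/omega
  expect_lt(abs(min(pts$period[which.min(pts$param)]) -
                2 * pi / hb$omega) / (2 * pi / hb$omega), 0.02)
  # period decreases monotonically across Kp in [1.5, 2.5]
  mid <- pts[pts$param >= 1.5 & pts$param <= 2.5, ]
  expect_true(all(diff(mid$period) < 0))
  # the cycle is orbitally stable there (non-trivial multiplier inside the
  # unit circle) and its amplitude is positive
  expect_true(all(mid$floquet < 1))
  expect_true(all(mid$Gl_max > mid$Gl_min))
  # supercritical onset: amplitude shrinks toward the Hopf point
  lo <- pts[order(pts$param)[1:5], ]
  expect_true(all(diff(lo$Gl_max - lo$Gl_min) > 0))
})

test_that("cycle amplitude shrinks continuously above the detected HB", {
  # re-simulated onset: the oscillation just above the Hopf point is small
  # and grows with the distance, consistent with a supercritical branch
  br <- continue_equilibria(mepd_params(), "Kp", c(0, 3), guess = c(0, 0, 0))
  hb <- detect_codim1(br)[[1]]
  amp <- vapply(c(0.02, 0.06, 0.15), function(eps) {
    tr <- integrate_model("mepd",
                          mepd = set_params(mepd_params(), Kp = hb$value + eps),
                          t_span = c(0, 400), dt_out = 0.01)
    po <- post_transient(tr)
    diff(range(po$states[, "Gl"]))
  }, numeric(1))
  expect_true(all(diff(amp) > 0))
  expect_gt(amp[1], 1e-4)   # a genuine oscillation, not noise
  expect_lt(amp[1], amp[3] / 2)
})

test_that("the cycle branch terminates on the homoclinic tail", {
  br <- continue_equilibria(mepd_params(), "Kp", c(0, 3), guess = c(0, 0, 0))
  hb <- detect_codim1(br)[[1]]
  lc <- continue_limit_cycle(hb, mepd_params(), range = c(1.42, 20))
  expect_true(lc$status %in% c("hc_proxy", "period_blowup"))
  pts <- lc$points
  iend <- which.max(pts$param)
  # the destruction point sits between the Table-1 range end and the folds
  expect_gt(pts$param[iend], 14)
  expect_lt(pts$param[iend], 18.5)
  # period rises steeply toward the end of the branch
  tail_pts <- pts[pts$param > pts$param[iend] - 0.5, ]
  expect_gt(max(tail_pts$period), 2 * min(tail_pts$period))
})

test_that("two-parameter HB locus and Bogdanov-Takens point", {
  br <- continue_equilibria(mepd_params(), "Kp", c(0, 14),
                            guess = c(0, 0, 0))
  hb <- Filter(function(b) b$kind == "HB", detect_codim1(br))[[1]]
  cv <- continue_codim1_locus(hb, mepd_params(), c("Kp", "alpha"),
                              box = c(0, 20, 0.5, 1))
  pts <- cv$points
  # every returned point satisfies the defining system
  expect_lt(max(abs(pts$g)), 1e-8)
  # oscillations require most excitation to go to the glutamatergic
  # population: the genuine Hopf segment never dips to low alpha
  expect_gt(min(pts$p2[pts$c1 > 0]), 0.7)
  bt <- Filter(function(b) b$kind == "BT", detect_codim2(cv))
  expect_gte(length(bt), 1L)
  # at the BT point two eigenvalues are (numerically) zero
  mods <- sort(Mod(bt[[1]]$eigenvalues))
  expect_lt(mods[1], 1e-4)
  expect_lt(mods[2], 1e-4)
})

test_that("saddle-node locus carries a cusp in the connectivity plane", {
  p <- mepd_params(Kp = 2.3)
  br <- continue_equilibria(p, "c_il", c(0, 80), guess = c(0.01, 0.01, 0.01))
  sn <- Filter(function(b) b$kind == "SN", detect_codim1(br))[[1]]
  cv <- continue_codim1_locus(sn, p, c("c_il", "c_li"), box = c(0, 40, 0, 40))
  expect_lt(max(abs(cv$points$g)), 1e-8)
  cp <- Filter(function(b) b$kind == "CP", detect_codim2(cv))
  expect_gte(length(cp), 1L)
})

test_that("connectivity branches reproduce the oscillatory windows", {
  p <- mepd_params(Kp = 2.3)
  # the Glu -> GABAint strength has a bounded oscillatory window
  br <- continue_equilibria(p, "c_li", c(0, 40), guess = c(0.01, 0.01, 0.01))
  kinds <- vapply(detect_codim1(br), `[[`, character(1), "kind")
  vals <- vapply(detect_codim1(br), `[[`, numeric(1), "value")
  hbv <- sort(vals[kinds == "HB"])
  expect_identical(length(hbv), 2L)
  expect_true(hbv[1] < 16 && hbv[2] > 16)  # the default sits inside
})

test_that("homoclinic approximation is insensitive to its threshold", {
  box <- c(1, 20, 0.895, 0.92)
  hc1 <- approximate_homoclinic(mepd_params(), c("Kp", "alpha"), box,
                                n_grid = 2, hc_factor = 4)
  hc2 <- approximate_homoclinic(mepd_params(), c("Kp", "alpha"), box,
                                n_grid = 2, hc_factor = 8)
  expect_identical(nrow(hc1$points), 2L)
  expect_identical(nrow(hc2$points), 2L)
  # doubling the period threshold moves each point by less than a
  # continuation step (the approach to the homoclinic is exponential)
  expect_lt(max(abs(hc1$points$p1 - hc2$points$p1)), 0.05)
  # the curve sits between the Table range end and the first fold
  expect_true(all(hc1$points$p1 > 14 & hc1$points$p1 < 18.5))
})

test_that("torus bifurcation aligns with the MePD Hopf point", {
  tr <- locate_torus_bifurcation(coupling = coupling_params("glut_stim"))
  expect_identical(tr$kind, "TR")
  expect_lt(abs(tr$value - 1.4), 0.05)
  # no external forcing, no torus
  expect_null(locate_torus_bifurcation(
    coupling = coupling_params(j_l = 0, j_e = 0)))
})
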