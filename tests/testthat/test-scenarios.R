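test_that("kisspeptin sweep: no drive reduces to the isolated oscillator", {
  sw <- sweep_kisspeptin(c(0, 0.5, 1))
  r <- sw$results
  # at Kp = 0 the MePD is silent and the KNDy IPI equals the uncoupled one
  un <- detect_pulses(integrate_model("kndy", t_span = c(0, 600)))
  expect_lt(abs(r$mean_ipi[1] - un$mean_ipi), 0.02 * un$mean_ipi)
  expect_lt(abs(r$mean_mepd[1]), 1e-6)
  # modest drive below the Hopf point already shortens the IPI
  expect_true(all(diff(r$mean_ipi) < 0))
  expect_identical(unique(r$label), "stationary")
})

test_that("GABA-efferent activity declines toward zero across the band", {
  # disinhibition: along the oscillatory band the cycle-averaged GABA
  # efferent output falls away toward zero as the drive grows
  mg <- vapply(c(2, 4, 6, 10, 14), function(kp) {
    tr <- integrate_model("mepd", mepd = mepd_params(Kp = kp),
                          t_span = c(0, 60))
    mean_outputs(tr)$mean_gaba
  }, numeric(1))
  expect_true(all(diff(mg) < 0))
  expect_lt(mg[5], 0.05)
})

test_that("find_gain_switch brackets the Ge amplitude maximum", {
  gs <- find_gain_switch()
  expect_lt(abs(gs$Kp - 1.6), 0.1)
  g <- gs$grid
  im <- which.max(g$ge_max)
  # rising before the switch, falling after
  expect_true(all(diff(g$ge_max[1:im]) > 0))
  expect_true(all(diff(g$ge_max[im:nrow(g)]) < 0))
  # located switch is stable under halving the grid resolution
  gs2 <- find_gain_switch(n_grid = 24)
  expect_lt(abs(gs$Kp - gs2$Kp), 0.05)
})

test_that("mean-output heat map obeys linearity and the disinhibition story", {
  hm <- heatmap_mean_output(c("Kp", "c_ie"), seq(0, 12, by = 2),
                            c(5, 25, 45))
  # cell-wise linearity of the output functionals
  expect_equal(hm$mean_mepd, hm$mean_glut - hm$mean_gaba, tolerance = 1e-12)
  # weak GABA-GABA interaction: GABAergic output grows with excitation
  # (monotone up to very strong drive, where it saturates)
  expect_true(all(diff(hm$mean_gaba[1:6, 1]) > 0))
  expect_gt(hm$mean_gaba[7, 1], 0.25)
  # strong interaction drives the GABA efferents to silence
  expect_lt(hm$mean_gaba[length(hm$grid1), 3], 0.02)
  # the long-format CSV export round-trips
  tf <- withr::local_tempfile(fileext = ".csv")
  write_heatmap_csv(hm, tf)
  df <- utils::read.csv(tf)
  expect_identical(nrow(df), length(hm$grid1) * length(hm$grid2))
})

test_that("antagonism scenarios reproduce the receptor-blocking stories", {
  base_low <- sweep_kisspeptin(0.5)$results
  base_hi <- sweep_kisspeptin(3)$results
  an <- sweep_antagonism("beta1", c(0, 0.5), c(0.5, 3),
                         coupled_cells = data.frame(beta = c(0.5, 0.5),
                                                    Kp = c(0.5, 3)))
  cc <- an$coupled
  # partial GABA antagonism at low drive leaves the KNDy IPI unchanged
  expect_lt(abs(cc$mean_ipi[1] - base_low$mean_ipi[1]),
            0.02 * base_low$mean_ipi[1])
  # combined with strong drive the output turns more inhibitory and the
  # IPI lengthens
  expect_gt(cc$mean_ipi[2], 1.2 * base_hi$mean_ipi[1])
  expect_lt(cc$mean_mepd[2], base_hi$mean_mepd[1])
  # glutamate antagonism plus strong drive silences the pulse generator
  an2 <- sweep_antagonism("beta2", c(0.5), c(6),
                          coupled_cells = data.frame(beta = 0.5, Kp = 6))
  expect_false(an2$coupled$classification[1] == "pulsatile")
  expect_gt(an2$coupled$mean_mepd[1], 0)  # exclusively excitatory output
})

test_that("projection presets reduce to the baseline when weights are equal", {
  sw1 <- sweep_kisspeptin(c(0, 0.8))
  sw2 <- sweep_projection_stimulation("baseline", c(0, 0.8))
  expect_equal(sw1$results$mean_ipi, sw2$results$mean_ipi, tolerance = 1e-12)
})

test_that("warm- and cold-started sweeps agree where dynamics match", {
  grid <- c(0.5, 3, 6)
  warm <- sweep_kisspeptin(grid)$results
  cold <- do.call(rbind, lapply(grid, function(kp)
    sweep_kisspeptin(kp)$results))
  same <- warm$classification == cold$classification
  expect_true(all(same))
  expect_lt(max(abs(warm$mean_ipi[same] - cold$mean_ipi[same]) /
                cold$mean_ipi[same]), 0.02)
})
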