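# Scenario drivers: the in-silico experiments (kisspeptin stimulation,
# receptor antagonism, projection stimulation, mean-output heat maps,
# gain-switch location).

#' Simulate the MePD circuit and classify its post-transient dynamics
#'
#' A post-transient peak-to-peak `Gl` range above `osc_tol` counts as
#' oscillatory; this is the simulation-side classifier used as the
#' independent oracle against the continued Hopf boundary.
#'
#' @param p an [mepd_params()] object.
#' @param init initial state (warm-start with a previous end state when
#'   sweeping).
#' @param t_end simulation window (min); statistics use the second half.
#' @param osc_tol peak-to-peak threshold for the oscillatory call.
#' @return List: `label` (`"oscillatory"`/`"stationary"`), per-component
#'   post-transient `range` and `max`, `summary` (an `mk_output_summary`),
#'   `end_state`.
#' @export
classify_mepd <- function(p, init = c(0.1, 0.1, 0.1), t_end = 60,
                          osc_tol = 1e-3) {
  tr <- integrate_model("mepd", mepd = p, init = init, t_span = c(0, t_end),
                        dt_out = 0.005)
  po <- post_transient(tr)
  rng <- apply(po$states, 2, function(z) diff(range(z)))
  os <- mean_outputs(tr)
  list(label = if (rng[["Gl"]] > osc_tol) "oscillatory" else "stationary",
       range = rng, summary = os, end_state = po$states[nrow(po$states), ],
       max = apply(po$states, 2, max))
}

# One coupled run returning output + pulse statistics (used by all sweeps)
coupled_point <- function(mepd, kndy, coupling, init, t_end) {
  tr <- integrate_model("coupled", mepd = mepd, kndy = kndy,
                        coupling = coupling, init = init,
                        t_span = c(0, t_end))
  os <- mean_outputs(tr)
  ps <- detect_pulses(tr)
  list(summary = os, pulses = ps,
       end_state = tr$states[nrow(tr$states), ])
}

sweep_row <- function(val, cp, label) {
  data.frame(param = val,
             mean_glut = cp$summary$mean_glut,
             mean_gaba = cp$summary$mean_gaba,
             mean_mepd = cp$summary$mean_mepd,
             n_pulses = cp$pulses$n_pulses,
             mean_ipi = cp$pulses$mean_ipi,
             ipi_cv = if (length(cp$pulses$ipis) > 1)
               stats::sd(cp$pulses$ipis) / mean(cp$pulses$ipis) else NA_real_,
             classification = cp$pulses$classification,
             label = label)
}

#' Kisspeptin-stimulation sweep of the coupled system
#'
#' Mimics optogenetic stimulation of MePD kisspeptin neurons: the coupled
#' MePD-KNDy system is simulated across a grid of kisspeptin drives `Kp`
#' with baseline projection weights, recording mean MePD outputs and KNDy
#' pulse statistics per grid point.  Runs are warm-started from the
#' previous grid point's end state to stay on the attracting branch.
#'
#' @param kp_grid increasing vector of `Kp` values.
#' @param mepd,kndy parameter objects (the `Kp` in `mepd` is overridden).
#' @param coupling projection weights; defaults to the baseline preset
#'   `(j_l, j_e) = (1, 1)`.
#' @param t_end coupled simulation window per point (min); pulse statistics
#'   use the second half.
#' @return An object of class `mk_sweep`: `results` data frame (one row per
#'   grid point: `param`, mean outputs, `n_pulses`, `mean_ipi`, `ipi_cv`,
#'   KNDy `classification`, MePD dynamics `label`), plus sweep metadata.
#' @export
sweep_kisspeptin <- function(kp_grid, mepd = mepd_params(),
                             kndy = kndy_params(),
                             coupling = coupling_params("baseline"),
                             t_end = 600) {
  sweep_coupled_kp(kp_grid, mepd, kndy, coupling, t_end,
                   scenario = "kisspeptin")
}

#' Projection-stimulation sweep of the coupled system
#'
#' Mimics optogenetic stimulation of MePD projection terminals in the ARC
#' by re-weighting the glutamatergic and GABAergic contributions
#' (`glut_stim`: `j_l = 1.5, j_e = 0.5`; `gaba_stim`: `j_l = 0.5,
#' j_e = 1.5`) while sweeping the MePD drive `Kp` (the in-silico
#' stimulation level).
#'
#' @param preset `"glut_stim"` or `"gaba_stim"` (or `"baseline"`, which
#'   reduces to [sweep_kisspeptin()]).
#' @inheritParams sweep_kisspeptin
#' @return An `mk_sweep` (see [sweep_kisspeptin()]); KNDy quiescence at high
#'   stimulation shows up as `classification != "pulsatile"` rows.
#' @export
sweep_projection_stimulation <- function(preset = c("glut_stim", "gaba_stim",
                                                    "baseline"),
                                         kp_grid, mepd = mepd_params(),
                                         kndy = kndy_params(), t_end = 600) {
  preset <- match.arg(preset)
  sweep_coupled_kp(kp_grid, mepd, kndy, coupling_params(preset), t_end,
                   scenario = paste0("projection_", preset))
}

sweep_coupled_kp <- function(kp_grid, mepd, kndy, coupling, t_end, scenario) {
  stopifnot(is.numeric(kp_grid), !is.unsorted(kp_grid))
  init <- NULL
  rows <- vector("list", length(kp_grid))
  for (i in seq_along(kp_grid)) {
    pm <- set_params(mepd, Kp = kp_grid[i])
    lab <- classify_mepd(pm)$label
    cp <- coupled_point(pm, kndy, coupling, init, t_end)
    init <- cp$end_state
    rows[[i]] <- sweep_row(kp_grid[i], cp, lab)
  }
  structure(list(results = do.call(rbind, rows), param = "Kp",
                 scenario = scenario, coupling = unclass(coupling),
                 t_end = t_end),
            class = "mk_sweep")
}

#' @export
print.mk_sweep <- function(x, ...) {
  cat(sprintf("<mk_sweep> scenario '%s': %d points over '%s' in [%g, %g]\n",
              x$scenario, nrow(x$results), x$param, min(x$results$param),
              max(x$results$param)))
  invisible(x)
}

#' Receptor-antagonism sweep
#'
#' Models partial pharmacological antagonism by the fractional suppression
#' coefficients: `beta1` scales down all GABAergic interactions, `beta2`
#' all glutamatergic ones.  Over a `beta x Kp` grid the MePD circuit is
#' classified and its mean outputs recorded (a heat map); for selected
#' cells full coupled simulations yield KNDy pulse statistics.
#'
#' @param which `"beta1"` or `"beta2"`.
#' @param beta_grid suppression values in \[0, 1\].
#' @param kp_grid `Kp` values in \[0, 14\].
#' @param mepd,kndy parameter objects.
#' @param coupled_cells data frame with columns `beta`, `Kp`: cells to run
#'   through the coupled system (default none).
#' @param t_end coupled window (min).
#' @return List of class `mk_antagonism`: `heatmap` (an `mk_heatmap` of
#'   mean MePD output over the grid), `coupled` (an `mk_sweep`-style data
#'   frame for the requested cells, or `NULL`).
#' @export
sweep_antagonism <- function(which = c("beta1", "beta2"), beta_grid, kp_grid,
                             mepd = mepd_params(), kndy = kndy_params(),
                             coupled_cells = NULL, t_end = 600) {
  which <- match.arg(which)
  stopifnot(all(beta_grid >= 0 & beta_grid <= 1))
  hm <- heatmap_mean_output(c("Kp", which), kp_grid, beta_grid,
                            params = mepd)
  coupled <- NULL
  if (!is.null(coupled_cells)) {
    rows <- vector("list", nrow(coupled_cells))
    for (i in seq_len(nrow(coupled_cells))) {
      pm <- do.call(set_params, c(list(mepd), stats::setNames(
        list(coupled_cells$beta[i], coupled_cells$Kp[i]), c(which, "Kp"))))
      lab <- classify_mepd(pm)$label
      cp <- coupled_point(pm, kndy, coupling_params("baseline"), NULL, t_end)
      r <- sweep_row(coupled_cells$Kp[i], cp, lab)
      r$beta <- coupled_cells$beta[i]
      rows[[i]] <- r
    }
    coupled <- do.call(rbind, rows)
  }
  structure(list(which = which, heatmap = hm, coupled = coupled),
            class = "mk_antagonism")
}

#' Mean-output heat map over a two-parameter grid
#'
#' For every cell of a two-parameter grid the MePD circuit is simulated
#' past its transient and the time-averaged outputs (mean glutamatergic,
#' mean GABAergic, mean MePD = difference) are recorded, together with an
#' oscillatory-region mask from the post-transient peak-to-peak range.
#' Stationary cells carry the steady-state mean (flagged by the mask).
#'
#' @param param_pair names of the two swept parameters (axis 1, axis 2).
#' @param grid1,grid2 axis grids.
#' @param params base [mepd_params()] object.
#' @param t_end,osc_tol simulation window and oscillation threshold per
#'   cell.
#' @return An object of class `mk_heatmap`: `grid1`, `grid2`, matrices
#'   `mean_glut`, `mean_gaba`, `mean_mepd` (rows = `grid1`), logical mask
#'   `oscillatory`.
#' @export
heatmap_mean_output <- function(param_pair, grid1, grid2,
                                params = mepd_params(), t_end = 60,
                                osc_tol = 1e-3) {
  stopifnot(length(param_pair) == 2)
  n1 <- length(grid1); n2 <- length(grid2)
  mg <- mb <- mm <- matrix(NA_real_, n1, n2)
  osc <- matrix(FALSE, n1, n2)
  for (j in seq_len(n2)) {
    init <- c(0.1, 0.1, 0.1)  # warm start along axis 1 within each column
    for (i in seq_len(n1)) {
      ps <- set_param1_raw(set_param1_raw(params, param_pair[1], grid1[i]),
                           param_pair[2], grid2[j])
      cl <- classify_mepd(ps, init = init, t_end = t_end, osc_tol = osc_tol)
      init <- cl$end_state
      mg[i, j] <- cl$summary$mean_glut
      mb[i, j] <- cl$summary$mean_gaba
      mm[i, j] <- cl$summary$mean_mepd
      osc[i, j] <- cl$label == "oscillatory"
    }
  }
  structure(list(pair = param_pair, grid1 = grid1, grid2 = grid2,
                 mean_glut = mg, mean_gaba = mb, mean_mepd = mm,
                 oscillatory = osc),
            class = "mk_heatmap")
}

#' @export
print.mk_heatmap <- function(x, ...) {
  cat(sprintf("<mk_heatmap> mean outputs on %d x %d (%s, %s) grid; %.0f%% oscillatory\n",
              length(x$grid1), length(x$grid2), x$pair[1], x$pair[2],
              100 * mean(x$oscillatory)))
  invisible(x)
}

#' Locate the GABA-efferent gain switch
#'
#' Within the oscillatory band the per-cycle maximum of the GABA-efferent
#' activity `Ge` (the limit-cycle amplitude branch) first rises with the
#' kisspeptin drive and then falls: past the switch, the inhibitory input
#' from the GABA interneurons outweighs the glutamatergic excitation and
#' additional drive *reduces* GABAergic output.  The switch is located as
#' the interior maximum of the cycle maximum of `Ge` over a `Kp` grid
#' (warm-started simulations), refined by interpolation.
#'
#' @param p [mepd_params()] fixed parameters.
#' @param kp_range grid range; default `hopf + 0.02` to `hopf + 1`, with
#'   the Hopf point found by continuation.
#' @param n_grid grid resolution.
#' @param t_end per-point simulation window (min).
#' @return List with `Kp` (the switch), `max_ge`, and the `grid` data
#'   frame; `NULL` if the curve has no interior maximum.
#' @export
find_gain_switch <- function(p = mepd_params(), kp_range = NULL, n_grid = 48,
                             t_end = 80) {
  if (is.null(kp_range)) {
    br <- continue_equilibria(p, "Kp", c(0, 14), guess = c(0.01, 0.01, 0.01))
    hbs <- Filter(function(b) b$kind == "HB", detect_codim1(br))
    if (!length(hbs)) stop("no Hopf point: no oscillatory band", call. = FALSE)
    kp_range <- c(hbs[[1]]$value + 0.02, hbs[[1]]$value + 1)
  }
  grid <- seq(kp_range[1], kp_range[2], length.out = n_grid)
  ge_max <- numeric(n_grid)
  init <- c(0.1, 0.1, 0.1)
  for (i in seq_along(grid)) {
    cl <- classify_mepd(set_params(p, Kp = grid[i]), init = init,
                        t_end = t_end)
    init <- cl$end_state
    ge_max[i] <- cl$max[["Ge"]]
  }
  im <- which.max(ge_max)
  if (im == 1L || im == n_grid) return(NULL)
  f <- stats::splinefun(grid, ge_max)
  opt <- stats::optimize(f, interval = grid[c(im - 1L, im + 1L)],
                         maximum = TRUE)
  list(Kp = opt$maximum, max_ge = opt$objective,
       grid = data.frame(Kp = grid, ge_max = ge_max))
}
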