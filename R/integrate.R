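#' Integrate a model trajectory
#'
#' Adaptive Dormand-Prince 5(4) integration with dense output resampled onto
#' a uniform time grid (minutes).  Deterministic: identical inputs reproduce
#' the trajectory bit-identically.
#'
#' Default initial conditions (the models' reference states): MePD
#' `(0.1, 0.1, 0.1)`; KNDy `(0.1, 0.1, 1)`; coupled, their concatenation.
#' The default output step is 0.002 min for the MePD system and 0.01 min for
#' the KNDy and coupled systems; default windows are 30 min (MePD) and
#' 600 min (KNDy/coupled), long enough for at least ten KNDy pulses.
#'
#' @param model `"mepd"`, `"kndy"` or `"coupled"`.
#' @param mepd an [mepd_params()] object (models `"mepd"`, `"coupled"`).
#' @param kndy a [kndy_params()] object (models `"kndy"`, `"coupled"`).
#' @param coupling a [coupling_params()] object (models `"kndy"`,
#'   `"coupled"`); for `"kndy"` it weights the constant `ext` drive.
#' @param init initial state; defaults as above.
#' @param t_span integration window `c(t0, t1)` in minutes.
#' @param dt_out uniform output step (min).
#' @param ext constant external `(Gl, Ge)` drive for the isolated KNDy model.
#' @param rtol,atol relative / absolute integration tolerances.
#' @param transient_frac fraction of the window discarded as transient when
#'   computing statistics, capped at `transient_cap` minutes.
#' @param transient_cap cap (min) on the discarded transient.
#' @param maxsteps safety cap on accepted + rejected solver steps.
#' @return An object of class `mk_trajectory`: list with `times`, `states`
#'   (matrix, named columns), `transient_end` (time), `model` and `meta`
#'   (parameters and solver settings).
#' @examples
#' tr <- integrate_model("mepd", mepd = mepd_params(Kp = 2.3),
#'                       t_span = c(0, 30))
#' range(tr$states[, "Gl"])
#' @export
integrate_model <- function(model = c("mepd", "kndy", "coupled"),
                            mepd = mepd_params(), kndy = kndy_params(),
                            coupling = coupling_params("baseline"),
                            init = NULL, t_span = NULL, dt_out = NULL,
                            ext = c(0, 0), rtol = 1e-8, atol = 1e-10,
                            transient_frac = 0.5, transient_cap = 200,
                            maxsteps = 5e7) {
  model <- match.arg(model)
  sys_id <- match(model, c("mepd", "kndy", "coupled")) - 1L
  if (is.null(t_span)) t_span <- if (model == "mepd") c(0, 30) else c(0, 600)
  if (length(t_span) != 2L || t_span[2] <= t_span[1])
    stop("t_span must be c(t0, t1) with t1 > t0", call. = FALSE)
  if (is.null(dt_out)) dt_out <- if (model == "mepd") 0.002 else 0.01
  if (is.null(init))
    init <- switch(model,
                   mepd = c(0.1, 0.1, 0.1),
                   kndy = c(0.1, 0.1, 1),
                   coupled = c(0.1, 0.1, 0.1, 0.1, 0.1, 1))
  dim_need <- if (model == "coupled") 6L else 3L
  if (length(init) != dim_need || !all(is.finite(init)))
    stop("init must be a finite vector of length ", dim_need, call. = FALSE)
  pm <- if (model != "kndy") as_mepd_vec(mepd) else numeric(0)
  pk <- if (model != "mepd") as_kndy_vec(kndy) else numeric(0)
  cp <- as_coupling_vec(coupling)
  res <- tryCatch(
    integrate_cpp(sys_id, pm, pk, cp, as.numeric(ext), as.numeric(init),
                  t_span[1], t_span[2], dt_out, rtol, atol, maxsteps),
    error = function(e)
      stop("integration failed for model '", model, "' (",
           conditionMessage(e), "); parameters: ",
           paste(utils::capture.output(utils::str(
             list(mepd = if (model != "kndy") unclass(mepd),
                  kndy = if (model != "mepd") unclass(kndy)))),
             collapse = " "), call. = FALSE))
  g <- res$grid
  cols <- switch(model,
                 mepd = c("Gl", "Gi", "Ge"),
                 kndy = c("D", "N", "v"),
                 coupled = c("Gl", "Gi", "Ge", "D", "N", "v"))
  states <- g[, -1, drop = FALSE]
  colnames(states) <- cols
  window <- t_span[2] - t_span[1]
  tend <- t_span[1] + min(transient_frac * window, transient_cap)
  structure(list(times = g[, 1], states = states,
                 transient_end = tend, model = model,
                 meta = list(mepd = if (model != "kndy") unclass(mepd),
                             kndy = if (model != "mepd") unclass(kndy),
                             coupling = unclass(coupling),
                             ext = ext, init = init, t_span = t_span,
                             dt_out = dt_out, rtol = rtol, atol = atol,
                             nstep = res$nstep)),
            class = "mk_trajectory")
}

#' @export
print.mk_trajectory <- function(x, ...) {
  cat(sprintf("<mk_trajectory> model '%s': %d samples on [%g, %g] min (dt = %g), transient end %g min\n",
              x$model, length(x$times), x$times[1],
              x$times[length(x$times)], x$meta$dt_out, x$transient_end))
  invisible(x)
}

#' Post-transient portion of a trajectory
#'
#' @param traj an `mk_trajectory`.
#' @return The same object restricted to `times >= transient_end`.
#' @export
post_transient <- function(traj) {
  stopifnot(inherits(traj, "mk_trajectory"))
  keep <- traj$times >= traj$transient_end
  traj$times <- traj$times[keep]
  traj$states <- traj$states[keep, , drop = FALSE]
  traj$transient_end <- traj$times[1]
  traj
}

#' Mean MePD output functionals
#'
#' Time averages over the post-transient window by trapezoidal quadrature:
#' mean glutamatergic output (average of `Gl`), mean GABAergic output
#' (average of `Ge`) and the mean MePD output, the average of `Gl - Ge`.
#' A negative mean MePD output means net inhibitory drive to downstream
#' targets; positive means net excitatory.
#'
#' @param traj an `mk_trajectory` containing `Gl` and `Ge` columns.
#' @param window optional `c(t0, t1)` overriding the trajectory's
#'   post-transient window.
#' @return An object of class `mk_output_summary` with fields `mean_glut`,
#'   `mean_gaba`, `mean_mepd` and `window`.
#' @export
mean_outputs <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "mk_trajectory"))
  if (!all(c("Gl", "Ge") %in% colnames(traj$states)))
    stop("trajectory has no MePD components", call. = FALSE)
  if (is.null(window)) window <- c(traj$transient_end, max(traj$times))
  keep <- traj$times >= window[1] & traj$times <= window[2]
  t <- traj$times[keep]
  if (length(t) < 2L) stop("averaging window holds fewer than 2 samples",
                           call. = FALSE)
  mg <- trapz_mean(t, traj$states[keep, "Gl"])
  mb <- trapz_mean(t, traj$states[keep, "Ge"])
  structure(list(mean_glut = mg, mean_gaba = mb, mean_mepd = mg - mb,
                 window = c(t[1], t[length(t)])),
            class = "mk_output_summary")
}

#' @export
print.mk_output_summary <- function(x, ...) {
  cat(sprintf("mean outputs on [%g, %g] min: glut %.6f, GABA %.6f, MePD (glut - GABA) %.6f\n",
              x$window[1], x$window[2], x$mean_glut, x$mean_gaba, x$mean_mepd))
  invisible(x)
}

# trapezoidal time average; exact for the uniform grids produced here
trapz_mean <- function(t, y) {
  n <- length(t)
  dt <- diff(t)
  sum(dt * (y[-1] + y[-n]) / 2) / (t[n] - t[1])
}

#' Write a trajectory to CSV
#'
#' Columns: `time` then the state components, 12 significant digits.
#'
#' @param traj an `mk_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = signif(traj$times, 12),
                   signif(traj$states, 12), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
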