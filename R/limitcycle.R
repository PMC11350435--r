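# Limit-cycle location by single shooting on a Poincare section, and
# continuation of the cycle in one parameter.

# One shooting solve: section Gl = sec fixed, unknowns (Gi0, Ge0, T).
# Residual: flow((sec, Gi0, Ge0), T) - (sec, Gi0, Ge0).
# Jacobian columns from the monodromy matrix and the endpoint vector field.
shoot_cycle <- function(p, sec, gi, ge, Tper, tol = 1e-10, max_iter = 25,
                        rtol = 1e-10, atol = 1e-12) {
  pm <- as_mepd_vec(p)
  for (it in seq_len(max_iter)) {
    x0 <- c(sec, gi, ge)
    fl <- tryCatch(flow_mepd_cpp(pm, x0, Tper, rtol, atol),
                   error = function(e) NULL)
    if (is.null(fl)) return(NULL)
    r <- fl$x - x0
    if (max(abs(r)) < tol)
      return(list(x0 = unname(x0), period = unname(Tper),
                  monodromy = fl$monodromy, residual = max(abs(r))))
    M <- fl$monodromy
    fT <- mepd_rhs(fl$x, p)
    A <- cbind((M - diag(3))[, 2:3], fT)
    d <- tryCatch(solve(A, -r), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    # damp large steps; the period must stay positive
    sc <- min(1, 0.5 * Tper / max(abs(d[3]), 1e-12), 0.3 / max(abs(d[1:2]), 1e-12))
    gi <- gi + sc * d[1]
    ge <- ge + sc * d[2]
    Tper <- Tper + sc * d[3]
    if (Tper <= 0) return(NULL)
  }
  NULL
}

# Shooting with the period held fixed and the parameter free: used on the
# blow-up tail near the homoclinic, where the parameter is numerically
# pinned and only the period advances.  Unknowns (Gi0, Ge0, s); damped
# Newton with residual monitoring (the linearization degrades near the
# saddle passage).
shoot_cycle_fixedT <- function(p, param, s, sec, gi, ge, Tper, tol = 1e-10,
                               max_iter = 120, rtol = 1e-10, atol = 1e-12) {
  relax <- 1
  res_prev <- Inf
  for (it in seq_len(max_iter)) {
    pm <- as_mepd_vec(set_param1_raw(p, param, s))
    x0 <- c(sec, gi, ge)
    fl <- tryCatch(flow_mepd_cpp(pm, x0, Tper, rtol, atol),
                   error = function(e) NULL)
    if (is.null(fl)) return(NULL)
    r <- fl$x - x0
    res <- max(abs(r))
    if (res < tol)
      return(list(x0 = unname(x0), period = Tper, s = s,
                  monodromy = fl$monodromy, residual = res))
    if (res > 0.8 * res_prev) relax <- max(relax / 2, 0.25)
    else relax <- min(relax * 1.3, 1)
    res_prev <- res
    hs <- 1e-7 * max(1, abs(s))
    fl2 <- flow_mepd_cpp(as_mepd_vec(set_param1_raw(p, param, s + hs)),
                         x0, Tper, rtol, atol)
    dds <- (fl2$x - fl$x) / hs
    A <- cbind((fl$monodromy - diag(3))[, 2:3], dds)
    d <- tryCatch(solve(A, -r), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    sc <- relax * min(1, 0.3 / max(abs(d[1:2]), 1e-12))
    gi <- gi + sc * d[1]; ge <- ge + sc * d[2]; s <- s + sc * unname(d[3])
  }
  NULL
}

# simulate to the attractor and extract a seed (section value, state on the
# section, period estimate); returns NULL when no oscillation is found
seed_cycle <- function(p, t_win = 400, dt = 0.005) {
  tr <- integrate_model("mepd", mepd = p, t_span = c(0, t_win), dt_out = dt,
                        transient_frac = 0.75, transient_cap = t_win)
  tr <- post_transient(tr)
  gl <- tr$states[, "Gl"]
  if (diff(range(gl)) < 1e-5) return(NULL)
  sec <- mean(range(gl))
  up <- which(gl[-length(gl)] < sec & gl[-1] >= sec)
  if (length(up) < 3L) return(NULL)
  Tper <- mean(diff(tr$times[up]))
  i <- up[length(up) - 1L]
  # linear interpolation onto the section
  w <- (sec - gl[i]) / (gl[i + 1] - gl[i])
  x0 <- (1 - w) * tr$states[i, ] + w * tr$states[i + 1, ]
  list(sec = sec, gi = x0[["Gi"]], ge = x0[["Ge"]], period = Tper)
}

# locate the cycle at one parameter value, refining a seed by shooting
solve_cycle_at <- function(p, seed) {
  sol <- shoot_cycle(p, seed$sec, seed$gi, seed$ge, seed$period)
  if (is.null(sol)) return(NULL)
  sol
}

cycle_extrema <- function(p, sol, n_samp = 400) {
  tr <- integrate_model("mepd", mepd = p, init = sol$x0,
                        t_span = c(0, sol$period),
                        dt_out = sol$period / n_samp, transient_frac = 0,
                        rtol = 1e-10, atol = 1e-12)
  st <- tr$states
  list(max = apply(st, 2, max), min = apply(st, 2, min),
       mean = apply(st, 2, mean), traj = st)
}

# move the shooting anchor to the cycle's current mid-range Gl level,
# so the section stays transverse as the cycle drifts along the branch
reanchor <- function(sol, ex) {
  st <- ex$traj
  sec <- (ex$max[["Gl"]] + ex$min[["Gl"]]) / 2
  gl <- st[, "Gl"]
  n <- nrow(st)
  up <- which(gl[-n] < sec & gl[-1] >= sec)
  if (!length(up)) return(sol)
  i <- up[1]
  w <- (sec - gl[i]) / (gl[i + 1] - gl[i])
  x0 <- (1 - w) * st[i, ] + w * st[i + 1, ]
  x0[1] <- sec
  sol$x0 <- unname(x0)
  sol
}

# One pseudo-arclength corrector for the cycle system.  Unknowns, scaled:
# v = (Gi0, Ge0, s, tau * T) with the section Gl0 = sec held fixed and
# tau = 1/onset_period so the period contributes O(1) to the arclength
# metric.  Residual: flow((sec, Gi0, Ge0), T; s) - x0 plus the arclength
# condition along the frozen tangent.
lc_corrector <- function(p, param, sec, v0, tvec, h, tau, tol = 1e-9,
                         max_iter = 40, rtol = 1e-10, atol = 1e-12,
                         tmax = Inf) {
  v <- v0 + h * tvec
  damp <- 1
  res_prev <- Inf
  for (it in seq_len(max_iter)) {
    if (v[4] <= 0 || v[4] > tmax) return(NULL)
    s <- v[3]
    Tper <- v[4] / tau
    ps <- set_param1_raw(p, param, s)
    x0 <- c(sec, v[1], v[2])
    fl <- tryCatch(flow_mepd_cpp(as_mepd_vec(ps), x0, Tper, rtol, atol),
                   error = function(e) NULL)
    if (is.null(fl)) return(NULL)
    rr <- fl$x - x0
    arc <- sum((v - v0) * tvec) - h
    res <- max(abs(rr))
    if (res < tol && abs(arc) < 1e-10)
      return(list(v = v, x0 = unname(x0), period = Tper, s = s,
                  monodromy = fl$monodromy, residual = res))
    # damp when the linearization is poor (residual stalls or grows)
    if (res > 0.8 * res_prev) damp <- max(damp / 2, 0.2)
    else damp <- min(damp * 1.5, 1)
    res_prev <- res
    hs <- 1e-7 * max(1, abs(s))
    fl2 <- tryCatch(flow_mepd_cpp(as_mepd_vec(set_param1_raw(p, param, s + hs)),
                                  x0, Tper, rtol, atol),
                    error = function(e) NULL)
    if (is.null(fl2)) return(NULL)
    dds <- (fl2$x - fl$x) / hs
    fT <- mepd_rhs(fl$x, ps)
    A <- rbind(cbind((fl$monodromy - diag(3))[, 2:3], dds, fT / tau), tvec)
    d <- tryCatch(solve(A, -c(rr, arc)), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    v <- v + damp * d
  }
  NULL
}

# scaled tangent (null vector of the 3x4 shooting Jacobian) at a solution
lc_tangent <- function(p, param, sol, tau, prefer, rtol = 1e-10, atol = 1e-12) {
  s <- sol$s
  ps <- set_param1_raw(p, param, s)
  fl <- tryCatch(flow_mepd_cpp(as_mepd_vec(ps), sol$x0, sol$period, rtol, atol),
                 error = function(e) NULL)
  fl2 <- tryCatch(flow_mepd_cpp(as_mepd_vec(set_param1_raw(
                    p, param, s + 1e-7 * max(1, abs(s)))),
                    sol$x0, sol$period, rtol, atol),
                  error = function(e) NULL)
  if (is.null(fl) || is.null(fl2)) return(NULL)
  hs <- 1e-7 * max(1, abs(s))
  dds <- (fl2$x - fl$x) / hs
  fT <- mepd_rhs(fl$x, ps)
  A <- cbind((fl$monodromy - diag(3))[, 2:3], dds, fT / tau)
  tryCatch(null_tangent(A, prefer = prefer), error = function(e) NULL)
}

# Number of upward crossings of the cycle's 75%-range Gl level: 1 for a
# simple loop, n for an n-times-wrapped copy (which must be rejected).
# The high level avoids false counts from the near-homoclinic saddle dwell,
# which sits close to the mid-range level.
lc_loop_count <- function(st) {
  gl <- st[, "Gl"]
  m <- min(gl) + 0.75 * (max(gl) - min(gl))
  n <- length(gl)
  sum(gl[-n] < m & gl[-1] >= m)
}

#' Continue a limit cycle from a Hopf point
#'
#' Characterizes the periodic orbit born at a Hopf bifurcation across a
#' parameter range by single shooting on a Poincare section (the cycle's
#' mid-range `Gl` level, re-anchored as the cycle drifts), with the
#' monodromy matrix from the variational equations and pseudo-arclength
#' continuation in (state, parameter, period).  The period is part of the
#' continuation vector, so folds of cycles and the steep period growth near
#' a homoclinic are traversed.  The branch is seeded by direct simulation
#' just inside the oscillatory side of the Hopf point.  Continuation stops
#' at the range ends, when the period exceeds `hc_factor` times the period
#' at onset (the homoclinic proxy), when the cycle amplitude collapses (the
#' Hopf end), or on corrector failure at the minimum step.
#'
#' @param hb an `mk_bifpoint` of kind `"HB"` from [detect_codim1()].
#' @param p the [mepd_params()] object used for the branch (fixed
#'   parameters).
#' @param range parameter interval to cover.
#' @param h0,h_min,h_max initial / minimum / maximum arclength step.
#' @param hc_factor period blow-up factor used as the homoclinic proxy
#'   threshold, in units of the period at onset.  The default (10) is close
#'   to the largest dwell time representable in double precision for this
#'   circuit's saddle eigenvalues; the recorded homoclinic parameter is
#'   insensitive to any threshold above ~6 (see the methods vignette).
#' @param seed_offset parameter offset from the Hopf point for the
#'   simulation seed.
#' @param max_points safety cap on branch length.
#' @return An object of class `mk_lcbranch`: `points` data frame (param,
#'   period, per-variable max/min/mean over the cycle, modulus of the
#'   largest non-trivial Floquet multiplier, section state) ordered by
#'   increasing parameter along the branch, plus `param`, `hb`,
#'   `onset_period` and end statuses `status` (marching away from the Hopf
#'   point: `"range"`, `"period_blowup"`, `"hc_proxy"` (the branch ends on
#'   the unstable tail past a fold of cycles with rising period -- the
#'   homoclinic-destruction signature), `"hopf_end"` or
#'   `"corrector_failure"`) and `status_lower` (marching back toward it).
#' @export
continue_limit_cycle <- function(hb, p, range = NULL, h0 = 0.03,
                                 h_min = 1e-7, h_max = 0.2,
                                 hc_factor = 10, seed_offset = 0.1,
                                 max_points = 2000) {
  stopifnot(inherits(hb, "mk_bifpoint"), hb$kind == "HB")
  param <- hb$param
  if (is.null(range)) range <- c(hb$value, hb$value + 5)
  onset_period <- 2 * pi / hb$omega
  tau <- 1 / onset_period
  dir_up <- range[2] > hb$value
  sp <- hb$value + if (dir_up) seed_offset else -seed_offset
  pseed <- set_param1_raw(p, param, sp)
  sd <- seed_cycle(pseed)
  if (is.null(sd))
    stop("no oscillation found near the Hopf point; wrong HB or subcritical case",
         call. = FALSE)
  sol <- shoot_cycle(pseed, sd$sec, sd$gi, sd$ge, sd$period)
  if (is.null(sol))
    stop("shooting failed at the seed point next to the Hopf bifurcation",
         call. = FALSE)
  sol$s <- sp

  row_of <- function(sol, ex) {
    mult <- sort(Mod(eigen(sol$monodromy, only.values = TRUE)$values),
                 decreasing = TRUE)
    nontriv <- if (abs(mult[1] - 1) < abs(mult[2] - 1)) mult[2] else mult[1]
    data.frame(
      param = sol$s, period = sol$period,
      Gl_max = ex$max[["Gl"]], Gl_min = ex$min[["Gl"]], Gl_mean = ex$mean[["Gl"]],
      Gi_max = ex$max[["Gi"]], Gi_min = ex$min[["Gi"]], Gi_mean = ex$mean[["Gi"]],
      Ge_max = ex$max[["Ge"]], Ge_min = ex$min[["Ge"]], Ge_mean = ex$mean[["Ge"]],
      floquet = nontriv, sec = sol$x0[1], Gi0 = sol$x0[2], Ge0 = sol$x0[3])
  }

  march <- function(sol, dirsign) {
    rows <- list()
    status <- "range"
    ex <- cycle_extrema(set_param1_raw(p, param, sol$s), sol)
    sol <- reanchor(sol, ex)
    rows[[1]] <- row_of(sol, ex)
    tvec <- lc_tangent(p, param, sol, tau, prefer = c(0, 0, dirsign, 0))
    if (is.null(tvec)) return(list(rows = rows, status = "corrector_failure"))
    h <- h0
    creep <- 0L
    while (length(rows) < max_points) {
      v <- c(sol$x0[2], sol$x0[3], sol$s, tau * sol$period)
      cand <- lc_corrector(p, param, sol$x0[1], v, tvec, h, tau,
                           tmax = 1.5 * hc_factor)
      ok <- FALSE
      if (!is.null(cand)) {
        exn <- cycle_extrema(set_param1_raw(p, param, cand$s), cand)
        if (lc_loop_count(exn$traj) == 1L) ok <- TRUE
      }
      if (!ok) {
        h <- h / 2
        if (h < h_min) { status <- "corrector_failure"; break }
        next
      }
      # stall detection: single shooting loses its convergence basin on the
      # near-homoclinic tail; hand over to the fixed-period climber
      dprog <- abs(cand$period - sol$period) / sol$period +
        abs(cand$s - sol$s) / max(1, abs(sol$s))
      creep <- if (dprog < 1e-5) creep + 1L else 0L
      period_rising <- cand$period > sol$period
      sol <- reanchor(cand, exn)
      rows[[length(rows) + 1L]] <- row_of(sol, exn)
      if (creep >= 8L) {
        # parameter numerically pinned while the period keeps growing:
        # the branch is climbing its homoclinic asymptote
        status <- if (period_rising) "hc_proxy" else "corrector_failure"
        break
      }
      tnew <- lc_tangent(p, param, sol, tau, prefer = tvec)
      if (is.null(tnew)) { status <- "corrector_failure"; break }
      tvec <- tnew
      h <- min(h * 1.3, h_max)
      if (sol$s > range[2] || sol$s < range[1]) { status <- "range"; break }
      if (sol$period > hc_factor * onset_period) { status <- "period_blowup"; break }
      if (exn$max[["Gl"]] - exn$min[["Gl"]] < 1e-5) { status <- "hopf_end"; break }
    }
    if (status == "corrector_failure" && length(rows)) {
      last <- rows[[length(rows)]]
      if (last$Gl_max - last$Gl_min < 1e-3) status <- "hopf_end"
      # branch terminates on the unstable tail past a fold of cycles with
      # the period rising: the numerical signature of homoclinic
      # destruction (the true HC lies within ~1e-3 of the end parameter)
      else if (last$floquet > 1) status <- "hc_proxy"
    }
    list(rows = rows, status = status, sol = sol)
  }

  # climb the period blow-up with the period as the marching variable and
  # the parameter free (numerically pinned near the homoclinic)
  period_march <- function(sol, tfac = 1.15, max_steps = 200) {
    rows <- list()
    status <- "corrector_failure"
    Tcur <- sol$period
    s <- sol$s
    while (Tcur < hc_factor * onset_period && length(rows) < max_steps) {
      Tnew <- min(Tcur * tfac, hc_factor * onset_period * 1.001)
      cand <- shoot_cycle_fixedT(p, param, s, sol$x0[1], sol$x0[2],
                                 sol$x0[3], Tnew)
      ok <- FALSE
      if (!is.null(cand) && abs(cand$s - s) < 0.05 * (1 + abs(s))) {
        exn <- cycle_extrema(set_param1_raw(p, param, cand$s), cand)
        if (lc_loop_count(exn$traj) == 1L) ok <- TRUE
      }
      if (!ok) {
        tfac <- 1 + (tfac - 1) / 2
        if (tfac - 1 < 2e-3) break
        next
      }
      sol <- reanchor(cand, exn)
      s <- cand$s
      Tcur <- Tnew
      tfac <- min(1 + (tfac - 1) * 1.4, 1.3)
      rows[[length(rows) + 1L]] <- row_of(sol, exn)
    }
    if (Tcur >= hc_factor * onset_period) status <- "period_blowup"
    list(rows = rows, status = status)
  }

  up <- march(sol, if (dir_up) 1 else -1)
  if (up$status %in% c("corrector_failure", "hc_proxy") &&
      length(up$rows) >= 2L) {
    k <- length(up$rows)
    if (up$rows[[k]]$period > up$rows[[k - 1L]]$period * (1 - 1e-9)) {
      blow <- period_march(up$sol)
      up$rows <- c(up$rows, blow$rows)
      if (blow$status == "period_blowup") up$status <- "period_blowup"
    }
  }
  down <- march(sol, if (dir_up) -1 else 1)
  rows <- c(rev(down$rows[-1]), up$rows)
  pts <- do.call(rbind, rows)
  rownames(pts) <- NULL
  structure(list(points = pts, param = param, hb = hb,
                 onset_period = onset_period,
                 status = up$status, status_lower = down$status),
            class = "mk_lcbranch")
}
#' @export
print.mk_lcbranch <- function(x, ...) {
  pr <- range(x$points$param)
  cat(sprintf("<mk_lcbranch> %d cycles along '%s' in [%.4g, %.4g]; period %.4g..%.4g min; upper end: %s\n",
              nrow(x$points), x$param, pr[1], pr[2], min(x$points$period),
              max(x$points$period), x$status))
  invisible(x)
}
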