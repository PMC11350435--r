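# Torus bifurcation of the coupled MePD-KNDy system.

#' Poincare section of a coupled trajectory
#'
#' Intersections of the post-transient orbit with the plane where one
#' component crosses a level upward, linearly interpolated.  Used to
#' distinguish a closed periodic orbit (returns cluster to a point) from a
#' quasi-periodic orbit on a torus (returns fill a curve).
#'
#' @param traj an `mk_trajectory`.
#' @param var section variable (default `"v"`).
#' @param level section level; default the post-transient midrange of `var`.
#' @return Matrix of section states (columns = remaining state components),
#'   with attribute `diameter`, the maximum pairwise distance of the return
#'   points after component-wise scaling by each component's range along
#'   the full orbit.
#' @export
poincare_section <- function(traj, var = "v", level = NULL) {
  stopifnot(inherits(traj, "mk_trajectory"))
  traj <- post_transient(traj)
  st <- traj$states
  y <- st[, var]
  if (is.null(level)) level <- mean(range(y))
  n <- nrow(st)
  up <- which(y[-n] < level & y[-1] >= level)
  others <- setdiff(colnames(st), var)
  if (!length(up))
    return(structure(matrix(numeric(0), 0, length(others),
                            dimnames = list(NULL, others)), diameter = 0))
  w <- (level - y[up]) / (y[up + 1] - y[up])
  sec <- (1 - w) * st[up, others, drop = FALSE] +
    w * st[up + 1, others, drop = FALSE]
  colnames(sec) <- others
  scl <- apply(st[, others, drop = FALSE], 2, function(z) max(diff(range(z)), 1e-12))
  ssec <- sweep(sec, 2, scl, "/")
  dia <- if (nrow(ssec) > 1) max(stats::dist(ssec)) else 0
  structure(sec, diameter = dia)
}

#' Locate the torus bifurcation of the coupled system
#'
#' When the MePD circuit crosses its Hopf bifurcation its output changes
#' from constant to periodic, so the forced KNDy oscillator's limit cycle
#' acquires a second frequency: the coupled system's periodic orbit becomes
#' a torus.  The torus bifurcation is therefore located at the MePD
#' subsystem's Hopf parameter (the two coincide because the coupling is
#' one-way).  With `verify = TRUE` the alignment is checked dynamically:
#' just below the point the coupled attractor's Poincare returns cluster to
#' a point, just above they spread along a curve.
#'
#' @param mepd,kndy,coupling parameter objects of the coupled system.
#' @param param free MePD parameter (default `"Kp"`).
#' @param range parameter interval searched for the MePD Hopf point.
#' @param verify run the Poincare-section diagnostic?
#' @param offset parameter offset used for the verification runs.
#' @param t_end simulation window for verification (min).
#' @return An `mk_bifpoint` of kind `"TR"` (fields as for HB, plus
#'   `diagnostics` when verified: section diameters below/above), or `NULL`
#'   when the MePD system has no Hopf point in the range.
#' @export
locate_torus_bifurcation <- function(mepd = mepd_params(),
                                     kndy = kndy_params(),
                                     coupling = coupling_params("baseline"),
                                     param = "Kp", range = c(0, 14),
                                     verify = FALSE, offset = 0.15,
                                     t_end = 600) {
  if (coupling$j_l == 0 && coupling$j_e == 0) return(NULL)
  br <- continue_equilibria(mepd, param, range, guess = c(0.01, 0.01, 0.01))
  hbs <- Filter(function(b) b$kind == "HB", detect_codim1(br))
  if (!length(hbs)) return(NULL)
  hb <- hbs[[1]]
  tr_point <- structure(
    list(kind = "TR", param = param, value = hb$value, state = hb$state,
         eigenvalues = hb$eigenvalues, omega = hb$omega, mepd_hb = hb),
    class = "mk_bifpoint")
  if (verify) {
    dia <- function(val) {
      ps <- set_param1_raw(mepd, param, val)
      tj <- integrate_model("coupled", mepd = ps, kndy = kndy,
                            coupling = coupling, t_span = c(0, t_end))
      attr(poincare_section(tj), "diameter")
    }
    tr_point$diagnostics <- list(
      below = dia(hb$value - offset),
      above = dia(hb$value + offset),
      offset = offset)
  }
  tr_point
}
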