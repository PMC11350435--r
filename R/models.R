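#' Sigmoid stimulus-response function
#'
#' The Wilson-Cowan firing-rate response
#' \deqn{\phi(a, F, \theta) = \frac{1}{1 + e^{-a(F-\theta)}} -
#'       \frac{1}{1 + e^{a\theta}},}
#' shifted so that an unstimulated population is silent: `phi(a, 0, theta)`
#' is exactly 0.  Strictly increasing in `F`, bounded above by
#' `1 - 1/(1 + exp(a * theta))`.  Arguments of the exponential are clipped at
#' +/-500 to avoid overflow (no effect in the operating range).
#'
#' @param a maximum slope (> 0).
#' @param F input (finite; vectorized).
#' @param theta half-maximum threshold (finite).
#' @return Response value(s), same length as `F`.
#' @examples
#' phi(2, 0, 3.7)    # exactly 0
#' phi(2, 3.7, 3.7)  # 0.5 - 1/(1 + exp(7.4))
#' @export
phi <- function(a, F, theta) {
  if (!all(is.finite(a)) || !all(is.finite(F)) || !all(is.finite(theta)))
    stop("phi: non-finite input", call. = FALSE)
  if (any(a <= 0)) stop("phi: slope a must be positive", call. = FALSE)
  clip <- function(x) pmin(pmax(x, -500), 500)
  1 / (1 + exp(clip(-a * (F - theta)))) - 1 / (1 + exp(clip(a * theta)))
}

#' @rdname phi
#' @details `phi_slope()` is the derivative of `phi` with respect to `F`.
#' @export
phi_slope <- function(a, F, theta) {
  clip <- function(x) pmin(pmax(x, -500), 500)
  s <- 1 / (1 + exp(clip(-a * (F - theta))))
  a * s * (1 - s)
}

#' Synaptic inputs to the MePD populations
#'
#' The linear excitatory/inhibitory input sums
#' \deqn{F_l = (1-\beta_2) c_{ll} G_l - (1-\beta_1) c_{il} G_i + \alpha K_p}
#' \deqn{F_i = (1-\beta_2) c_{li} G_l + (1-\alpha) K_p}
#' \deqn{F_e = (1-\beta_2) c_{le} G_l - (1-\beta_1) c_{ie} G_i}
#'
#' @param state numeric length-3 vector `(Gl, Gi, Ge)`.
#' @param p an [mepd_params()] object.
#' @return Named numeric vector `(Fl, Fi, Fe)`.
#' @export
mepd_inputs <- function(state, p) {
  stopifnot(length(state) == 3, all(is.finite(state)))
  c(Fl = (1 - p$beta2) * p$c_ll * state[[1]] -
         (1 - p$beta1) * p$c_il * state[[2]] + p$alpha * p$Kp,
    Fi = (1 - p$beta2) * p$c_li * state[[1]] + (1 - p$alpha) * p$Kp,
    Fe = (1 - p$beta2) * p$c_le * state[[1]] -
         (1 - p$beta1) * p$c_ie * state[[2]])
}

#' MePD right-hand side
#'
#' Time derivative of the MePD activities.  Each component has the form
#' `delta * (-G + (1 - G) * phi(a, F, theta))`; the refractory factor
#' `(1 - G)` keeps activities below 1.  The system is autonomous.  With
#' `time_scaled = FALSE` the arbitrary-time form (without the `delta` factor)
#' is returned; all integration and continuation in the package use the
#' minutes scale (`time_scaled = TRUE`).
#'
#' @param state numeric length-3 `(Gl, Gi, Ge)`.
#' @param p an [mepd_params()] object.
#' @param time_scaled logical; multiply by `delta` (minutes scale)?
#' @return Numeric length-3 derivative.
#' @export
mepd_rhs <- function(state, p, time_scaled = TRUE) {
  stopifnot(length(state) == 3, all(is.finite(state)))
  d <- mepd_rhs_cpp(as.numeric(state), as_mepd_vec(p))
  if (!time_scaled) d <- d / p$delta
  d
}

#' Analytic Jacobian of the MePD right-hand side
#'
#' @inheritParams mepd_rhs
#' @return 3 x 3 matrix of partial derivatives (minutes scale unless
#'   `time_scaled = FALSE`).
#' @export
mepd_jacobian <- function(state, p, time_scaled = TRUE) {
  stopifnot(length(state) == 3, all(is.finite(state)))
  J <- mepd_jac_cpp(as.numeric(state), as_mepd_vec(p))
  if (!time_scaled) J <- J / p$delta
  dimnames(J) <- list(c("Gl", "Gi", "Ge"), c("Gl", "Gi", "Ge"))
  J
}

#' KNDy network right-hand side
#'
#' Time derivative of `(D, N, v)`: dynorphin and NKB production saturate in
#' the firing rate `v` (Hill exponent 2), dynorphin suppresses NKB
#' production, and the firing rate responds sigmoidally to the synaptic input
#' \deqn{I = I_0 + p_v \frac{N^2}{N^2 + K_N^2} v + j_l G_l - j_e G_e,}
#' where `(Gl, Ge)` is the external MePD drive (pass `ext = c(0, 0)` for the
#' isolated KNDy network).
#'
#' @param state numeric length-3 `(D, N, v)`.
#' @param p a [kndy_params()] object.
#' @param ext external MePD activities `(Gl, Ge)`.
#' @param coupling a [coupling_params()] object (weights `j_l`, `j_e`).
#' @return Numeric length-3 derivative (per minute).
#' @export
kndy_rhs <- function(state, p, ext = c(0, 0),
                     coupling = coupling_params("baseline")) {
  stopifnot(length(state) == 3, all(is.finite(state)),
            length(ext) == 2, all(is.finite(ext)))
  kndy_rhs_cpp(as.numeric(state), as_kndy_vec(p), as.numeric(ext),
               as_coupling_vec(coupling))
}

#' Coupled MePD -> KNDy right-hand side
#'
#' Six-dimensional system `(Gl, Gi, Ge, D, N, v)` on the minutes time grid.
#' The first three components are the MePD derivatives; the last three are
#' the KNDy derivatives driven by the instantaneous `(Gl, Ge)`.  Coupling is
#' strictly one-way: the KNDy state never feeds back into the MePD circuit.
#'
#' @param state numeric length-6 `(Gl, Gi, Ge, D, N, v)`.
#' @param mepd an [mepd_params()] object.
#' @param kndy a [kndy_params()] object.
#' @param coupling a [coupling_params()] object.
#' @return Numeric length-6 derivative.
#' @export
coupled_rhs <- function(state, mepd, kndy,
                        coupling = coupling_params("baseline")) {
  stopifnot(length(state) == 6, all(is.finite(state)))
  c(mepd_rhs(state[1:3], mepd),
    kndy_rhs(state[4:6], kndy, ext = c(state[[1]], state[[3]]), coupling))
}
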