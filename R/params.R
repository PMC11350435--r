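#' MePD circuit parameters
#'
#' Construct the parameter set of the three-population Wilson-Cowan model of
#' the MePD GABA-glutamate circuit: a glutamatergic population (`Gl`), GABA
#' interneurons (`Gi`) and GABA efferent neurons (`Ge`).  Defaults are the
#' published reference values; `Kp` (kisspeptin drive) defaults to 0 and
#' `beta1`/`beta2` (fractional receptor antagonism) to 0.
#'
#' @param delta temporal scaling factor relating arbitrary Wilson-Cowan time
#'   to minutes (1/min).
#' @param alpha relative glutamatergic excitation ratio in \[0, 1\]: the
#'   fraction of the kisspeptin drive `Kp` delivered to the glutamatergic
#'   population (the remainder goes to the GABA interneurons).
#' @param Kp kisspeptin excitatory input (a.u., >= 0).
#' @param c_ll,c_li,c_il,c_le,c_ie interaction strengths (a.u.):
#'   glutamatergic self-excitation, Glu -> GABAint, GABAint -> Glu,
#'   Glu -> GABAeff and GABAint -> GABAeff respectively.
#' @param a_l,a_i,a_e maximum slopes of the sigmoid response of each
#'   population.
#' @param theta_l,theta_i,theta_e half-maximum firing thresholds.
#' @param beta1 fractional suppression of GABAergic interactions in \[0, 1\]
#'   (GABA receptor antagonism; 1 removes all GABAergic coupling).
#' @param beta2 fractional suppression of glutamatergic interactions in
#'   \[0, 1\] (glutamate receptor antagonism).
#' @return An object of class `mepd_params` (a named list).
#' @examples
#' p <- mepd_params(Kp = 2.3)
#' p$alpha
#' @export
mepd_params <- function(delta = 3, alpha = 0.9, Kp = 0,
                        c_ll = 18, c_li = 16, c_il = 35, c_le = 40, c_ie = 25,
                        a_l = 1.3, a_i = 2, a_e = 2,
                        theta_l = 4, theta_i = 3.7, theta_e = 3.7,
                        beta1 = 0, beta2 = 0) {
  p <- list(delta = delta, alpha = alpha, Kp = Kp,
            c_ll = c_ll, c_li = c_li, c_il = c_il, c_le = c_le, c_ie = c_ie,
            a_l = a_l, a_i = a_i, a_e = a_e,
            theta_l = theta_l, theta_i = theta_i, theta_e = theta_e,
            beta1 = beta1, beta2 = beta2)
  validate_mepd_params(p)
  structure(p, class = "mepd_params")
}

validate_mepd_params <- function(p) {
  num1 <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("MePD parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    v
  }
  for (nm in names(p)) num1(nm)
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (p$beta1 < 0 || p$beta1 > 1) stop("beta1 must lie in [0, 1]", call. = FALSE)
  if (p$beta2 < 0 || p$beta2 > 1) stop("beta2 must lie in [0, 1]", call. = FALSE)
  if (p$Kp < 0) stop("Kp must be non-negative", call. = FALSE)
  if (p$delta <= 0) stop("delta must be positive", call. = FALSE)
  for (nm in c("a_l", "a_i", "a_e", "theta_l", "theta_i", "theta_e"))
    if (p[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  invisible(p)
}

#' KNDy network parameters
#'
#' Parameters of the coarse-grained arcuate KNDy population model (the GnRH
#' pulse generator): dynorphin concentration `D` (nM), neurokinin B
#' concentration `N` (nM) and mean firing rate `v` (spikes/min).  Defaults are
#' the published reference values.
#'
#' @param d_D,d_N,d_v linear decay rates of D, N and v (1/min).
#' @param k_D,k_N dynorphin / NKB secretion strengths (nM/min).
#' @param p_v effective strength of NKB-mediated synaptic self-excitation.
#' @param v0 maximum rate of firing-rate increase (spikes/min^2).
#' @param K_D dynorphin concentration of half-maximal inhibition (nM).
#' @param K_N NKB concentration of half-maximal excitation (nM).
#' @param K_v1,K_v2 firing rates of half-maximal dynorphin / NKB secretion
#'   (spikes/min).
#' @param k sigmoid steepness of the firing-rate response.
#' @param m synaptic input of half-maximal firing-rate increase.
#' @param I0 basal synaptic input.
#' @return An object of class `kndy_params`.
#' @examples
#' q <- kndy_params()
#' q$v0
#' @export
kndy_params <- function(d_D = 0.2, d_N = 1, d_v = 10, k_D = 4, k_N = 40,
                        p_v = 0.006, v0 = 25000, K_D = 0.3, K_N = 4,
                        K_v1 = 600, K_v2 = 200, k = 10, m = 0.5, I0 = 0.14) {
  p <- list(d_D = d_D, d_N = d_N, d_v = d_v, k_D = k_D, k_N = k_N,
            p_v = p_v, v0 = v0, K_D = K_D, K_N = K_N,
            K_v1 = K_v1, K_v2 = K_v2, k = k, m = m, I0 = I0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("KNDy parameter '", nm, "' must be a positive finite scalar",
           call. = FALSE)
  }
  structure(p, class = "kndy_params")
}

#' MePD -> KNDy projection weights
#'
#' Pre-synaptic firing-rate conversion weights turning the MePD glutamatergic
#' (`Gl`) and GABA-efferent (`Ge`) activities into synaptic input to the KNDy
#' network (`I = ... + j_l * Gl - j_e * Ge`).  Named presets follow the
#' in-silico experiments: `"baseline"` (1, 1) for kisspeptin stimulation and
#' antagonism, `"glut_stim"` (1.5, 0.5) for glutamatergic-terminal
#' stimulation, `"gaba_stim"` (0.5, 1.5) for GABAergic-terminal stimulation.
#'
#' @param preset one of `"baseline"`, `"glut_stim"`, `"gaba_stim"`; ignored
#'   when both `j_l` and `j_e` are given.
#' @param j_l,j_e non-negative weights (Hz per activity unit), overriding the
#'   preset.
#' @return An object of class `coupling_params`.
#' @examples
#' coupling_params("glut_stim")
#' @export
coupling_params <- function(preset = c("baseline", "glut_stim", "gaba_stim"),
                            j_l = NULL, j_e = NULL) {
  preset <- match.arg(preset)
  w <- switch(preset,
              baseline  = c(1, 1),
              glut_stim = c(1.5, 0.5),
              gaba_stim = c(0.5, 1.5))
  if (!is.null(j_l)) w[1] <- j_l
  if (!is.null(j_e)) w[2] <- j_e
  if (any(!is.finite(w)) || any(w < 0))
    stop("j_l and j_e must be finite and non-negative", call. = FALSE)
  structure(list(j_l = w[1], j_e = w[2], preset = preset),
            class = "coupling_params")
}

# fixed vector layouts shared with the compiled code
mepd_par_names <- c("delta", "alpha", "Kp", "c_ll", "c_li", "c_il", "c_le",
                    "c_ie", "a_l", "a_i", "a_e", "theta_l", "theta_i",
                    "theta_e", "beta1", "beta2")
kndy_par_names <- c("d_D", "d_N", "d_v", "k_D", "k_N", "p_v", "v0", "K_D",
                    "K_N", "K_v1", "K_v2", "k", "m", "I0")

as_mepd_vec <- function(p) {
  stopifnot(inherits(p, "mepd_params"))
  unlist(p[mepd_par_names], use.names = FALSE)
}

as_kndy_vec <- function(p) {
  stopifnot(inherits(p, "kndy_params"))
  unlist(p[kndy_par_names], use.names = FALSE)
}

as_coupling_vec <- function(p) {
  stopifnot(inherits(p, "coupling_params"))
  c(p$j_l, p$j_e)
}

#' Modify a parameter set
#'
#' Returns a copy of a parameter object with the named entries replaced,
#' re-running validation.
#'
#' @param p an object from [mepd_params()], [kndy_params()] or
#'   [coupling_params()].
#' @param ... name = value replacements; unknown names are an error.
#' @return The modified object, same class as `p`.
#' @examples
#' set_params(mepd_params(), Kp = 2.3, beta1 = 0.25)
#' @export
set_params <- function(p, ...) {
  repl <- list(...)
  if (length(repl) == 0L) return(p)
  known <- setdiff(names(p), "preset")
  bad <- setdiff(names(repl), known)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  q <- unclass(p)
  q[names(repl)] <- repl
  if (inherits(p, "mepd_params")) return(do.call(mepd_params, q))
  if (inherits(p, "kndy_params")) return(do.call(kndy_params, q))
  if (inherits(p, "coupling_params"))
    return(coupling_params(p$preset, j_l = q$j_l, j_e = q$j_e))
  stop("unsupported parameter class")
}

#' Read / write parameter sets as flat JSON
#'
#' Parameter sets serialize to a flat JSON object keyed by the ASCII symbol
#' names used throughout the package (`delta`, `alpha`, `Kp`, ..., `d_D`,
#' ..., `j_l`, `j_e`).  `read_params()` dispatches on which keys are present.
#'
#' @param p a parameter object.
#' @param path file path.
#' @return `read_params()` returns the reconstructed parameter object.
#' @export
write_params <- function(p, path) {
  x <- unclass(p)
  x$preset <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- names(x)
  if (all(nm %in% mepd_par_names)) return(do.call(mepd_params, x))
  if (all(nm %in% kndy_par_names)) return(do.call(kndy_params, x))
  if (all(nm %in% c("j_l", "j_e")))
    return(coupling_params(j_l = x$j_l, j_e = x$j_e))
  stop("unrecognized parameter keys: ", paste(nm, collapse = ", "),
       call. = FALSE)
}

#' @export
print.mepd_params <- function(x, ...) {
  cat("MePD circuit parameters\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.kndy_params <- function(x, ...) {
  cat("KNDy network parameters\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.coupling_params <- function(x, ...) {
  cat(sprintf("MePD->KNDy projection weights (preset '%s'): j_l = %g, j_e = %g\n",
              x$preset, x$j_l, x$j_e))
  invisible(x)
}
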