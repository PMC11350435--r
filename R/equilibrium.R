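#' Find an MePD equilibrium by damped Newton iteration
#'
#' Newton's method with the analytic Jacobian and simple step-halving line
#' search, converging to `||rhs|| < tol`.
#'
#' @param p an [mepd_params()] object.
#' @param guess starting state (length 3).
#' @param tol residual tolerance (max-norm of the minutes-scale RHS).
#' @param max_iter maximum Newton iterations.
#' @return The equilibrium state (named numeric length 3) with attribute
#'   `residual`.
#' @examples
#' find_equilibrium(mepd_params(Kp = 0), c(0, 0, 0))
#' @export
find_equilibrium <- function(p, guess, tol = 1e-12, max_iter = 50) {
  x <- as.numeric(guess)
  r <- mepd_rhs(x, p)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    dx <- tryCatch(solve(mepd_jacobian(x, p), -r),
                   error = function(e) NULL)
    if (is.null(dx)) stop("singular Jacobian in Newton iteration", call. = FALSE)
    lam <- 1
    repeat {
      xn <- x + lam * dx
      rn <- mepd_rhs(xn, p)
      if (sum(rn^2) < sum(r^2) || lam < 1 / 64) break
      lam <- lam / 2
    }
    x <- xn
    r <- rn
  }
  if (max(abs(r)) >= tol)
    stop(sprintf("Newton did not converge (residual %.3e after %d iterations)",
                 max(abs(r)), max_iter), call. = FALSE)
  names(x) <- c("Gl", "Gi", "Ge")
  attr(x, "residual") <- max(abs(r))
  x
}

# coefficients of det(lambda I - J) = lambda^3 + c2 lambda^2 + c1 lambda + c0.
# Routh-Hurwitz test functions: SN at c0 = 0; Hopf at c1*c2 - c0 = 0 with
# c1 > 0 (eigenvalues +/- i*sqrt(c1)); both zero at a Bogdanov-Takens point.
char_coeffs <- function(J) {
  tr <- sum(diag(J))
  c(c0 = -det(J),
    c1 = (tr^2 - sum(diag(J %*% J))) / 2,
    c2 = -tr)
}

# replace one named scalar parameter, returning a validated object
set_param1 <- function(p, param, value) {
  args <- stats::setNames(list(value), param)
  do.call(set_params, c(list(p), args))
}

# unvalidated variant for continuation internals: predictor steps and
# finite-difference probes may transiently leave the admissible box
# (e.g. Kp a hair below 0); the vector field extends smoothly there
set_param1_raw <- function(p, param, value) {
  if (!param %in% names(p)) stop("unknown parameter: ", param, call. = FALSE)
  p[[param]] <- value
  p
}

# residual and Jacobian of the extended system F(x, s) = rhs(x; param = s),
# with dF/ds by central finite differences (generic in the parameter)
ext_system <- function(p, param) {
  list(
    F = function(u) mepd_rhs(u[1:3], set_param1_raw(p, param, u[4])),
    J = function(u) {
      ps <- set_param1_raw(p, param, u[4])
      h <- 1e-6 * max(1, abs(u[4]))
      dFds <- (mepd_rhs(u[1:3], set_param1_raw(p, param, u[4] + h)) -
               mepd_rhs(u[1:3], set_param1_raw(p, param, u[4] - h))) / (2 * h)
      cbind(mepd_jacobian(u[1:3], ps), dFds)
    })
}

# unit-norm tangent of an underdetermined system (n x (n+1) Jacobian),
# oriented along `prefer` when given
null_tangent <- function(A, prefer = NULL) {
  n <- nrow(A)
  v <- qr.solve(rbind(A, if (is.null(prefer)) c(rep(0, n), 1) else prefer),
                c(rep(0, n), 1))
  v <- v / sqrt(sum(v^2))
  if (!is.null(prefer) && sum(v * prefer) < 0) v <- -v
  v
}

# one pseudo-arclength predictor-corrector step; returns corrected u or NULL
pa_step <- function(Ffun, Jfun, u, tvec, h, tol = 1e-11, max_iter = 12) {
  up <- u + h * tvec
  for (it in seq_len(max_iter)) {
    r <- c(Ffun(up), sum((up - u) * tvec) - h)
    if (max(abs(r)) < tol) return(up)
    A <- rbind(Jfun(up), tvec)
    d <- tryCatch(solve(A, -r), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    up <- up + d
  }
  NULL
}

#' Continue an MePD equilibrium branch in one parameter
#'
#' Pseudo-arclength predictor-corrector continuation of the equilibrium
#' equations in one free parameter.  Folds are traversed; the step halves on
#' corrector failure and grows by a factor 1.3 after three consecutive
#' successes, within `c(h_min, h_max)`.  Eigenvalues of the analytic
#' Jacobian and the Routh-Hurwitz test functions are recorded at every
#' accepted point.
#'
#' @param p an [mepd_params()] object holding the fixed parameters.
#' @param param name of the free parameter (e.g. `"Kp"`, `"c_il"`).
#' @param range `c(lo, hi)`; continuation starts from an equilibrium at
#'   `range[1]` and stops when the parameter leaves the interval.
#' @param guess starting state for the initial equilibrium solve.
#' @param h0,h_min,h_max initial / minimum / maximum arclength step.
#' @param max_points safety cap on branch length.
#' @return An object of class `mk_branch`: list with `points` (data frame:
#'   parameter, state, eigenvalue real/imag parts, test functions `det_test`
#'   (= -c0, zero at a fold) and `hopf_test` (= c1*c2 - c0), `c1`, `stable`,
#'   `arclength`), plus `param`, `p`, and `status` (`"ok"` or
#'   `"truncated"`).
#' @examples
#' br <- continue_equilibria(mepd_params(), "Kp", c(0, 3), guess = c(0, 0, 0))
#' detect_codim1(br)
#' @export
continue_equilibria <- function(p, param, range, guess = c(0, 0, 0),
                                h0 = 0.01, h_min = 1e-5, h_max = 0.05,
                                max_points = 20000) {
  stopifnot(length(range) == 2, range[2] > range[1])
  p0 <- set_param1(p, param, range[1])
  x0 <- tryCatch(find_equilibrium(p0, guess), error = function(e) NULL)
  if (is.null(x0)) {
    # Newton can stall on sigmoid plateaus; relax toward an attractor first
    tr <- integrate_model("mepd", mepd = p0, init = as.numeric(guess),
                          t_span = c(0, 60), dt_out = 0.05)
    x0 <- find_equilibrium(p0, tr$states[nrow(tr$states), ])
  }
  sys <- ext_system(p, param)
  u <- c(as.numeric(x0), range[1])
  tvec <- null_tangent(sys$J(u))
  if (tvec[4] < 0) tvec <- -tvec  # march toward increasing parameter
  h <- h0
  ok_run <- 0L
  status <- "ok"
  rows <- vector("list", 0)
  add_row <- function(u, s) {
    ps <- set_param1_raw(p, param, u[4])
    J <- mepd_jacobian(u[1:3], ps)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(Re(ev), decreasing = TRUE)]
    cc <- char_coeffs(J)
    data.frame(param = u[4], Gl = u[1], Gi = u[2], Ge = u[3],
               re1 = Re(ev[1]), im1 = Im(ev[1]), re2 = Re(ev[2]),
               im2 = Im(ev[2]), re3 = Re(ev[3]), im3 = Im(ev[3]),
               det_test = -cc[["c0"]], hopf_test = cc[["c1"]] * cc[["c2"]] - cc[["c0"]],
               c1 = cc[["c1"]], stable = all(Re(ev) < 0), arclength = s)
  }
  s <- 0
  rows[[1]] <- add_row(u, s)
  n <- 1L
  while (n < max_points) {
    un <- pa_step(sys$F, sys$J, u, tvec, h)
    if (is.null(un)) {
      h <- h / 2
      ok_run <- 0L
      if (h < h_min) { status <- "truncated"; warning("continuation step underflow; branch truncated"); break }
      next
    }
    s <- s + h
    tn <- null_tangent(sys$J(un), prefer = tvec)
    u <- un
    tvec <- tn
    n <- n + 1L
    rows[[n]] <- add_row(u, s)
    if (u[4] > range[2] || u[4] < range[1]) break
    ok_run <- ok_run + 1L
    if (ok_run >= 3L) { h <- min(h * 1.3, h_max); ok_run <- 0L }
  }
  structure(list(points = do.call(rbind, rows), param = param, p = p,
                 range = range, status = status),
            class = "mk_branch")
}

#' @export
print.mk_branch <- function(x, ...) {
  pr <- range(x$points$param)
  cat(sprintf("<mk_branch> %d equilibria along '%s' in [%.4g, %.4g] (%s)\n",
              nrow(x$points), x$param, pr[1], pr[2], x$status))
  invisible(x)
}

# solve for the point at fraction `th` of the secant between branch rows
# u1, u2 (pseudo-arclength corrector with frozen secant direction)
segment_point <- function(sys, u1, u2, th) {
  d <- u2 - u1
  h <- sqrt(sum(d^2))
  tv <- d / h
  pa_step(sys$F, sys$J, u1, tv, th * h)
}

#' Detect Hopf and saddle-node points along an equilibrium branch
#'
#' Scans consecutive branch points for sign changes of the Routh-Hurwitz
#' test functions (fold: `det J = 0`; Hopf: `c1 c2 - c0 = 0` with `c1 > 0`,
#' where the `c`s are characteristic-polynomial coefficients), then refines
#' each crossing by bisection along the branch segment to `|test| < 1e-10`,
#' which places the critical eigenvalue real part below 1e-8.
#'
#' @param branch an `mk_branch` from [continue_equilibria()].
#' @return List of `mk_bifpoint` objects (fields: `kind` (`"HB"` or
#'   `"SN"`), `param`, `value`, `state`, `eigenvalues`, and for HB `omega`,
#'   the Hopf angular frequency in rad/min).
#' @export
detect_codim1 <- function(branch) {
  stopifnot(inherits(branch, "mk_branch"))
  pts <- branch$points
  if (nrow(pts) < 2L) return(list())
  sys <- ext_system(branch$p, branch$param)
  out <- list()
  tests <- list(HB = "hopf_test", SN = "det_test")
  for (kind in names(tests)) {
    tf <- pts[[tests[[kind]]]]
    idx <- which(tf[-1] * tf[-length(tf)] < 0)
    if (kind == "HB") idx <- idx[pts$c1[idx] > 0 & pts$c1[idx + 1] > 0]
    for (i in idx) {
      u1 <- unlist(pts[i, c("Gl", "Gi", "Ge", "param")], use.names = FALSE)
      u2 <- unlist(pts[i + 1, c("Gl", "Gi", "Ge", "param")], use.names = FALSE)
      f1 <- tf[i]
      tfun <- function(u) {
        cc <- char_coeffs(mepd_jacobian(u[1:3],
                                        set_param1_raw(branch$p, branch$param, u[4])))
        if (kind == "SN") -cc[["c0"]] else cc[["c1"]] * cc[["c2"]] - cc[["c0"]]
      }
      lo <- 0; hi <- 1; um <- NULL
      for (bis in 1:60) {
        mid <- (lo + hi) / 2
        uc <- segment_point(sys, u1, u2, mid)
        if (is.null(uc)) break
        fm <- tfun(uc)
        um <- uc
        if (abs(fm) < 1e-10) break
        if (sign(fm) == sign(f1)) lo <- mid else hi <- mid
      }
      if (is.null(um)) next
      ps <- set_param1_raw(branch$p, branch$param, um[4])
      ev <- eigen(mepd_jacobian(um[1:3], ps), only.values = TRUE)$values
      bp <- list(kind = kind, param = branch$param, value = um[4],
                 state = stats::setNames(um[1:3], c("Gl", "Gi", "Ge")),
                 eigenvalues = ev)
      if (kind == "HB") {
        cc <- char_coeffs(mepd_jacobian(um[1:3], ps))
        bp$omega <- sqrt(max(cc[["c1"]], 0))
      }
      out[[length(out) + 1L]] <- structure(bp, class = "mk_bifpoint")
    }
  }
  ord <- order(vapply(out, `[[`, numeric(1), "value"))
  out[ord]
}

#' @export
print.mk_bifpoint <- function(x, ...) {
  loc <- if (!is.null(x$param2))
    sprintf("(%s, %s) = (%.6g, %.6g)", x$param, x$param2, x$value, x$value2)
  else sprintf("%s = %.6g", x$param, x$value)
  cat(sprintf("<mk_bifpoint> %s at %s\n", x$kind, loc))
  invisible(x)
}
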