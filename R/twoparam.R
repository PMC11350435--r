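# Two-parameter continuation of codimension-one bifurcation loci and
# detection of codimension-two points (Bogdanov-Takens, cusp).

# extended defining system for a codim-1 locus: u = (Gl, Gi, Ge, p1, p2),
# F(u) = (rhs(x; p), g(x; p)) with g the Routh-Hurwitz test function of the
# locus kind ("SN": -c0 = det J; "HB": c1*c2 - c0).
locus_system <- function(p, pair, kind) {
  gfun <- function(u) {
    ps <- set_param1_raw(set_param1_raw(p, pair[1], u[4]), pair[2], u[5])
    cc <- char_coeffs(mepd_jacobian(u[1:3], ps))
    if (kind == "SN") -cc[["c0"]] else cc[["c1"]] * cc[["c2"]] - cc[["c0"]]
  }
  Ffun <- function(u) {
    ps <- set_param1_raw(set_param1_raw(p, pair[1], u[4]), pair[2], u[5])
    c(mepd_rhs(u[1:3], ps), gfun(u))
  }
  Jfun <- function(u) {
    ps <- set_param1_raw(set_param1_raw(p, pair[1], u[4]), pair[2], u[5])
    Jx <- mepd_jacobian(u[1:3], ps)
    J <- matrix(0, 4, 5)
    J[1:3, 1:3] <- Jx
    for (k in 4:5) {
      h <- 1e-6 * max(1, abs(u[k]))
      up <- u; up[k] <- u[k] + h
      um <- u; um[k] <- u[k] - h
      J[1:3, k] <- (Ffun(up)[1:3] - Ffun(um)[1:3]) / (2 * h)
    }
    for (k in 1:5) {
      h <- 1e-6 * max(1, abs(u[k]))
      up <- u; up[k] <- u[k] + h
      um <- u; um[k] <- u[k] - h
      J[4, k] <- (gfun(up) - gfun(um)) / (2 * h)
    }
    J
  }
  list(F = Ffun, J = Jfun, g = gfun)
}

# characteristic-polynomial c1 (= omega^2 on the Hopf side) at a locus point
locus_c1 <- function(p, pair, u) {
  ps <- set_param1_raw(set_param1_raw(p, pair[1], u[4]), pair[2], u[5])
  char_coeffs(mepd_jacobian(u[1:3], ps))[["c1"]]
}

# quadratic fold coefficient b = <w, B(q, q)> at a saddle-node locus point;
# changes sign at a cusp
fold_coefficient <- function(p, pair, u) {
  ps <- set_param1_raw(set_param1_raw(p, pair[1], u[4]), pair[2], u[5])
  J <- mepd_jacobian(u[1:3], ps)
  sv <- svd(J)
  q <- sv$v[, 3]
  w <- sv$u[, 3]
  # fix the arbitrary SVD sign so b varies continuously along a curve
  i <- which.max(abs(w))
  if (w[i] < 0) w <- -w
  i <- which.max(abs(q))
  if (q[i] < 0) q <- -q
  eps <- 1e-3
  Bqq <- (mepd_rhs(u[1:3] + eps * q, ps) - 2 * mepd_rhs(u[1:3], ps) +
          mepd_rhs(u[1:3] - eps * q, ps)) / eps^2
  sum(w * Bqq)
}

#' Continue a Hopf or saddle-node locus in two parameters
#'
#' Pseudo-arclength continuation of the augmented defining system
#' (equilibrium equations plus the codimension-one Routh-Hurwitz test
#' function) in a two-parameter box, marching in both directions from the
#' starting point.  Note the Hopf test function `c1 c2 - c0 = 0` also
#' vanishes on neutral-saddle sets (`c1 < 0`); points carry `c1` so that
#' genuine Hopf segments (`c1 > 0`) can be distinguished, and the
#' `c1` sign change is how [detect_codim2()] finds Bogdanov-Takens points.
#'
#' @param point an `mk_bifpoint` (kind `"HB"` or `"SN"`) located at
#'   parameter `pair[1]` (e.g. from [detect_codim1()] on a branch in
#'   `pair[1]` with `pair[2]` fixed at the value in `p`).
#' @param p the [mepd_params()] object of fixed parameters.
#' @param pair character vector of the two free parameter names; the first
#'   must be the parameter of `point`.
#' @param box numeric `c(p1_min, p1_max, p2_min, p2_max)` continuation box.
#' @param h0,h_min,h_max arclength step control.
#' @param max_points cap per marching direction.
#' @return An object of class `mk_twoparam`: `points` data frame (`p1`,
#'   `p2`, state, test-function value `g`, `c1`, fold coefficient `b` for SN
#'   curves), `kind`, `pair`, `status`.
#' @export
continue_codim1_locus <- function(point, p, pair, box, h0 = 0.01,
                                  h_min = 1e-7, h_max = 0.05,
                                  max_points = 5000) {
  stopifnot(inherits(point, "mk_bifpoint"), point$kind %in% c("HB", "SN"),
            length(pair) == 2, length(box) == 4)
  if (point$param != pair[1])
    stop("point was detected in parameter '", point$param,
         "', not '", pair[1], "'", call. = FALSE)
  kind <- point$kind
  sys <- locus_system(p, pair, kind)
  u0 <- c(as.numeric(point$state), point$value, p[[pair[2]]])
  # polish the starting point with the second parameter frozen
  u0 <- polish_locus_point(sys, u0)
  if (is.null(u0)) stop("could not converge the starting locus point",
                        call. = FALSE)
  in_box <- function(u) u[4] >= box[1] - 1e-9 && u[4] <= box[2] + 1e-9 &&
    u[5] >= box[3] - 1e-9 && u[5] <= box[4] + 1e-9
  row_of <- function(u) {
    data.frame(p1 = u[4], p2 = u[5], Gl = u[1], Gi = u[2], Ge = u[3],
               g = sys$g(u), c1 = locus_c1(p, pair, u),
               b = if (kind == "SN") fold_coefficient(p, pair, u) else NA_real_)
  }
  march <- function(dirsign) {
    rows <- list(row_of(u0))
    tvec <- tryCatch(null_tangent(sys$J(u0), prefer = c(0, 0, 0, 0, dirsign)),
                     error = function(e) NULL)
    if (is.null(tvec)) return(list(rows = rows, status = "singular_start"))
    u <- u0
    h <- h0
    status <- "box"
    while (length(rows) < max_points) {
      un <- pa_step(sys$F, sys$J, u, tvec, h, tol = 1e-10)
      if (is.null(un)) {
        h <- h / 2
        if (h < h_min) { status <- "truncated"; break }
        next
      }
      tn <- tryCatch(null_tangent(sys$J(un), prefer = tvec),
                     error = function(e) NULL)
      if (is.null(tn)) { status <- "truncated"; break }
      u <- un
      tvec <- tn
      rows[[length(rows) + 1L]] <- row_of(u)
      if (!in_box(u)) { status <- "box"; break }
      h <- min(h * 1.3, h_max)
    }
    list(rows = rows, status = status)
  }
  fwd <- march(1)
  bwd <- march(-1)
  pts <- rbind(do.call(rbind, rev(bwd$rows[-1])), do.call(rbind, fwd$rows))
  rownames(pts) <- NULL
  status <- if (fwd$status == "truncated" || bwd$status == "truncated")
    "truncated" else "ok"
  if (status == "truncated")
    warning("locus continuation truncated before reaching the box boundary")
  structure(list(points = pts, kind = kind, pair = pair, box = box, p = p,
                 status = status),
            class = "mk_twoparam")
}

# Newton polish of a locus point with p2 frozen (solve rhs + test in
# (x, p1) by bordered iteration)
polish_locus_point <- function(sys, u0, tol = 1e-10, max_iter = 30) {
  u <- u0
  for (it in seq_len(max_iter)) {
    r <- sys$F(u)
    if (max(abs(r)) < tol) return(u)
    J <- sys$J(u)[, 1:4, drop = FALSE]
    d <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    u[1:4] <- u[1:4] + d
  }
  NULL
}

#' @export
print.mk_twoparam <- function(x, ...) {
  cat(sprintf("<mk_twoparam> %s locus: %d points in (%s, %s) box [%g, %g] x [%g, %g] (%s)\n",
              x$kind, nrow(x$points), x$pair[1], x$pair[2], x$box[1],
              x$box[2], x$box[3], x$box[4], x$status))
  invisible(x)
}

#' Detect codimension-two points on two-parameter loci
#'
#' Bogdanov-Takens points are located on Hopf curves where the Hopf
#' frequency vanishes (`c1 = omega^2` changes sign along the curve, the HB
#' curve turning into a neutral-saddle curve); cusps are located on
#' saddle-node curves where the quadratic fold coefficient
#' `b = <w, B(q, q)>` changes sign.  Each crossing is refined by bisection
#' on the curve segment.
#'
#' @param curves a single `mk_twoparam` or a list of them.
#' @return List of `mk_bifpoint` objects with kinds `"BT"` / `"CP"`, fields
#'   `param`, `value`, `param2`, `value2`, `state`, `eigenvalues`.
#' @export
detect_codim2 <- function(curves) {
  if (inherits(curves, "mk_twoparam")) curves <- list(curves)
  out <- list()
  for (cv in curves) {
    pts <- cv$points
    if (nrow(pts) < 2L) next
    sys <- locus_system(cv$p, cv$pair, cv$kind)
    if (cv$kind == "HB") {
      tf <- pts$c1
      kind2 <- "BT"
      tfun <- function(u) locus_c1(cv$p, cv$pair, u)
    } else {
      tf <- pts$b
      kind2 <- "CP"
      tfun <- function(u) fold_coefficient(cv$p, cv$pair, u)
    }
    idx <- which(tf[-1] * tf[-length(tf)] < 0)
    # keep only crossings where the test function is genuinely small:
    # residual sign flips of the (orientation-dependent) fold coefficient
    # jump between large values and are not codim-2 points
    idx <- idx[pmin(abs(tf[idx]), abs(tf[idx + 1])) <
                 0.25 * stats::median(abs(tf), na.rm = TRUE)]
    for (i in idx) {
      u1 <- unlist(pts[i, c("Gl", "Gi", "Ge", "p1", "p2")], use.names = FALSE)
      u2 <- unlist(pts[i + 1, c("Gl", "Gi", "Ge", "p1", "p2")],
                   use.names = FALSE)
      f1 <- tf[i]
      lo <- 0; hi <- 1; um <- NULL
      for (bis in 1:60) {
        mid <- (lo + hi) / 2
        uc <- segment_point(sys, u1, u2, mid)
        if (is.null(uc)) break
        fm <- tfun(uc)
        um <- uc
        if (abs(fm) < 1e-12 || (hi - lo) < 1e-14) break
        if (sign(fm) == sign(f1)) lo <- mid else hi <- mid
      }
      if (is.null(um)) next
      ps <- set_param1_raw(set_param1_raw(cv$p, cv$pair[1], um[4]),
                           cv$pair[2], um[5])
      ev <- eigen(mepd_jacobian(um[1:3], ps), only.values = TRUE)$values
      out[[length(out) + 1L]] <- structure(
        list(kind = kind2, param = cv$pair[1], value = um[4],
             param2 = cv$pair[2], value2 = um[5],
             state = stats::setNames(um[1:3], c("Gl", "Gi", "Ge")),
             eigenvalues = ev),
        class = "mk_bifpoint")
    }
    # the test functions chatter near a genuine codim-2 point; merge
    # detections of the same kind closer than 5% of the curve span
    span <- c(diff(range(pts$p1)), diff(range(pts$p2)))
    tol <- 0.05 * pmax(span, 1e-8)
    keep <- list()
    for (b in out) {
      dup <- any(vapply(keep, function(k)
        k$kind == b$kind && abs(k$value - b$value) < tol[1] &&
          abs(k$value2 - b$value2) < tol[2], logical(1)))
      if (!dup) keep[[length(keep) + 1L]] <- b
    }
    out <- keep
  }
  out
}

#' Approximate a homoclinic locus by period blow-up
#'
#' For each value of the second parameter on a grid, the Hopf point in the
#' first parameter is located by equilibrium continuation and the limit
#' cycle born there is continued until its branch terminates on the
#' large-period tail ([continue_limit_cycle()] end status `"period_blowup"`
#' or `"hc_proxy"`); the terminal first-parameter value is recorded as the
#' homoclinic location for that grid line.  This is an approximation whose
#' accuracy is controlled by `hc_factor`; because the period grows
#' exponentially with the parameter distance to the homoclinic, the
#' recorded location is insensitive to the threshold (doubling `hc_factor`
#' moves each point by less than a continuation step).
#'
#' @param p the [mepd_params()] fixed-parameter object.
#' @param pair two free parameter names (`pair[1]` is continued within each
#'   grid line).
#' @param box `c(p1_min, p1_max, p2_min, p2_max)`.
#' @param n_grid number of `pair[2]` grid lines.
#' @param hc_factor period threshold in units of the onset period, passed
#'   to [continue_limit_cycle()].
#' @return An `mk_twoparam` of kind `"HC"`; grid lines where no cycle
#'   reaches the blow-up tail are skipped (recorded in `skipped`).
#' @export
approximate_homoclinic <- function(p, pair, box, n_grid = 7, hc_factor = 10) {
  p2_grid <- seq(box[3], box[4], length.out = n_grid)
  rows <- list()
  skipped <- numeric(0)
  for (p2 in p2_grid) {
    ps <- set_param1_raw(p, pair[2], p2)
    res <- tryCatch({
      br <- continue_equilibria(ps, pair[1], box[1:2],
                                guess = c(0.01, 0.01, 0.01))
      hbs <- Filter(function(b) b$kind == "HB", detect_codim1(br))
      if (!length(hbs)) stop("no HB")
      lc <- continue_limit_cycle(hbs[[1]], ps, range = c(hbs[[1]]$value,
                                                         box[2]),
                                 hc_factor = hc_factor)
      if (!(lc$status %in% c("period_blowup", "hc_proxy"))) stop("no blow-up")
      utils::tail(lc$points, 1)
    }, error = function(e) NULL)
    if (is.null(res)) { skipped <- c(skipped, p2); next }
    rows[[length(rows) + 1L]] <- data.frame(
      p1 = res$param, p2 = p2, Gl = res$Gl_max, Gi = res$Gi_max,
      Ge = res$Ge_max, g = NA_real_, c1 = NA_real_, b = NA_real_,
      period = res$period)
  }
  if (length(skipped))
    message("homoclinic approximation: no blow-up found for ", pair[2],
            " = ", paste(signif(skipped, 4), collapse = ", "))
  structure(list(points = do.call(rbind, rows), kind = "HC", pair = pair,
                 box = box, p = p, status = "ok", skipped = skipped,
                 hc_factor = hc_factor),
            class = "mk_twoparam")
}
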