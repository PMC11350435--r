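# Independent reference implementations used as oracles.  These are written
# from the model equations directly (scalar arithmetic, no shared code with
# the package internals) and must stay independent of the paths they check.

phi_ref <- function(a, F, theta)
  1 / (1 + exp(-a * (F - theta))) - 1 / (1 + exp(a * theta))

mepd_inputs_ref <- function(state, p) {
  Gl <- state[1]; Gi <- state[2]
  c((1 - p$beta2) * p$c_ll * Gl - (1 - p$beta1) * p$c_il * Gi + p$alpha * p$Kp,
    (1 - p$beta2) * p$c_li * Gl + (1 - p$alpha) * p$Kp,
    (1 - p$beta2) * p$c_le * Gl - (1 - p$beta1) * p$c_ie * Gi)
}

mepd_rhs_ref <- function(state, p) {
  Fv <- mepd_inputs_ref(state, p)
  p$delta * c(
    -state[1] + (1 - state[1]) * phi_ref(p$a_l, Fv[1], p$theta_l),
    -state[2] + (1 - state[2]) * phi_ref(p$a_i, Fv[2], p$theta_i),
    -state[3] + (1 - state[3]) * phi_ref(p$a_e, Fv[3], p$theta_e))
}

kndy_rhs_ref <- function(state, q, ext = c(0, 0), jl = 0, je = 0) {
  D <- state[1]; N <- state[2]; v <- state[3]
  I <- q$I0 + q$p_v * N^2 / (N^2 + q$K_N^2) * v + jl * ext[1] - je * ext[2]
  c(q$k_D * v^2 / (v^2 + q$K_v1^2) - q$d_D * D,
    q$k_N * v^2 / (v^2 + q$K_v2^2) * q$K_D^2 / (q$K_D^2 + D^2) - q$d_N * N,
    q$v0 / (1 + exp(q$k * (-I + q$m))) - q$d_v * v)
}

# central-difference Jacobian of a vector field
num_jac <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

# classical fixed-step RK4, independent of the package integrator
rk4_ref <- function(f, x, t1, dt) {
  n <- ceiling(t1 / dt)
  for (i in seq_len(n)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# period via zero crossings of the mean-subtracted signal (independent of
# the peak detector)
period_by_zero_crossings <- function(t, y) {
  z <- y - mean(y)
  up <- which(z[-length(z)] < 0 & z[-1] >= 0)
  if (length(up) < 2) return(NA_real_)
  mean(diff(t[up]))
}
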