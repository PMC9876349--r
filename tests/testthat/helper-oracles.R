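# Independent numerical oracles: plain bisection for the algebraic structure
# constraints, a finite-difference boundary-value solver for the radial
# diffusion profiles, and fixed-step RK4 / deSolve integrators whose
# right-hand sides resolve the constraints with uniroot (independent of the
# package's compiled root-finder and stepper).

bisect <- function(f, lo, hi, tol = 1e-9, maxit = 200) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

oracle_necrotic <- function(R_o, R_c, tol = 1e-9) {
  if (R_o <= R_c) return(0)
  f <- function(Rn) R_o^2 - 3 * Rn^2 + 2 * Rn^3 / R_o - R_c^2
  bisect(f, 0, R_o, tol)
}

oracle_inhibited <- function(R_o, R_n, Rbar, tol = 1e-9) {
  if (R_o <= Rbar) return(0)
  g <- function(Ri) R_o^2 - Ri^2 - 2 * R_n^3 * (1 / Ri - 1 / R_o) - Rbar^2
  if (R_n <= 0) return(sqrt(R_o^2 - Rbar^2))
  if (g(R_n) <= 0) return(if (g(R_n) == 0) R_n else 0)
  bisect(g, R_n, R_o, tol)
}

# finite-difference solution of (1/r^2) d/dr (r^2 dy/dr) = source on
# [max(R_n, eps), R_o], zero flux at the inner boundary, y(R_o) = y_surface;
# Thomas tridiagonal solve
fd_radial_profile <- function(r_eval, R_o, R_n, source, y_surface,
                              n = 10000) {
  r0 <- max(R_n, R_o * 1e-6)
  r <- seq(r0, R_o, length.out = n)
  h <- r[2] - r[1]
  rph <- (r + h / 2)^2
  rmh <- (r - h / 2)^2
  a <- rmh / h^2          # sub-diagonal coefficient
  b <- -(rph + rmh) / h^2 # diagonal
  cc <- rph / h^2         # super-diagonal
  d <- rep(source, n) * r^2
  # inner Neumann via ghost node y_{-1} = y_1
  b[1] <- -(rph[1] + rmh[1]) / h^2
  cc[1] <- (rph[1] + rmh[1]) / h^2
  # outer Dirichlet
  b[n] <- 1; a[n] <- 0; d[n] <- y_surface
  for (i in 2:n) {
    w <- a[i] / b[i - 1]
    b[i] <- b[i] - w * cc[i - 1]
    d[i] <- d[i] - w * d[i - 1]
  }
  y <- numeric(n)
  y[n] <- d[n] / b[n]
  for (i in (n - 1):1) y[i] <- (d[i] - cc[i] * y[i + 1]) / b[i]
  approx(r, y, xout = pmax(r_eval, r0))$y
}

oracle_greenspan_rhs <- function(t, y, parms) {
  R_o <- y[1]
  R_n <- oracle_necrotic(R_o, parms$R_c, tol = 1e-12)
  R_i <- oracle_inhibited(R_o, R_n, parms$Rbar, tol = 1e-12)
  list(parms$s / (3 * R_o^2) * (R_o^3 - max(R_i, R_n)^3) -
         parms$lambda * R_n^3 / R_o^2)
}

oracle_greenspan_lsoda <- function(params, times) {
  sol <- deSolve::lsoda(c(R_o = params$R_o0), times, oracle_greenspan_rhs,
                        parms = params, rtol = 1e-10, atol = 1e-10)
  sol[, "R_o"]
}

rk4_path <- function(rhs, y0, t0, t1, dt) {
  t <- t0
  y <- y0
  while (t < t1 - 1e-12) {
    h <- min(dt, t1 - t)
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2)
    k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# independent R-side RHS of the post-switch deoxygenation system
oracle_deoxy_rhs <- function(t, y, p) {
  R_o <- y[1]; V_n <- max(y[2], 0)
  u <- relax(p$p_inf_pre / p$R_c_n^2, p$p_inf_post / p$R_c_h^2,
             p$tau_alpha, t, p$t_s)
  R_c_t <- sqrt(p$p_inf_post / u)
  Rbar_t <- relax(p$Rbar_n, p$Rbar_h, p$tau_Rbar, t, p$t_s)
  s_t <- relax(p$s_n, p$s_h, p$tau_s, t, p$t_s)
  lam_t <- relax(p$lambda_n, p$lambda_h, p$tau_lambda, t, p$t_s)
  lhat <- min(p$lambda_hat0 * exp((t - p$t_s) / p$tau_lambda_hat), 500)
  R_n <- (V_n / (4 * pi / 3))^(1 / 3)
  R_np <- oracle_necrotic(R_o, R_c_t, tol = 1e-12)
  R_i <- oracle_inhibited(R_o, R_n, Rbar_t, tol = 1e-12)
  dRo <- (s_t / 3 * (R_o^3 - max(R_i, R_n)^3) - lam_t * R_n^3) / R_o^2
  dVn <- 3 * lhat * max(4 * pi / 3 * R_np^3 - V_n, 0) - 3 * lam_t * V_n
  if (y[2] <= 0 && dVn < 0) dVn <- 0
  c(dRo, dVn)
}

# Gaussian-mean toy model: one parameter, predictions constant over days
toy_mean_handle <- function() {
  structure(list(
    simulate = function(theta, days) {
      days <- sort(unique(days))
      cbind(R_o = rep(theta[[1]], length(days)), R_n = NA_real_,
            R_i = NA_real_)
    },
    par_names = "mu", channels = "R_o", model = "toy"),
    class = "model_handle")
}

toy_mean_table <- function(x) {
  data.frame(spheroid_id = seq_along(x), day = 1, condition = "toy",
             R_o_um = x, R_n_um = NA_real_, R_i_um = NA_real_,
             R_p_um = NA_real_)
}
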