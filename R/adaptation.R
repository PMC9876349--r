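#' Exponential relaxation of a model parameter after an environment switch
#'
#' After the ambient oxygen switches at `t_s`, a rate parameter relaxes from
#' its pre-switch endpoint `v_from` to its post-switch endpoint `v_to` with
#' timescale `tau`:
#' `v(t) = v_to + (v_from - v_to) * exp(-(t - t_s)/tau)`.
#' Applied identically to the consumption rate, necrotic loss rate,
#' proliferation rate and inhibition-onset radius.
#'
#' @param v_from value at the switch (continuity: `relax(t_s) = v_from`).
#' @param v_to asymptotic post-switch value.
#' @param tau adaptation timescale \[days\], positive.
#' @param t evaluation time(s) \[days\], `t >= t_s`.
#' @param t_s switch time \[days\].
#' @return Relaxed value(s).
#' @export
relax <- function(v_from, v_to, tau, t, t_s) {
  stopifnot(tau > 0)
  if (any(t < t_s)) stop("relax() is defined for t >= t_s only")
  v_to + (v_from - v_to) * exp(-(t - t_s) / tau)
}

#' Death rate in the newly anoxic shell after deoxygenation
#'
#' Cells caught between the old necrotic boundary and the (larger)
#' post-switch predicted boundary die at a per-volume rate that grows
#' exponentially, `lambda_hat(t) = lambda_hat0 * exp((t - t_s)/tau)`, so the
#' shell term eventually dominates and the core converges onto its
#' quasi-steady prediction.
#'
#' @param t time(s) \[days\], `t >= t_s`.
#' @param lambda_hat0 initial rate \[day^-1\].
#' @param tau_lambda_hat growth timescale \[days\].
#' @param t_s switch time \[days\].
#' @return Rate(s) \[day^-1\].
#' @export
lambda_hat <- function(t, lambda_hat0, tau_lambda_hat, t_s) {
  stopifnot(tau_lambda_hat > 0)
  if (any(t < t_s)) stop("lambda_hat() is defined for t >= t_s only")
  lambda_hat0 * exp((t - t_s) / tau_lambda_hat)
}

#' Quasi-steady (predicted) necrotic radius under a time-varying oxygen field
#'
#' The necrotic radius the oxygen field would dictate if the core tracked it
#' instantaneously: the same structure inversion as [necrotic_radius()],
#' evaluated at the instantaneous critical radius `R_c(t)`. After
#' deoxygenation it jumps above the actual core radius; the dynamic core
#' relaxes toward it.
#'
#' @param R_o outer radius \[um\].
#' @param R_c_t instantaneous critical radius \[um\].
#' @return Predicted necrotic radius \[um\].
#' @export
predicted_necrotic_radius <- function(R_o, R_c_t) {
  necrotic_radius(R_o, R_c_t)
}

#' Necrotic-core volume balance
#'
#' `dV_n/dt = 3 lambda_hat_t (V_n_plus - V_n) - 3 lambda_t V_n` where
#' `V_n_plus = (4 pi / 3) R_n_plus^3` is the quasi-steady core volume. The
#' first term converts living cells in the newly anoxic shell into necrotic
#' material; the second is the usual degradation loss.
#'
#' @param V_n necrotic core volume \[um^3\], non-negative.
#' @param R_n_plus predicted necrotic radius \[um\].
#' @param lambda_t degradation rate \[day^-1\].
#' @param lambda_hat_t shell death rate \[day^-1\].
#' @return `dV_n/dt` \[um^3 day^-1\].
#' @export
necrotic_volume_rhs <- function(V_n, R_n_plus, lambda_t, lambda_hat_t) {
  stopifnot(V_n >= 0)
  3 * lambda_hat_t * (4 * pi / 3 * R_n_plus^3 - V_n) - 3 * lambda_t * V_n
}

check_adaptation_core <- function(p) {
  with(p, stopifnot(R_o0 > 0, R_c_n > 0, R_c_h > 0, tau_alpha > 0,
                    Rbar_n > 0, Rbar_h > 0, tau_Rbar > 0,
                    s_n > 0, s_h > 0, tau_s > 0,
                    lambda_n > 0, lambda_h > 0, tau_lambda > 0,
                    t_s > 0, p_inf_pre > 0, p_inf_post > 0))
}

#' Deoxygenation model parameters
#'
#' The fifteen free parameters of the normoxia-to-hypoxia switching model:
#' the initial outer radius, the normoxia/hypoxia endpoint values and
#' adaptation timescales of the four relaxing quantities (consumption rate,
#' inhibition-onset radius, proliferation rate, necrotic loss rate), and the
#' shell death rate and its timescale. The consumption rate is carried in
#' lumped form as the critical radii `R_c_n` (under the pre-switch ambient
#' pressure, from the normoxia calibration) and `R_c_h` (under the
#' post-switch pressure, from the hypoxia calibration); the underlying
#' lumped coefficient `u = alpha Omega / (6 k) = p_inf / R_c^2` is what
#' relaxes exponentially, identical to relaxing `alpha` itself.
#'
#' @param R_o0 initial outer radius \[um\].
#' @param R_c_n,R_c_h critical radii at the normoxia / hypoxia endpoints
#'   \[um\] (each under its own ambient pressure).
#' @param tau_alpha adaptation timescale of the consumption rate \[days\].
#' @param Rbar_n,Rbar_h inhibition-onset radii at the endpoints \[um\].
#' @param tau_Rbar its adaptation timescale \[days\].
#' @param s_n,s_h proliferation rates \[day^-1\]; `tau_s` its timescale.
#' @param tau_s adaptation timescale of `s` \[days\].
#' @param lambda_n,lambda_h necrotic loss rates \[day^-1\]; `tau_lambda` its
#'   timescale.
#' @param tau_lambda adaptation timescale of `lambda` \[days\].
#' @param lambda_hat0 initial shell death rate \[day^-1\].
#' @param tau_lambda_hat its exponential-growth timescale \[days\].
#' @param t_s switch time \[days\].
#' @param p_inf_pre,p_inf_post ambient oxygen before / after the switch
#'   \[%\].
#' @return An object of class `deoxygenation_params`.
#' @export
deoxygenation_params <- function(R_o0, R_c_n, R_c_h, tau_alpha,
                                 Rbar_n, Rbar_h, tau_Rbar,
                                 s_n, s_h, tau_s,
                                 lambda_n, lambda_h, tau_lambda,
                                 lambda_hat0, tau_lambda_hat,
                                 t_s = 2, p_inf_pre = 21, p_inf_post = 2) {
  p <- list(R_o0 = R_o0, R_c_n = R_c_n, R_c_h = R_c_h,
            tau_alpha = tau_alpha, Rbar_n = Rbar_n, Rbar_h = Rbar_h,
            tau_Rbar = tau_Rbar, s_n = s_n, s_h = s_h, tau_s = tau_s,
            lambda_n = lambda_n, lambda_h = lambda_h,
            tau_lambda = tau_lambda, lambda_hat0 = lambda_hat0,
            tau_lambda_hat = tau_lambda_hat, t_s = t_s,
            p_inf_pre = p_inf_pre, p_inf_post = p_inf_post)
  check_adaptation_core(p)
  stopifnot(lambda_hat0 >= 0, tau_lambda_hat > 0)
  structure(p, class = "deoxygenation_params")
}

#' Re-oxygenation model parameters
#'
#' The seventeen free parameters of the hypoxia-to-normoxia switching model:
#' as [deoxygenation_params()] but with the endpoint roles swapped
#' (relaxation runs h to n), an initial necrotic radius `R_n0`, and the
#' core-clearance mechanism in place of the shell death rate: cleared volume
#' rate `lambda_tilde(t) = lambda_tilde0 * exp((t - t_s)/tau_lambda_tilde)`
#' acting on the re-oxygenated shell, of which a fraction `nu` rejoins the
#' living-cell volume and `1 - nu` leaves the spheroid.
#'
#' @inheritParams deoxygenation_params
#' @param R_n0 initial necrotic radius \[um\].
#' @param lambda_tilde0 initial clearance rate \[day^-1\].
#' @param tau_lambda_tilde its exponential-growth timescale \[days\].
#' @param nu recovered fraction of cleared core volume, in \[0, 1\].
#' @param lambda_eq first-order rate \[day^-1\] at which the core tracks its
#'   quasi-steady (algebraic) value when no re-oxygenated shell exists; used
#'   for the pre-switch segment started from a free `R_n0` and for late-time
#'   core re-formation. A numerical-coupling constant, not a fitted
#'   parameter.
#' @return An object of class `reoxygenation_params`.
#' @export
reoxygenation_params <- function(R_o0, R_n0, R_c_n, R_c_h, tau_alpha,
                                 Rbar_n, Rbar_h, tau_Rbar,
                                 s_n, s_h, tau_s,
                                 lambda_n, lambda_h, tau_lambda,
                                 lambda_tilde0, tau_lambda_tilde, nu,
                                 lambda_eq = 50,
                                 t_s = 4, p_inf_pre = 2, p_inf_post = 21) {
  p <- list(R_o0 = R_o0, R_n0 = R_n0, R_c_n = R_c_n, R_c_h = R_c_h,
            tau_alpha = tau_alpha, Rbar_n = Rbar_n, Rbar_h = Rbar_h,
            tau_Rbar = tau_Rbar, s_n = s_n, s_h = s_h, tau_s = tau_s,
            lambda_n = lambda_n, lambda_h = lambda_h,
            tau_lambda = tau_lambda, lambda_tilde0 = lambda_tilde0,
            tau_lambda_tilde = tau_lambda_tilde, nu = nu,
            lambda_eq = lambda_eq, t_s = t_s,
            p_inf_pre = p_inf_pre, p_inf_post = p_inf_post)
  check_adaptation_core(p)
  stopifnot(R_n0 >= 0, R_n0 < R_o0, lambda_tilde0 >= 0,
            tau_lambda_tilde > 0, nu >= 0, nu <= 1, lambda_eq > 0)
  structure(p, class = "reoxygenation_params")
}

switching_frame <- function(sol, params) {
  traj <- data.frame(time = sol$time, R_o = sol$R_o, R_n = sol$R_n,
                     R_i = sol$R_i, R_n_plus = sol$R_n_plus, V_n = sol$V_n,
                     R_c_t = sol$R_c_t, Rbar_t = sol$Rbar_t, s_t = sol$s_t,
                     lambda_t = sol$lambda_t,
                     exchange_rate = sol$exchange_rate)
  # The dynamic core volume decays exponentially during clearance and never
  # reaches exactly zero; a core below 0.5 um (far below cell scale and
  # measurement resolution) counts as absent for phase labelling.
  traj$phase <- ifelse(traj$R_n > 0.5, "phase_iii",
                       ifelse(traj$R_i > 0.5, "phase_ii", "phase_i"))
  structure(traj, class = c("switching_trajectory", "spheroid_trajectory",
                            "data.frame"),
            params = params)
}

#' Solve the deoxygenation model
#'
#' For `t < t_s` the constant-environment model with the normoxia endpoint
#' parameters; at `t_s` the outer radius and necrotic volume carry over
#' continuously while the ambient pressure drops, so the predicted necrotic
#' radius jumps above the actual one; for `t > t_s` the coefficients relax
#' toward the hypoxia endpoints while the core volume grows by shell death
#' at rate `lambda_hat(t)`.
#'
#' @param params a [deoxygenation_params()] object.
#' @param t_grid strictly increasing output times \[days\] spanning the
#'   switch.
#' @param rtol,atol integrator tolerances.
#' @return An object of class `switching_trajectory`: data frame with
#'   columns `time`, `R_o`, `R_n`, `R_i`, `R_n_plus`, `V_n`, the
#'   instantaneous coefficient values `R_c_t`, `Rbar_t`, `s_t`, `lambda_t`,
#'   the active exchange rate (`lambda_hat` here), and `phase`.
#' @export
solve_deoxygenation <- function(params, t_grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "deoxygenation_params"),
            length(t_grid) >= 2, all(diff(t_grid) > 0),
            max(t_grid) > params$t_s)
  u_n <- params$p_inf_pre / params$R_c_n^2
  u_h <- params$p_inf_post / params$R_c_h^2
  sol <- cpp_solve_deoxygenation(params$R_o0, u_n, u_h, params$tau_alpha,
                                 params$Rbar_n, params$Rbar_h,
                                 params$tau_Rbar, params$s_n, params$s_h,
                                 params$tau_s, params$lambda_n,
                                 params$lambda_h, params$tau_lambda,
                                 params$lambda_hat0, params$tau_lambda_hat,
                                 params$t_s, params$p_inf_pre,
                                 params$p_inf_post, as.numeric(t_grid),
                                 rtol, atol)
  switching_frame(sol, params)
}

#' Solve the re-oxygenation model
#'
#' For `t < t_s` the hypoxia-endpoint model started from `(R_o0, R_n0)`;
#' after the switch the ambient pressure rises, the predicted necrotic
#' radius drops below the actual one, and the re-oxygenated shell clears at
#' rate `lambda_tilde(t)` with a fraction `nu` of the cleared volume
#' rejoining the living cells. Coefficients relax from the hypoxia to the
#' normoxia endpoints, so trajectories can pass through the growth phases in
#' reverse before growth resumes.
#'
#' @param params a [reoxygenation_params()] object.
#' @inheritParams solve_deoxygenation
#' @return An object of class `switching_trajectory`; the exchange-rate
#'   column holds `lambda_tilde(t)`.
#' @export
solve_reoxygenation <- function(params, t_grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "reoxygenation_params"),
            length(t_grid) >= 2, all(diff(t_grid) > 0),
            max(t_grid) > params$t_s)
  u_n <- params$p_inf_post / params$R_c_n^2
  u_h <- params$p_inf_pre / params$R_c_h^2
  sol <- cpp_solve_reoxygenation(params$R_o0, params$R_n0, u_n, u_h,
                                 params$tau_alpha, params$Rbar_n,
                                 params$Rbar_h, params$tau_Rbar,
                                 params$s_n, params$s_h, params$tau_s,
                                 params$lambda_n, params$lambda_h,
                                 params$tau_lambda, params$lambda_tilde0,
                                 params$tau_lambda_tilde, params$nu,
                                 params$lambda_eq, params$t_s,
                                 params$p_inf_pre, params$p_inf_post,
                                 as.numeric(t_grid), rtol, atol)
  switching_frame(sol, params)
}
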