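# Forward-model handles: a uniform surface the likelihood, optimizer and
# sampler use to evaluate any of the three growth models at a parameter
# vector, returning predicted structure radii at the measurement days.

theta_to_params <- function(model, theta, fixed) {
  switch(model,
    greenspan = greenspan_params(R_o0 = theta[["R_o0"]], s = theta[["s"]],
                                 R_c = theta[["R_c"]],
                                 gamma = theta[["gamma"]], Q = theta[["Q"]]),
    deoxygenation = deoxygenation_params(
      R_o0 = theta[["R_o0"]], R_c_n = theta[["R_c_n"]],
      R_c_h = theta[["R_c_h"]], tau_alpha = theta[["tau_alpha"]],
      Rbar_n = theta[["Rbar_n"]], Rbar_h = theta[["Rbar_h"]],
      tau_Rbar = theta[["tau_Rbar"]], s_n = theta[["s_n"]],
      s_h = theta[["s_h"]], tau_s = theta[["tau_s"]],
      lambda_n = theta[["lambda_n"]], lambda_h = theta[["lambda_h"]],
      tau_lambda = theta[["tau_lambda"]],
      lambda_hat0 = theta[["lambda_hat0"]],
      tau_lambda_hat = theta[["tau_lambda_hat"]],
      t_s = fixed$t_s, p_inf_pre = fixed$p_inf_pre,
      p_inf_post = fixed$p_inf_post),
    reoxygenation = reoxygenation_params(
      R_o0 = theta[["R_o0"]], R_n0 = theta[["R_n0"]],
      R_c_n = theta[["R_c_n"]], R_c_h = theta[["R_c_h"]],
      tau_alpha = theta[["tau_alpha"]], Rbar_n = theta[["Rbar_n"]],
      Rbar_h = theta[["Rbar_h"]], tau_Rbar = theta[["tau_Rbar"]],
      s_n = theta[["s_n"]], s_h = theta[["s_h"]], tau_s = theta[["tau_s"]],
      lambda_n = theta[["lambda_n"]], lambda_h = theta[["lambda_h"]],
      tau_lambda = theta[["tau_lambda"]],
      lambda_tilde0 = theta[["lambda_tilde0"]],
      tau_lambda_tilde = theta[["tau_lambda_tilde"]], nu = theta[["nu"]],
      lambda_eq = fixed$lambda_eq, t_s = fixed$t_s,
      p_inf_pre = fixed$p_inf_pre, p_inf_post = fixed$p_inf_post),
    stop("unknown model: ", model))
}

model_par_names <- function(model) {
  switch(model,
    greenspan = c("R_o0", "s", "R_c", "gamma", "Q"),
    deoxygenation = c("R_o0", "R_c_n", "R_c_h", "tau_alpha",
                      "Rbar_n", "Rbar_h", "tau_Rbar", "s_n", "s_h", "tau_s",
                      "lambda_n", "lambda_h", "tau_lambda",
                      "lambda_hat0", "tau_lambda_hat"),
    reoxygenation = c("R_o0", "R_n0", "R_c_n", "R_c_h", "tau_alpha",
                      "Rbar_n", "Rbar_h", "tau_Rbar", "s_n", "s_h", "tau_s",
                      "lambda_n", "lambda_h", "tau_lambda",
                      "lambda_tilde0", "tau_lambda_tilde", "nu"),
    stop("unknown model: ", model))
}

#' Forward-model handle for calibration
#'
#' Wraps one of the growth models as a function `simulate(theta, days)`
#' returning a matrix of predicted radii (columns `R_o`, `R_n`, `R_i`; one
#' row per requested day), together with the parameter names the vector
#' `theta` must carry. Environment settings that are part of the
#' experimental design rather than the inference (switch time, ambient
#' pressures, core-tracking rate, solver start time) are fixed here.
#'
#' @param model one of `"greenspan"`, `"deoxygenation"`,
#'   `"reoxygenation"`.
#' @param t_s switch time \[days\] (switching models).
#' @param p_inf_pre,p_inf_post ambient oxygen \[%\] before / after the
#'   switch.
#' @param lambda_eq core-tracking rate \[day^-1\] (re-oxygenation model).
#' @param t0 time of the initial condition \[days\].
#' @param rtol,atol solver tolerances used during calibration.
#' @return An object of class `model_handle`: list with `simulate`,
#'   `par_names`, `channels`, `model`.
#' @export
model_handle <- function(model = c("greenspan", "deoxygenation",
                                   "reoxygenation"),
                         t_s = 2, p_inf_pre = 21, p_inf_post = 2,
                         lambda_eq = 50, t0 = 0, rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  fixed <- list(t_s = t_s, p_inf_pre = p_inf_pre, p_inf_post = p_inf_post,
                lambda_eq = lambda_eq)
  par_names <- model_par_names(model)
  # lean path: call the compiled solvers directly, skipping the rich
  # trajectory construction, since this runs once per likelihood evaluation
  simulate <- function(theta, days) {
    theta <- stats::setNames(as.numeric(theta), par_names)
    params <- theta_to_params(model, theta, fixed)
    days <- sort(unique(days))
    grid <- sort(unique(c(t0, if (model != "greenspan") t_s, days)))
    sol <- switch(model,
      greenspan = cpp_solve_greenspan(params$R_o0, params$s,
                                      params$lambda, params$R_c,
                                      params$Rbar, grid, rtol, atol),
      deoxygenation = cpp_solve_deoxygenation(
        params$R_o0, params$p_inf_pre / params$R_c_n^2,
        params$p_inf_post / params$R_c_h^2, params$tau_alpha,
        params$Rbar_n, params$Rbar_h, params$tau_Rbar, params$s_n,
        params$s_h, params$tau_s, params$lambda_n, params$lambda_h,
        params$tau_lambda, params$lambda_hat0, params$tau_lambda_hat,
        params$t_s, params$p_inf_pre, params$p_inf_post, grid, rtol,
        atol),
      reoxygenation = cpp_solve_reoxygenation(
        params$R_o0, params$R_n0, params$p_inf_post / params$R_c_n^2,
        params$p_inf_pre / params$R_c_h^2, params$tau_alpha,
        params$Rbar_n, params$Rbar_h, params$tau_Rbar, params$s_n,
        params$s_h, params$tau_s, params$lambda_n, params$lambda_h,
        params$tau_lambda, params$lambda_tilde0,
        params$tau_lambda_tilde, params$nu, params$lambda_eq,
        params$t_s, params$p_inf_pre, params$p_inf_post, grid, rtol,
        atol))
    idx <- match(days, grid)
    cbind(R_o = sol$R_o[idx], R_n = sol$R_n[idx], R_i = sol$R_i[idx])
  }
  structure(list(simulate = simulate, par_names = par_names,
                 channels = c("R_o", "R_n", "R_i"), model = model,
                 fixed = fixed),
            class = "model_handle")
}
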