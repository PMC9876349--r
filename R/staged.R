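# Staged calibration of the deoxygenation model: independent per-snapshot
# estimates and constant-environment fits narrow the bounds before the
# full switching model is fitted.

normal_fit <- function(x) {
  x <- x[is.finite(x)]
  list(mean = mean(x), sd = sqrt(mean((x - mean(x))^2)), n = length(x))
}

#' Per-spheroid snapshot estimates over a measurement table
#'
#' Applies [snapshot_estimate()] row-wise; rows whose phase does not
#' support an estimator contribute `NA`. `p_inf` may be a single ambient
#' pressure or a function of the measurement day (switching experiments).
#'
#' @param tab measurement table.
#' @param p_inf ambient oxygen \[%\], scalar or `function(day)`.
#' @param constants an [oxygen_constants()].
#' @return Data frame: `spheroid_id`, `day`, `R_c`, `alpha`, `p_i`, `Rbar`,
#'   `phase`.
#' @export
snapshot_estimates_table <- function(tab, p_inf,
                                     constants = oxygen_constants()) {
  pfun <- if (is.function(p_inf)) p_inf else function(day) p_inf
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    R_o <- tab$R_o_um[i]
    R_n <- tab$R_n_um[i]
    R_i <- tab$R_i_um[i]
    if (!is.finite(R_o) || R_o <= 0)
      return(data.frame(spheroid_id = tab$spheroid_id[i], day = tab$day[i],
                        R_c = NA_real_, alpha = NA_real_, p_i = NA_real_,
                        Rbar = NA_real_, phase = NA_character_))
    st <- spheroid_structure(R_o = R_o,
                             R_n = if (is.finite(R_n)) min(R_n, R_o) else 0,
                             R_i = if (is.finite(R_i)) min(R_i, R_o) else 0)
    est <- suppressWarnings(
      snapshot_estimate(st, p_inf = pfun(tab$day[i]), constants = constants))
    data.frame(spheroid_id = tab$spheroid_id[i], day = tab$day[i],
               R_c = est$R_c, alpha = est$alpha, p_i = est$p_i,
               Rbar = est$Rbar, phase = est$phase)
  })
  do.call(rbind, rows)
}

# model handle for fitting the exponential relaxation form to per-snapshot
# estimates: parameters (v_from, v_to, tau), one observed pseudo-channel
relaxation_handle <- function(t_s) {
  simulate <- function(theta, days) {
    days <- sort(unique(days))
    v <- relax(theta[[1]], theta[[2]], theta[[3]], pmax(days, t_s), t_s)
    cbind(R_o = v, R_n = NA_real_, R_i = NA_real_)
  }
  structure(list(simulate = simulate,
                 par_names = c("v_from", "v_to", "tau"),
                 channels = "R_o", model = "relaxation",
                 fixed = list(t_s = t_s)),
            class = "model_handle")
}

#' Fit the exponential adaptation form to per-snapshot estimates
#'
#' Least-squares plus posterior sampling of
#' `v(t) = v_to + (v_from - v_to) exp(-(t - t_s)/tau)` given per-spheroid
#' estimates of a relaxing quantity at post-switch days; used to estimate
#' the endpoint values and adaptation timescale of the inhibition-onset
#' radius and of the (lumped) consumption rate.
#'
#' @param days observation days \[days\] (>= `t_s`).
#' @param values per-snapshot estimates of the quantity.
#' @param t_s switch time \[days\].
#' @param lower,upper bounds on `(v_from, v_to, tau)`.
#' @param n_starts multistart count for the optimisation.
#' @param mcmc list with `n_chains`, `n_samples`, `burn_in` (NULL skips
#'   sampling).
#' @param seed RNG seed.
#' @return List: `fit` (an `mle_fit`), `mcmc` (an `mcmc_result` or NULL),
#'   estimates `v_from`, `v_to`, `tau`.
#' @export
fit_relaxation <- function(days, values, t_s, lower, upper, n_starts = 30,
                           mcmc = list(n_chains = 2, n_samples = 4000,
                                       burn_in = 1000), seed = 1) {
  keep <- is.finite(values) & is.finite(days)
  stopifnot(sum(keep) >= 4)
  tab <- data.frame(spheroid_id = seq_len(sum(keep)), day = days[keep],
                    condition = "relax", R_o_um = values[keep],
                    R_n_um = NA_real_, R_i_um = NA_real_, R_p_um = NA_real_)
  handle <- relaxation_handle(t_s)
  names(lower) <- names(upper) <- handle$par_names
  fit <- fit_mle(tab, handle, lower, upper, n_starts = n_starts,
                 seed = seed, channels = "R_o")
  post <- NULL
  if (!is.null(mcmc))
    post <- run_mcmc(tab, handle, lower, upper, init = fit$theta_hat,
                     n_chains = mcmc$n_chains, n_samples = mcmc$n_samples,
                     burn_in = mcmc$burn_in, seed = seed + 1,
                     channels = "R_o")
  list(fit = fit, mcmc = post,
       v_from = fit$theta_hat[["v_from"]], v_to = fit$theta_hat[["v_to"]],
       tau = fit$theta_hat[["tau"]])
}

default_greenspan_bounds <- function() {
  list(lower = c(R_o0 = 40, s = 0.1, R_c = 80, gamma = 0.05, Q = 0.3),
       upper = c(R_o0 = 250, s = 2, R_c = 450, gamma = 3, Q = 1.2))
}

#' Staged calibration of the deoxygenation model
#'
#' Executes the full calibration pipeline on a normoxia, a hypoxia and a
#' deoxygenation measurement table (outliers filtered internally):
#' \enumerate{
#'   \item Normal fit to the first-day outer-radius measurements (initial
#'     condition scale).
#'   \item Per-spheroid snapshot estimates of the critical radius and
#'     inhibition-onset radius in both constant conditions, with normal
#'     summaries.
#'   \item Constant-environment model calibration (multistart MLE then
#'     MCMC) for the normoxia and hypoxia endpoint parameter sets.
#'   \item Per-snapshot time series of the inhibition-onset radius and of
#'     the lumped consumption rate from the deoxygenation table (assuming
#'     the core tracks its quasi-steady prediction), fitted to the
#'     exponential adaptation form to estimate the endpoint pairs and
#'     adaptation timescales.
#'   \item Full deoxygenation-model fit (multistart MLE then MCMC) with
#'     bounds informed by stages 1-4.
#'   \item Posterior-predictive check: coverage of the observations by the
#'     95% prediction band.
#' }
#'
#' @param normoxia_data,hypoxia_data,deoxy_data measurement tables.
#' @param t_s switch time of the deoxygenation experiment \[days\].
#' @param p_inf_pre,p_inf_post ambient oxygen \[%\] before/after.
#' @param constants an [oxygen_constants()].
#' @param greenspan_bounds list of `lower`/`upper` for stage 3.
#' @param mcmc desk-scale chain settings used for every sampling stage.
#' @param n_starts multistart count.
#' @param seed RNG seed.
#' @return An object of class `staged_calibration` with one element per
#'   stage.
#' @export
staged_deoxygenation_calibration <- function(normoxia_data, hypoxia_data,
                                             deoxy_data, t_s = 2,
                                             p_inf_pre = 21, p_inf_post = 2,
                                             constants = oxygen_constants(),
                                             greenspan_bounds =
                                               default_greenspan_bounds(),
                                             mcmc = list(n_chains = 2,
                                                         n_samples = 4000,
                                                         burn_in = 1000),
                                             n_starts = 15, seed = 1) {
  normoxia_data <- filter_outliers(normoxia_data)
  hypoxia_data <- filter_outliers(hypoxia_data)
  deoxy_data <- filter_outliers(deoxy_data)

  # stage 1: initial-size distribution
  day1 <- function(tab) tab$R_o_um[tab$day == min(tab$day)]
  stage1 <- list(normoxia = normal_fit(day1(normoxia_data)),
                 deoxygenation = normal_fit(day1(deoxy_data)))

  # stage 2: snapshot estimates in the constant conditions
  snap_n <- snapshot_estimates_table(normoxia_data, p_inf_pre, constants)
  snap_h <- snapshot_estimates_table(hypoxia_data, p_inf_post, constants)
  stage2 <- list(normoxia = list(snapshots = snap_n,
                                 R_c = normal_fit(snap_n$R_c),
                                 Rbar = normal_fit(snap_n$Rbar)),
                 hypoxia = list(snapshots = snap_h,
                                R_c = normal_fit(snap_h$R_c),
                                Rbar = normal_fit(snap_h$Rbar)))

  # stage 3: constant-environment calibrations
  run_greenspan <- function(tab, sub_seed) {
    handle <- model_handle("greenspan")
    fit <- fit_mle(tab, handle, greenspan_bounds$lower,
                   greenspan_bounds$upper, n_starts = n_starts,
                   seed = sub_seed)
    post <- run_mcmc(tab, handle, greenspan_bounds$lower,
                     greenspan_bounds$upper, init = fit$theta_hat,
                     n_chains = mcmc$n_chains, n_samples = mcmc$n_samples,
                     burn_in = mcmc$burn_in, seed = sub_seed + 1)
    list(fit = fit, mcmc = post)
  }
  stage3 <- list(normoxia = run_greenspan(normoxia_data, seed + 10),
                 hypoxia = run_greenspan(hypoxia_data, seed + 20))

  # stage 4: adaptation timescales from per-snapshot deoxygenation series
  p_of_day <- function(day) ifelse(day < t_s, p_inf_pre, p_inf_post)
  snap_d <- snapshot_estimates_table(deoxy_data, p_of_day, constants)
  post_switch <- snap_d$day >= t_s
  rc_mean_n <- stage2$normoxia$R_c$mean
  rbar_mean_n <- stage2$normoxia$Rbar$mean
  # lumped consumption u = p_inf / R_c^2 per snapshot (core assumed at its
  # quasi-steady radius)
  u_snap <- p_of_day(snap_d$day) / snap_d$R_c^2
  u_n_guess <- p_inf_pre / rc_mean_n^2
  stage4 <- list(
    Rbar = fit_relaxation(snap_d$day[post_switch],
                          snap_d$Rbar[post_switch], t_s,
                          lower = c(20, 20, 0.02),
                          upper = c(400, 400, 8),
                          n_starts = n_starts, mcmc = mcmc,
                          seed = seed + 30),
    u = fit_relaxation(snap_d$day[post_switch], u_snap[post_switch], t_s,
                       lower = c(rep(min(u_snap[post_switch],
                                         na.rm = TRUE) / 5, 2), 0.02),
                       upper = c(rep(max(c(u_snap[post_switch], u_n_guess),
                                         na.rm = TRUE) * 5, 2), 8),
                       n_starts = n_starts, mcmc = mcmc, seed = seed + 40),
    snapshots = snap_d)
  # report the consumption-rate relaxation as critical radii too
  stage4$R_c_n_est <- sqrt(p_inf_pre / stage4$u$v_from)
  stage4$R_c_h_est <- sqrt(p_inf_post / stage4$u$v_to)
  stage4$tau_alpha_est <- stage4$u$tau
  stage4$tau_Rbar_est <- stage4$Rbar$tau

  # stage 5: full deoxygenation model with informed bounds
  widen <- function(centre, lo_fac = 0.5, hi_fac = 2)
    c(max(centre * lo_fac, 1e-4), centre * hi_fac)
  g3 <- function(cond, fun) {
    th <- stage3[[cond]]$fit$theta_hat
    fun(th)
  }
  b <- list(
    R_o0 = c(max(stage1$deoxygenation$mean - 4 * stage1$deoxygenation$sd,
                 10),
             stage1$deoxygenation$mean + 4 * stage1$deoxygenation$sd),
    R_c_n = widen(g3("normoxia", function(th) th[["R_c"]])),
    R_c_h = widen(g3("hypoxia", function(th) th[["R_c"]])),
    tau_alpha = c(0.02, 8),
    Rbar_n = widen(g3("normoxia", function(th) th[["Q"]] * th[["R_c"]])),
    Rbar_h = widen(g3("hypoxia", function(th) th[["Q"]] * th[["R_c"]])),
    tau_Rbar = c(0.02, 8),
    s_n = widen(g3("normoxia", function(th) th[["s"]])),
    s_h = widen(g3("hypoxia", function(th) th[["s"]])),
    tau_s = c(0.02, 8),
    lambda_n = widen(g3("normoxia", function(th) th[["gamma"]] *
                          th[["s"]])),
    lambda_h = widen(g3("hypoxia", function(th) th[["gamma"]] * th[["s"]])),
    tau_lambda = c(0.02, 8),
    lambda_hat0 = c(0.005, 5),
    tau_lambda_hat = c(0.1, 10))
  lower_d <- vapply(b, `[`, numeric(1), 1)
  upper_d <- vapply(b, `[`, numeric(1), 2)
  handle_d <- model_handle("deoxygenation", t_s = t_s,
                           p_inf_pre = p_inf_pre, p_inf_post = p_inf_post)
  names(lower_d) <- names(upper_d) <- handle_d$par_names
  fit_d <- fit_mle(deoxy_data, handle_d, lower_d, upper_d,
                   n_starts = n_starts, seed = seed + 50)
  mcmc_d <- run_mcmc(deoxy_data, handle_d, lower_d, upper_d,
                     init = fit_d$theta_hat, n_chains = mcmc$n_chains,
                     n_samples = mcmc$n_samples, burn_in = mcmc$burn_in,
                     seed = seed + 60)
  stage5 <- list(bounds = list(lower = lower_d, upper = upper_d),
                 fit = fit_d, mcmc = mcmc_d)

  # stage 6: posterior-predictive coverage at 95%
  days <- sort(unique(deoxy_data$day))
  bands <- prediction_intervals(mcmc_d, handle_d, days, n_draws = 300,
                                seed = seed + 70, levels = 95)
  obs <- likelihood_obs(deoxy_data, c("R_o", "R_n", "R_i"))
  inside <- vapply(seq_len(nrow(obs)), function(i) {
    band <- bands[bands$channel == obs$channel[i] &
                    bands$time == obs$day[i], ]
    obs$value[i] >= band$lower && obs$value[i] <= band$upper
  }, logical(1))
  stage6 <- list(coverage95 = mean(inside), n_obs = nrow(obs))

  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 stage4 = stage4, stage5 = stage5, stage6 = stage6),
            class = "staged_calibration")
}
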