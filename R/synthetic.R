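# Synthetic radial-measurement generation emulating end-point spheroid
# experiments: per (day, spheroid) one destructively measured snapshot with
# additive Gaussian measurement noise and optional injected outliers.

with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Experimental design for synthetic measurement tables
#'
#' Encodes a sampling layout (measurement days, spheroids per day), the
#' ambient-oxygen condition, the measurement noise, and optional outlier
#' injection. The condition presets reproduce the study layouts this
#' package emulates: normoxia samples 12 spheroids on each of days
#' 2, 3, 4, 6, 8; hypoxia samples 7 spheroids on each of days 2, 4, 6, 8;
#' the deoxygenation design follows the normoxia layout with a switch at
#' `t_s = 2` days and the re-oxygenation design uses 7 spheroids per day
#' with a switch at `t_s = 2` days.
#'
#' @param condition one of `"normoxia"`, `"hypoxia"`, `"deoxygenation"`,
#'   `"reoxygenation"`.
#' @param days measurement days; `NULL` for the condition preset.
#' @param n_per_day spheroids measured per day; `NULL` for the preset.
#' @param t_s switch time \[days\] (switching conditions).
#' @param sigma measurement noise standard deviation \[um\]: a single value
#'   shared across channels or a named vector over
#'   `c("R_o","R_n","R_i","R_p")`.
#' @param outlier_fraction fraction of observations replaced by outliers.
#' @param outlier_factor multiplicative magnitude of injected outliers.
#' @param seed RNG seed used by [generate_dataset()].
#' @return An object of class `experimental_design`.
#' @export
experimental_design <- function(condition = c("normoxia", "hypoxia",
                                              "deoxygenation",
                                              "reoxygenation"),
                                days = NULL, n_per_day = NULL, t_s = NULL,
                                sigma = 4, outlier_fraction = 0,
                                outlier_factor = 10, seed = 1) {
  condition <- match.arg(condition)
  preset <- switch(condition,
    normoxia = list(days = c(2, 3, 4, 6, 8), n = 12, t_s = NA, p_inf = 21),
    hypoxia = list(days = c(2, 4, 6, 8), n = 7, t_s = NA, p_inf = 2),
    deoxygenation = list(days = c(2, 3, 4, 6, 8), n = 12, t_s = 2,
                         p_inf = c(pre = 21, post = 2)),
    reoxygenation = list(days = c(2, 3, 4, 6, 8), n = 7, t_s = 2,
                         p_inf = c(pre = 2, post = 21)))
  if (is.null(days)) days <- preset$days
  if (is.null(n_per_day)) n_per_day <- preset$n
  if (is.null(t_s)) t_s <- preset$t_s
  channels <- c("R_o", "R_n", "R_i", "R_p")
  if (length(sigma) == 1 && is.null(names(sigma)))
    sigma <- stats::setNames(rep(sigma, 4), channels)
  stopifnot(all(channels %in% names(sigma)), all(sigma >= 0),
            all(days > 0), n_per_day >= 1,
            outlier_fraction >= 0, outlier_fraction < 1, outlier_factor > 0)
  structure(list(condition = condition, days = sort(unique(days)),
                 n_per_day = n_per_day, t_s = t_s,
                 p_inf = preset$p_inf, sigma = sigma[channels],
                 outlier_fraction = outlier_fraction,
                 outlier_factor = outlier_factor, seed = seed),
            class = "experimental_design")
}

simulate_truth <- function(params, design, constants) {
  days <- design$days
  if (inherits(params, "greenspan_params")) {
    grid <- sort(unique(c(0, days)))
    traj <- solve_greenspan(params, grid)
    idx <- match(days, traj$time)
    rc <- rep(params$R_c, length(days))
    p_amb <- rep(design$p_inf[[1]], length(days))
  } else {
    grid <- sort(unique(c(0, params$t_s, days)))
    traj <- if (inherits(params, "deoxygenation_params"))
      solve_deoxygenation(params, grid) else solve_reoxygenation(params, grid)
    idx <- match(days, traj$time)
    rc <- traj$R_c_t[idx]
    p_amb <- ifelse(days < params$t_s, params$p_inf_pre, params$p_inf_post)
  }
  R_o <- traj$R_o[idx]
  R_n <- traj$R_n[idx]
  R_i <- traj$R_i[idx]
  R_p <- vapply(seq_along(days), function(j) {
    oxy <- oxygen_params(p_inf = p_amb[j], R_c = rc[j])
    predict_hypoxic_radius(R_o[j], R_n[j], oxy, constants$p_hyp)
  }, numeric(1))
  data.frame(day = days, R_o = R_o, R_n = R_n, R_i = R_i, R_p = R_p)
}

#' Generate a synthetic radial-measurement table
#'
#' Simulates the requested growth model, samples it destructively at the
#' design days (`n_per_day` spheroids per day), and adds iid Gaussian noise
#' per channel. Negative noisy draws are truncated at 0. Structure radii
#' that are exactly 0 in the model (region not yet formed) are recorded as
#' 0 without noise, matching the measurement convention that e.g. `R_n = 0`
#' before necrosis. The hypoxic radius is synthesised from the predicted
#' internal oxygen field at the configured marker threshold. Optionally a
#' random subset of observations is multiplied by `outlier_factor` to mimic
#' gross measurement failures. Fully reproducible per seed.
#'
#' @param params a `greenspan_params`, `deoxygenation_params` or
#'   `reoxygenation_params` object (the ground truth).
#' @param design an [experimental_design()].
#' @param constants an [oxygen_constants()] (hypoxia-marker threshold).
#' @param seed RNG seed; defaults to the design's.
#' @return A measurement table (`data.frame`) in the dialect of
#'   [read_measurements()], plus a logical `injected_outlier` column.
#' @export
generate_dataset <- function(params, design,
                             constants = oxygen_constants(),
                             seed = design$seed) {
  stopifnot(inherits(design, "experimental_design"))
  if (any(design$sigma < 0)) stop("noise sigma must be non-negative")
  truth <- simulate_truth(params, design, constants)
  n <- design$n_per_day
  tab <- truth[rep(seq_len(nrow(truth)), each = n), ]
  tab$spheroid_id <- paste0(design$condition, "_d", tab$day, "_",
                            rep(seq_len(n), times = nrow(truth)))
  with_preserved_seed(seed, {
    for (ch in c("R_o", "R_n", "R_i", "R_p")) {
      noisy <- tab[[ch]] + rnorm(nrow(tab), 0, design$sigma[[ch]])
      tab[[ch]] <- ifelse(tab[[ch]] > 0, pmax(noisy, 0), 0)
    }
    tab$injected_outlier <- FALSE
    if (design$outlier_fraction > 0) {
      cells <- which(as.matrix(tab[c("R_o", "R_n", "R_i", "R_p")]) > 0)
      k <- round(design$outlier_fraction * length(cells))
      if (k > 0) {
        hit <- sample(cells, k)
        m <- as.matrix(tab[c("R_o", "R_n", "R_i", "R_p")])
        m[hit] <- m[hit] * design$outlier_factor
        tab[c("R_o", "R_n", "R_i", "R_p")] <- m
        tab$injected_outlier[unique((hit - 1) %% nrow(tab) + 1)] <- TRUE
      }
    }
  })
  out <- data.frame(spheroid_id = tab$spheroid_id, day = tab$day,
                    condition = design$condition, R_o_um = tab$R_o,
                    R_n_um = tab$R_n, R_i_um = tab$R_i, R_p_um = tab$R_p,
                    injected_outlier = tab$injected_outlier,
                    row.names = NULL)
  out
}

#' Ground-truth parameter bundles for regression tests and examples
#'
#' Documented parameter sets of magnitudes plausible for melanoma spheroids
#' (radii growing from ~100 um at seeding toward saturation at a few
#' hundred um over eight days), paired with the matching experimental
#' design. These are package fixtures for exercising the pipeline, not
#' estimates of any experimental dataset. The switching presets are chosen
#' so that the qualitative behaviours the models exist to describe are
#' present: after deoxygenation the predicted necrotic radius exceeds the
#' actual one while the outer radius stays nearly constant; after
#' re-oxygenation the trajectory passes through the growth phases in
#' reverse before growth resumes.
#'
#' @param preset one of `"normoxia_like"`, `"hypoxia_like"`, `"deoxy_like"`,
#'   `"reoxy_like"`.
#' @return A list with elements `params` and `design`.
#' @export
ground_truth_bundle <- function(preset = c("normoxia_like", "hypoxia_like",
                                           "deoxy_like", "reoxy_like")) {
  preset <- match.arg(preset)
  switch(preset,
    normoxia_like = list(
      params = greenspan_params(R_o0 = 100, s = 0.6, R_c = 250,
                                gamma = 0.8, Q = 0.7),
      design = experimental_design("normoxia")),
    hypoxia_like = list(
      params = greenspan_params(R_o0 = 80, s = 0.75, R_c = 110,
                                gamma = 1.4, Q = 90 / 110),
      design = experimental_design("hypoxia")),
    deoxy_like = list(
      params = deoxygenation_params(
        R_o0 = 100, R_c_n = 250, R_c_h = 110, tau_alpha = 0.23,
        Rbar_n = 175, Rbar_h = 90, tau_Rbar = 0.23,
        s_n = 0.6, s_h = 0.75, tau_s = 1,
        lambda_n = 0.48, lambda_h = 1.05, tau_lambda = 1,
        lambda_hat0 = 0.3, tau_lambda_hat = 2,
        t_s = 2, p_inf_pre = 21, p_inf_post = 2),
      design = experimental_design("deoxygenation")),
    reoxy_like = list(
      params = reoxygenation_params(
        R_o0 = 95, R_n0 = 6, R_c_n = 250, R_c_h = 110, tau_alpha = 0.23,
        Rbar_n = 190, Rbar_h = 90, tau_Rbar = 0.4,
        s_n = 0.6, s_h = 0.75, tau_s = 1,
        lambda_n = 0.48, lambda_h = 0.9, tau_lambda = 1,
        lambda_tilde0 = 30, tau_lambda_tilde = 2, nu = 0.5,
        t_s = 2, p_inf_pre = 2, p_inf_post = 21),
      design = experimental_design("reoxygenation")))
}
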