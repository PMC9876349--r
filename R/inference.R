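# Statistical calibration workflow: quartile outlier filtering, Gaussian
# likelihood over radial measurements, multistart maximum likelihood,
# profile-likelihood identifiability, adaptive-Metropolis MCMC with
# error-variance sampling, convergence diagnostics, prediction intervals.

#' Flag outliers by the 1.5 IQR quartile rule
#'
#' Flags values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, quartiles by
#' linear interpolation between order statistics (quantile type 7). With
#' fewer than four finite values nothing is flagged; with zero IQR only
#' strict violations (values different from the common quartile) are
#' flagged. Applied independently per condition, measurement channel and
#' day by [filter_outliers()].
#'
#' @param values numeric vector \[um\].
#' @return Logical mask, `TRUE` for outliers (never `NA`).
#' @export
flag_outliers <- function(values) {
  ok <- is.finite(values)
  flags <- rep(FALSE, length(values))
  if (sum(ok) < 4) return(flags)
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  flags[ok] <- values[ok] < q[1] - 1.5 * iqr | values[ok] > q[2] + 1.5 * iqr
  flags
}

#' Remove outlying measurements channel-wise
#'
#' Applies [flag_outliers()] independently to every (condition, channel,
#' day) cell of a measurement table and sets flagged values to `NA` so they
#' no longer enter any likelihood.
#'
#' @param tab measurement table (dialect of [read_measurements()]).
#' @param channels channels to filter.
#' @return The table with flagged entries set to `NA` and logical columns
#'   `outlier_<channel>` recording the flags.
#' @export
filter_outliers <- function(tab, channels = c("R_o", "R_n", "R_i")) {
  for (ch in channels) {
    col <- paste0(ch, "_um")
    flags <- rep(FALSE, nrow(tab))
    for (cond in unique(tab$condition)) {
      for (d in unique(tab$day[tab$condition == cond])) {
        sel <- which(tab$condition == cond & tab$day == d)
        flags[sel] <- flag_outliers(tab[[col]][sel])
      }
    }
    tab[[paste0("outlier_", ch)]] <- flags
    tab[[col]][flags] <- NA_real_
  }
  tab
}

# long view of the observations entering the likelihood
likelihood_obs <- function(data, channels) {
  obs <- list()
  for (ch in channels) {
    col <- paste0(ch, "_um")
    keep <- is.finite(data[[col]])
    if (any(keep))
      obs[[ch]] <- data.frame(day = data$day[keep], channel = ch,
                              value = data[[col]][keep])
  }
  do.call(rbind, obs)
}

model_predictions <- function(model, theta, obs) {
  days <- sort(unique(obs$day))
  pred <- tryCatch(model$simulate(theta, days), error = function(e) NULL)
  if (is.null(pred)) return(NULL)
  mu <- pred[cbind(match(obs$day, days), match(obs$channel,
                                               colnames(pred)))]
  if (any(!is.finite(mu))) return(NULL)
  mu
}

#' Gaussian log-likelihood of a parameter vector
#'
#' Independent Gaussian measurement errors with shared standard deviation
#' `sigma` across the observed channels; missing entries contribute
#' nothing. The model is simulated once per distinct measurement day. A
#' failed simulation (solver failure, invalid parameters) yields `-Inf`.
#'
#' @param theta parameter vector in the order of `model$par_names`.
#' @param data outlier-filtered measurement table.
#' @param model a [model_handle()].
#' @param sigma error standard deviation \[um\].
#' @param channels observed channels entering the fit (the hypoxic radius
#'   is excluded by default; it is used for snapshot validation only).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(theta, data, model, sigma,
                           channels = c("R_o", "R_n", "R_i")) {
  stopifnot(sigma > 0)
  obs <- likelihood_obs(data, channels)
  if (is.null(obs) || nrow(obs) == 0) stop("no usable observations")
  mu <- model_predictions(model, theta, obs)
  if (is.null(mu)) return(-Inf)
  sum(dnorm(obs$value, mean = mu, sd = sigma, log = TRUE))
}

sum_sq_residuals <- function(theta, data, model, channels) {
  obs <- likelihood_obs(data, channels)
  mu <- model_predictions(model, theta, obs)
  if (is.null(mu)) return(list(ss = Inf, n = nrow(obs)))
  list(ss = sum((obs$value - mu)^2), n = nrow(obs))
}

# precomputed sum-of-squares objective: the observation view and index
# arithmetic are resolved once, so repeated evaluations (optimiser, profile,
# sampler) cost one model simulation each
make_ss_fun <- function(data, model, channels) {
  obs <- likelihood_obs(data, channels)
  if (is.null(obs) || nrow(obs) == 0) stop("no usable observations")
  days <- sort(unique(obs$day))
  ridx <- match(obs$day, days)
  cidx <- match(obs$channel, model$channels)
  value <- obs$value
  fn <- function(theta) {
    pred <- tryCatch(model$simulate(theta, days), error = function(e) NULL)
    if (is.null(pred)) return(Inf)
    mu <- pred[cbind(ridx, cidx)]
    if (any(!is.finite(mu))) return(Inf)
    sum((value - mu)^2)
  }
  attr(fn, "n_obs") <- nrow(obs)
  fn
}

#' Multistart maximum likelihood estimation
#'
#' Bounded local optimisation (L-BFGS-B on the profiled Gaussian
#' deviance, i.e. the sum of squared residuals) from `n_starts`
#' Latin-hypercube starting points; the best local optimum is returned.
#' Deterministic for a given seed. The error standard deviation is profiled
#' out analytically: `sigma_hat^2 = SSR(theta_hat) / N`.
#'
#' @param data outlier-filtered measurement table.
#' @param model a [model_handle()].
#' @param lower,upper named bounds on the parameters.
#' @param n_starts number of starting points.
#' @param seed RNG seed for the start design.
#' @param channels observed channels.
#' @param control passed to [stats::optim()].
#' @return A list of class `mle_fit`: `theta_hat` (named), `sigma_hat`,
#'   `logLik`, `ss`, `n_obs`, `starts` (per-start summary), `convergence`.
#' @export
fit_mle <- function(data, model, lower, upper, n_starts = 20, seed = 1,
                    channels = c("R_o", "R_n", "R_i"),
                    control = list(maxit = 500, factr = 1e7)) {
  stopifnot(n_starts >= 1, all(is.finite(lower)), all(is.finite(upper)),
            length(lower) == length(model$par_names),
            length(upper) == length(model$par_names), all(upper > lower))
  lower <- lower[model$par_names]
  upper <- upper[model$par_names]
  d <- length(lower)
  starts <- with_preserved_seed(seed, {
    u <- lhs::randomLHS(n_starts, d)
    sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  })
  ss_fun <- make_ss_fun(data, model, channels)
  objective <- function(th) {
    ss <- ss_fun(th)
    if (!is.finite(ss)) 1e12 else ss
  }
  # scale the search to the box so parameters of very different magnitude
  # are optimised on an even footing
  if (is.null(control$parscale))
    control$parscale <- pmax((upper - lower) / 10, 1e-300)
  results <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    results[[i]] <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = lower, upper = upper, control = control),
      error = function(e) list(value = Inf, convergence = 99,
                               message = conditionMessage(e)))
  }
  values <- vapply(results, function(r) r$value, numeric(1))
  if (all(!is.finite(values)))
    stop("all optimisation starts failed: ",
         paste(unique(vapply(results, function(r)
           if (!is.null(r$message)) r$message else "non-finite objective",
           character(1))), collapse = "; "))
  best <- results[[which.min(values)]]
  # polish the winner with a tighter tolerance
  best <- optim(best$par, objective, method = "L-BFGS-B",
                lower = lower, upper = upper,
                control = list(maxit = 1000, factr = 100,
                               parscale = control$parscale))
  ssr <- list(ss = ss_fun(best$par), n = attr(ss_fun, "n_obs"))
  sigma_hat <- sqrt(ssr$ss / ssr$n)
  theta_hat <- stats::setNames(best$par, model$par_names)
  structure(list(theta_hat = theta_hat,
                 sigma_hat = sigma_hat, ss = ssr$ss, n_obs = ssr$n,
                 logLik = if (sigma_hat > 0)
                   sum(dnorm(0, 0, sigma_hat, log = TRUE)) * ssr$n -
                     ssr$ss / (2 * sigma_hat^2)
                 else Inf,
                 starts = data.frame(value = values,
                                     convergence = vapply(results,
                                       function(r) as.integer(r$convergence),
                                       integer(1))),
                 convergence = best$convergence,
                 lower = lower, upper = upper, channels = channels),
            class = "mle_fit")
}

profile_loglik_at <- function(value, param, fit, ss_fun, model, warm) {
  keep <- setdiff(model$par_names, param)
  objective <- function(th_free) {
    th <- stats::setNames(numeric(length(model$par_names)),
                          model$par_names)
    th[keep] <- th_free
    th[param] <- value
    ss <- ss_fun(th)
    if (!is.finite(ss)) 1e12 else ss
  }
  if (length(keep) == 0)
    return(list(par = numeric(0), value = objective(numeric(0))))
  opt <- tryCatch(
    optim(warm, objective, method = "L-BFGS-B",
          lower = fit$lower[keep], upper = fit$upper[keep],
          control = list(maxit = 300, factr = 1e6,
                         parscale = pmax((fit$upper[keep] -
                                            fit$lower[keep]) / 10,
                                         1e-300))),
    error = function(e) list(par = warm, value = objective(warm)))
  opt
}

#' Profile likelihood for one parameter
#'
#' For each grid value of the target parameter, maximises the likelihood
#' over the remaining parameters (warm-started from the neighbouring grid
#' point). The profile is normalised to 0 at its maximum and the
#' approximate 95% confidence interval is the set where the normalised
#' profile exceeds the chi-squared(1) cutoff `-1.92`. The error standard
#' deviation is profiled analytically throughout, so the normalised profile
#' is `-(N/2) log(SSR(value)/SSR_min)`.
#'
#' @param data outlier-filtered measurement table.
#' @param model a [model_handle()].
#' @param fit an `mle_fit` from [fit_mle()].
#' @param param name of the profiled parameter.
#' @param grid grid of parameter values; default 25 equispaced points
#'   across the fit bounds for that parameter.
#' @param channels observed channels.
#' @param sigma if supplied, the error standard deviation is treated as
#'   known and the profile uses the fixed-sigma log-likelihood
#'   `-(SSR - SSR_min)/(2 sigma^2)`; by default sigma is profiled
#'   analytically, giving the deviance form `-(N/2) log(SSR/SSR_min)`.
#' @return An object of class `profile_result`: data frame `profile`
#'   (`value`, `loglik`), `ci95` (edges refined by root-finding between
#'   grid points), `mle`, `multimodal` flag.
#' @export
profile_likelihood <- function(data, model, fit, param, grid = NULL,
                               channels = fit$channels, sigma = NULL) {
  stopifnot(inherits(fit, "mle_fit"), param %in% model$par_names)
  if (is.null(grid))
    grid <- seq(fit$lower[[param]], fit$upper[[param]], length.out = 25)
  grid <- sort(unique(c(grid, fit$theta_hat[[param]])))
  keep <- setdiff(model$par_names, param)
  n <- fit$n_obs
  ss_fun <- make_ss_fun(data, model, channels)
  mle_value <- fit$theta_hat[[param]]
  i0 <- which.min(abs(grid - mle_value))
  ss_prof <- numeric(length(grid))
  warm_store <- vector("list", length(grid))
  # sweep outwards from the MLE so warm starts stay informative
  for (dir in list(seq(i0, length(grid)), seq(i0, 1))) {
    warm <- fit$theta_hat[keep]
    for (i in dir) {
      opt <- profile_loglik_at(grid[i], param, fit, ss_fun, model, warm)
      ss_prof[i] <- opt$value
      warm_store[[i]] <- warm <- opt$par
    }
  }
  ss_min <- min(fit$ss, min(ss_prof))
  norm_ll <- function(ss)
    if (is.null(sigma)) -(n / 2) * log(ss / ss_min)
    else -(ss - ss_min) / (2 * sigma^2)
  loglik <- norm_ll(ss_prof)
  loglik <- loglik - max(loglik)
  above <- loglik >= -1.92
  # refine the CI edges between bracketing grid points
  refine <- function(i_in, i_out) {
    g <- function(v) {
      opt <- profile_loglik_at(v, param, fit, ss_fun, model,
                               warm_store[[i_in]])
      norm_ll(opt$value) + 1.92
    }
    scale <- max(abs(grid[i_out] - grid[i_in]), 1e-8)
    tryCatch(stats::uniroot(g, sort(c(grid[i_in], grid[i_out])),
                            tol = min(1e-8, 1e-4 * scale),
                            maxiter = 30)$root,
             error = function(e) grid[i_in])
  }
  idx_above <- which(above)
  lo_i <- min(idx_above); hi_i <- max(idx_above)
  ci95 <- c(if (lo_i > 1) refine(lo_i, lo_i - 1) else grid[1],
            if (hi_i < length(grid)) refine(hi_i, hi_i + 1)
            else grid[length(grid)])
  # a profile that dips below the cutoff between regions above it is
  # multimodal; report, don't fail
  runs <- rle(above)
  multimodal <- sum(runs$values) > 1
  if (multimodal)
    warning("profile likelihood for ", param,
            " is not unimodal above the 95% cutoff")
  structure(list(param = param,
                 profile = data.frame(value = grid, loglik = loglik),
                 ci95 = ci95, mle = mle_value, multimodal = multimodal),
            class = "profile_result")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance diagnostic. With `m` chains of length `n`,
#' within-chain variance `W` (mean of the chain variances) and
#' between-chain variance `B` (`n` times the variance of the chain means),
#' this implementation uses the convention `R_hat = sqrt(1 + B / (n W))`:
#' the classic factor with its `(n - 1)/n` finite-sample term normalised so
#' that chains identical to each other give exactly 1. Values below 1.1 are
#' conventionally taken as converged.
#'
#' @param chains matrix (iterations x chains) for one parameter, or a
#'   3-d array (iterations x parameters x chains) for several.
#' @return A scale-reduction factor per parameter.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- array(chains,
                                         dim = c(nrow(chains), 1,
                                                 ncol(chains)))
  stopifnot(length(dim(chains)) == 3)
  n <- dim(chains)[1]
  m <- dim(chains)[3]
  if (m < 2) stop("at least two chains are required")
  if (n < 10) stop("chains must have length >= 10")
  out <- numeric(dim(chains)[2])
  for (p in seq_len(dim(chains)[2])) {
    x <- chains[, p, , drop = TRUE]
    means <- colMeans(x)
    W <- mean(apply(x, 2, var))
    B <- n * var(means)
    out[p] <- if (W == 0) {
      if (B == 0) 1 else Inf
    } else sqrt(1 + B / (n * W))
  }
  names(out) <- dimnames(chains)[[2]]
  out
}

mcmc_one_chain <- function(ss_fun, lower, upper, init, sigma2_init,
                           n_samples) {
  d <- length(init)
  n_obs <- attr(ss_fun, "n_obs")
  draws <- matrix(NA_real_, n_samples, d + 1)
  theta <- init
  ss <- ss_fun(theta)
  sigma2 <- sigma2_init
  scale0 <- (upper - lower) / 50
  cov_emp <- diag(scale0^2, d)
  chol_prop <- chol(2.38^2 / d * cov_emp + diag(1e-12, d))
  accepted <- 0
  acc_window <- 0
  log_sc <- 0  # global proposal scale, adapted toward 23.4% acceptance
  mean_run <- theta
  cov_run <- diag(scale0^2, d)
  for (i in seq_len(n_samples)) {
    prop <- theta + drop(rnorm(d) %*% chol_prop)
    if (all(prop >= lower) && all(prop <= upper)) {
      ss_prop <- ss_fun(prop)
      log_acc <- (ss - ss_prop) / (2 * sigma2)
      if (is.finite(ss_prop) && log(runif(1)) < log_acc) {
        theta <- prop
        ss <- ss_prop
        accepted <- accepted + 1
        acc_window <- acc_window + 1
      }
    }
    # conjugate update of the error variance (scale-invariant prior)
    sigma2 <- (ss / 2) / rgamma(1, shape = n_obs / 2)
    # running moments for the adaptive proposal
    w <- 1 / i
    delta <- theta - mean_run
    mean_run <- mean_run + w * delta
    cov_run <- (1 - w) * (cov_run + w * tcrossprod(delta))
    if (i %% 50 == 0) {
      rate <- acc_window / 50
      acc_window <- 0
      log_sc <- log_sc + (rate - 0.234) / sqrt(i / 50)
      if (i >= 200) {
        cp <- tryCatch(chol(exp(2 * log_sc) * 2.38^2 / d * cov_run +
                              diag(1e-10 * scale0^2, d)),
                       error = function(e) NULL)
        if (!is.null(cp)) chol_prop <- cp
      } else {
        chol_prop <- chol(exp(2 * log_sc) * 2.38^2 / d * cov_emp +
                            diag(1e-12, d))
      }
    }
    draws[i, ] <- c(theta, sqrt(sigma2))
  }
  list(draws = draws, acceptance = accepted / n_samples)
}

#' Adaptive-Metropolis posterior sampling
#'
#' Random-walk Metropolis with an adaptively tuned multivariate Gaussian
#' proposal: the running empirical covariance scaled by `2.38^2 / d`,
#' multiplied by a global factor adapted (Robbins-Monro) toward a 23.4%
#' acceptance rate. Uniform priors on the stated bounds; the Gaussian
#' error variance is sampled from its conjugate conditional between
#' parameter updates. Chains start at the supplied
#' initial point (usually the MLE) with small jitter.
#'
#' @param data outlier-filtered measurement table.
#' @param model a [model_handle()].
#' @param lower,upper named prior bounds (uniform).
#' @param init initial parameter vector; defaults to the centre of the
#'   bounds. Use the MLE in practice.
#' @param n_chains,n_samples,burn_in chain configuration. The defaults are
#'   a desk-scale profile; study-scale settings (4 chains of 250,000 with
#'   50,000 burn-in) are obtained by overriding them.
#' @param seed RNG seed (one sub-stream per chain).
#' @param sigma2_init initial error variance; defaults to the mean squared
#'   residual at `init`.
#' @param channels observed channels.
#' @return An object of class `mcmc_result`: `chains` (array iterations x
#'   parameters x chains, error sd included as `sigma`), `burn_in`,
#'   `summary` (post burn-in mean, sd, quartiles per parameter), `rhat`
#'   (post burn-in, model parameters), `acceptance` per chain.
#' @export
run_mcmc <- function(data, model, lower, upper, init = NULL,
                     n_chains = 4, n_samples = 20000, burn_in = 5000,
                     seed = 1, sigma2_init = NULL,
                     channels = c("R_o", "R_n", "R_i")) {
  stopifnot(all(upper > lower), n_chains >= 1, n_samples > burn_in)
  lower <- lower[model$par_names]
  upper <- upper[model$par_names]
  if (is.null(init)) init <- (lower + upper) / 2
  init <- init[model$par_names]
  ss_fun <- make_ss_fun(data, model, channels)
  n_obs <- attr(ss_fun, "n_obs")
  if (is.null(sigma2_init))
    sigma2_init <- max(ss_fun(init) / n_obs, 1e-6)
  d <- length(init)
  chains <- array(NA_real_, dim = c(n_samples, d + 1, n_chains),
                  dimnames = list(NULL, c(model$par_names, "sigma"), NULL))
  acceptance <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    res <- with_preserved_seed(seed + 7919 * ch, {
      jitter <- pmin(pmax(init * (1 + 0.01 * rnorm(d)), lower), upper)
      mcmc_one_chain(ss_fun, lower, upper, jitter, sigma2_init, n_samples)
    })
    chains[, , ch] <- res$draws
    acceptance[ch] <- res$acceptance
  }
  if (any(acceptance < 0.05 | acceptance > 0.6))
    warning("MCMC acceptance rate outside [0.05, 0.6] after adaptation: ",
            paste(signif(acceptance, 3), collapse = ", "))
  post <- chains[(burn_in + 1):n_samples, , , drop = FALSE]
  flat <- apply(post, 2, c)
  summ <- data.frame(parameter = colnames(flat),
                     mean = colMeans(flat),
                     sd = apply(flat, 2, sd),
                     Q25 = apply(flat, 2, quantile, 0.25),
                     Q50 = apply(flat, 2, quantile, 0.50),
                     Q75 = apply(flat, 2, quantile, 0.75),
                     row.names = NULL)
  structure(list(chains = chains, burn_in = burn_in, summary = summ,
                 rhat = if (n_chains >= 2)
                   rhat(post[, model$par_names, , drop = FALSE])
                 else stats::setNames(rep(NA_real_,
                                          length(model$par_names)),
                                      model$par_names),
                 acceptance = acceptance, lower = lower, upper = upper,
                 model = model, channels = channels),
            class = "mcmc_result")
}

#' Posterior draws after burn-in, pooled across chains
#'
#' @param mcmc an `mcmc_result`.
#' @return Matrix of pooled post burn-in samples.
#' @export
posterior_samples <- function(mcmc) {
  stopifnot(inherits(mcmc, "mcmc_result"))
  post <- mcmc$chains[(mcmc$burn_in + 1):dim(mcmc$chains)[1], , ,
                      drop = FALSE]
  flat <- apply(post, 2, c)
  colnames(flat) <- dimnames(mcmc$chains)[[2]]
  flat
}

#' Posterior prediction intervals
#'
#' Simulates the model at `n_draws` posterior samples over a time grid and
#' reports central quantile bands, per channel and time, at the requested
#' levels. Observation noise (the sampled error sd) is added when
#' `include_noise` is `TRUE`, giving prediction rather than credible bands.
#'
#' @param mcmc an `mcmc_result`.
#' @param model a [model_handle()] (defaults to the one used for
#'   sampling).
#' @param t_grid times \[days\] at which to evaluate the bands.
#' @param n_draws number of posterior draws.
#' @param seed RNG seed.
#' @param levels band levels in percent.
#' @param include_noise add Gaussian observation noise per draw.
#' @return A data frame: `time`, `channel`, `level`, `lower`, `upper`,
#'   `median` (the 50% column of the narrowest band's centre).
#' @export
prediction_intervals <- function(mcmc, model = mcmc$model, t_grid,
                                 n_draws = 200, seed = 1,
                                 levels = c(50, 75, 95, 97.5, 99.5),
                                 include_noise = TRUE) {
  stopifnot(all(diff(t_grid) > 0))
  samples <- posterior_samples(mcmc)
  channels <- model$channels
  with_preserved_seed(seed, {
    idx <- sample.int(nrow(samples), n_draws, replace = n_draws >
                        nrow(samples))
    sims <- array(NA_real_, dim = c(n_draws, length(t_grid),
                                    length(channels)))
    for (k in seq_len(n_draws)) {
      th <- samples[idx[k], model$par_names]
      pred <- tryCatch(model$simulate(th, t_grid), error = function(e) NULL)
      if (is.null(pred)) next
      if (include_noise)
        pred <- pred + rnorm(length(pred), 0, samples[idx[k], "sigma"])
      sims[k, , ] <- pred[, channels]
    }
    out <- list()
    for (ci in seq_along(channels)) {
      for (lev in levels) {
        pr <- c(0.5 - lev / 200, 0.5 + lev / 200)
        qs <- apply(sims[, , ci, drop = FALSE], 2, quantile, probs = pr,
                    na.rm = TRUE)
        med <- apply(sims[, , ci, drop = FALSE], 2, quantile, probs = 0.5,
                     na.rm = TRUE)
        out[[length(out) + 1]] <- data.frame(time = t_grid,
                                             channel = channels[ci],
                                             level = lev, lower = qs[1, ],
                                             upper = qs[2, ], median = med)
      }
    }
    do.call(rbind, out)
  })
}
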