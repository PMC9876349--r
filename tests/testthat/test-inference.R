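# Calibration machinery: outlier rule, likelihood algebra, optimizer,
# profile likelihood, sampler and diagnostics on analytically tractable
# targets plus Greenspan-model recovery.

test_that("quartile outlier rule flags exactly the gross values", {
  expect_equal(flag_outliers(10:18), rep(FALSE, 9))
  flags <- flag_outliers(c(10:18, 1000))
  expect_equal(which(flags), 10)
  expect_equal(flag_outliers(rep(7, 10)), rep(FALSE, 10))
  expect_equal(flag_outliers(c(5, 6, 1000)), rep(FALSE, 3))  # too few
  # NA values neither flagged nor counted
  expect_equal(flag_outliers(c(10:18, NA)), rep(FALSE, 10))
})

test_that("log-likelihood reduces to its closed forms", {
  handle <- toy_mean_handle()
  x <- c(5, 5, 5, 5)
  tab <- toy_mean_table(x)
  n <- length(x)
  # zero residuals
  expect_equal(log_likelihood(5, tab, handle, sigma = 2, channels = "R_o"),
               -(n / 2) * log(2 * pi * 4))
  # doubling sigma with fixed residuals
  tab2 <- toy_mean_table(c(4, 6, 5, 5))
  ss <- 2
  l1 <- log_likelihood(5, tab2, handle, sigma = 1, channels = "R_o")
  l2 <- log_likelihood(5, tab2, handle, sigma = 2, channels = "R_o")
  expect_equal(l1, -(n / 2) * log(2 * pi) - ss / 2)
  expect_equal(l2 - l1, -n * log(2) - ss / (2 * 4) + ss / 2)
  # brute-force per-point summation
  brute <- sum(dnorm(c(4, 6, 5, 5), 5, 1.5, log = TRUE))
  expect_equal(log_likelihood(5, tab2, handle, sigma = 1.5,
                              channels = "R_o"), brute)
})

test_that("likelihood is invariant to row order and missing channels", {
  b <- ground_truth_bundle("normoxia_like")
  tab <- generate_dataset(b$params, b$design, seed = 2)
  handle <- model_handle("greenspan")
  theta <- c(R_o0 = 100, s = 0.6, R_c = 250, gamma = 0.8, Q = 0.7)
  l0 <- log_likelihood(theta, tab, handle, sigma = 4)
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(log_likelihood(theta, perm, handle, sigma = 4), l0)
  tab_na <- tab
  tab_na$R_n_um[1:5] <- NA
  l_na <- log_likelihood(theta, tab_na, handle, sigma = 4)
  expect_false(isTRUE(all.equal(l_na, l0)))
  expect_true(is.finite(l_na))
  # unsimulable parameters are rejected with -Inf, not an error
  bad <- c(R_o0 = -5, s = 0.6, R_c = 250, gamma = 0.8, Q = 0.7)
  expect_identical(log_likelihood(bad, tab, handle, sigma = 4), -Inf)
})

test_that("multistart optimisation solves a quadratic exactly and is deterministic", {
  handle <- toy_mean_handle()
  x <- c(3.2, 4.8, 5.1, 4.4, 3.9)
  tab <- toy_mean_table(x)
  fit <- fit_mle(tab, handle, lower = c(mu = 0), upper = c(mu = 10),
                 n_starts = 5, seed = 2, channels = "R_o")
  expect_equal(unname(fit$theta_hat), mean(x), tolerance = 1e-7)
  expect_equal(fit$sigma_hat, sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-6)
  fit2 <- fit_mle(tab, handle, lower = c(mu = 0), upper = c(mu = 10),
                  n_starts = 5, seed = 2, channels = "R_o")
  expect_identical(fit$theta_hat, fit2$theta_hat)
})

test_that("profile CI on the Gaussian mean equals the analytic interval", {
  handle <- toy_mean_handle()
  set.seed(14)
  x <- rnorm(40, 10, 2)
  tab <- toy_mean_table(x)
  fit <- fit_mle(tab, handle, lower = c(mu = 0), upper = c(mu = 20),
                 n_starts = 3, seed = 1, channels = "R_o")
  pr <- profile_likelihood(tab, handle, fit, "mu",
                           grid = seq(8, 12, length.out = 41),
                           channels = "R_o", sigma = 2)
  expected <- mean(x) + c(-1, 1) * sqrt(2 * 1.92) * 2 / sqrt(40)
  expect_equal(pr$ci95, expected, tolerance = 1e-6)
  expect_equal(max(pr$profile$loglik), 0)
  expect_true(pr$ci95[1] <= pr$mle && pr$mle <= pr$ci95[2])
  expect_false(pr$multimodal)
})

test_that("wider measurement noise never narrows the profile CI", {
  handle <- toy_mean_handle()
  widths <- vapply(c(0.5, 1, 2, 4), function(s) {
    set.seed(7)
    x <- 10 + s * rnorm(30)
    tab <- toy_mean_table(x)
    fit <- fit_mle(tab, handle, lower = c(mu = 0), upper = c(mu = 20),
                   n_starts = 3, seed = 1, channels = "R_o")
    pr <- profile_likelihood(tab, handle, fit, "mu",
                             grid = seq(5, 15, length.out = 41),
                             channels = "R_o")
    diff(pr$ci95)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("R-hat is exactly one for identical chains and detects divergence", {
  set.seed(15)
  x <- rnorm(500)
  ident <- cbind(x, x, x)
  expect_equal(unname(rhat(ident)), 1, tolerance = 1e-12)
  same <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(rhat(same), 1.01)
  disjoint <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  r <- rhat(disjoint)
  expect_gt(r, 3)
  # brute-force evaluation of the documented formula
  W <- mean(apply(disjoint, 2, var))
  B <- 1000 * var(colMeans(disjoint))
  expect_equal(unname(r), sqrt(1 + B / (1000 * W)), tolerance = 1e-12)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "two chains")
})

test_that("sampler recovers a known Gaussian target", {
  # two independent means observed with noise: posterior centred on the
  # sample means
  handle <- structure(list(
    simulate = function(theta, days) {
      days <- sort(unique(days))
      cbind(R_o = theta[match(days, c(1, 2))], R_n = NA_real_,
            R_i = NA_real_)
    },
    par_names = c("mu1", "mu2"), channels = "R_o", model = "toy2"),
    class = "model_handle")
  set.seed(16)
  n_per <- 25
  x1 <- rnorm(n_per, 4, 1)
  x2 <- rnorm(n_per, 7, 1)
  tab <- data.frame(spheroid_id = 1:(2 * n_per),
                    day = rep(c(1, 2), each = n_per), condition = "toy",
                    R_o_um = c(x1, x2), R_n_um = NA_real_,
                    R_i_um = NA_real_, R_p_um = NA_real_)
  res <- run_mcmc(tab, handle, lower = c(mu1 = 0, mu2 = 0),
                  upper = c(mu1 = 10, mu2 = 10),
                  init = c(mu1 = 5, mu2 = 5), n_chains = 2,
                  n_samples = 6000, burn_in = 1000, seed = 3,
                  channels = "R_o")
  post <- posterior_samples(res)
  se <- 1 / sqrt(n_per)
  expect_lt(abs(mean(post[, "mu1"]) - mean(x1)), 3 * se)
  expect_lt(abs(mean(post[, "mu2"]) - mean(x2)), 3 * se)
  expect_true(all(res$rhat < 1.1))
  expect_true(all(post[, "mu1"] >= 0 & post[, "mu1"] <= 10))
  # summary quantiles are order-consistent
  s <- res$summary
  expect_true(all(s$Q25 <= s$Q50 & s$Q50 <= s$Q75))
})

test_that("the posterior concentrates on the MLE as the noise vanishes", {
  b <- ground_truth_bundle("normoxia_like")
  design <- experimental_design("normoxia", days = c(2, 4, 6, 8),
                                n_per_day = 6, sigma = 0.3, seed = 88)
  tab <- generate_dataset(b$params, design)
  handle <- model_handle("greenspan")
  lower <- c(R_o0 = 60, s = 0.2, R_c = 150, gamma = 0.2, Q = 0.4)
  upper <- c(R_o0 = 160, s = 1.2, R_c = 350, gamma = 1.6, Q = 1.0)
  fit <- fit_mle(tab, handle, lower, upper, n_starts = 6, seed = 5)
  res <- run_mcmc(tab, handle, lower, upper, init = fit$theta_hat,
                  n_chains = 2, n_samples = 4000, burn_in = 1000,
                  seed = 6)
  post <- posterior_samples(res)
  for (par in handle$par_names) {
    mc_se <- 3 * sd(post[, par])
    expect_lt(abs(mean(post[, par]) - fit$theta_hat[[par]]),
              mc_se + 0.01 * abs(fit$theta_hat[[par]]))
  }
})

test_that("prediction bands collapse for a degenerate posterior and nest by level", {
  b <- ground_truth_bundle("normoxia_like")
  tab <- generate_dataset(b$params, b$design, seed = 4)
  handle <- model_handle("greenspan")
  theta <- c(R_o0 = 100, s = 0.6, R_c = 250, gamma = 0.8, Q = 0.7)
  # degenerate: a single repeated posterior sample with sigma = 0
  fake_chain <- array(rep(c(theta, 0), each = 60),
                      dim = c(60, 6, 2),
                      dimnames = list(NULL, c(names(theta), "sigma"),
                                      NULL))
  fake <- structure(list(chains = fake_chain, burn_in = 10,
                         model = handle), class = "mcmc_result")
  bands <- prediction_intervals(fake, handle, t_grid = c(2, 4, 6, 8),
                                n_draws = 20, seed = 1,
                                include_noise = TRUE)
  tr <- solve_greenspan(b$params, c(0, 2, 4, 6, 8))
  for (d in c(2, 4, 8)) {
    band <- bands[bands$channel == "R_o" & bands$time == d, ]
    expect_equal(band$lower, band$upper)
    expect_equal(band$lower[1], tr$R_o[tr$time == d], tolerance = 1e-9)
  }
  expect_true(all(bands$lower <= bands$upper))
})

test_that("staged pipeline runs end-to-end and brackets the consumption timescale", {
  nb <- ground_truth_bundle("normoxia_like")
  hb <- ground_truth_bundle("hypoxia_like")
  d0 <- ground_truth_bundle("deoxy_like")$params
  # fast shell death makes the core track its quasi-steady value within
  # hours of the switch, so the stage-4 inversion assumption holds
  d <- deoxygenation_params(
    R_o0 = d0$R_o0, R_c_n = d0$R_c_n, R_c_h = d0$R_c_h,
    tau_alpha = d0$tau_alpha, Rbar_n = d0$Rbar_n, Rbar_h = d0$Rbar_h,
    tau_Rbar = d0$tau_Rbar, s_n = d0$s_n, s_h = d0$s_h, tau_s = d0$tau_s,
    lambda_n = d0$lambda_n, lambda_h = d0$lambda_h,
    tau_lambda = d0$tau_lambda, lambda_hat0 = 30, tau_lambda_hat = 2,
    t_s = 2)
  tab_n <- generate_dataset(nb$params, nb$design, seed = 61)
  tab_h <- generate_dataset(hb$params, hb$design, seed = 62)
  dd <- experimental_design("deoxygenation",
                            days = c(2, 2.1, 2.25, 2.5, 3, 4, 6, 8),
                            n_per_day = 8, sigma = 2, seed = 63)
  tab_d <- generate_dataset(d, dd)
  cal <- suppressWarnings(staged_deoxygenation_calibration(
    tab_n, tab_h, tab_d, t_s = 2,
    mcmc = list(n_chains = 2, n_samples = 1500, burn_in = 500),
    n_starts = 6, seed = 71))
  expect_s3_class(cal, "staged_calibration")
  expect_named(cal, paste0("stage", 1:6))
  # stage 2 recovers the snapshot scales of both conditions
  expect_equal(cal$stage2$normoxia$R_c$mean, nb$params$R_c,
               tolerance = 0.03)
  expect_equal(cal$stage2$hypoxia$R_c$mean, hb$params$R_c,
               tolerance = 0.03)
  # stage 4: consumption-rate adaptation timescale inside its posterior CI
  post_tau <- posterior_samples(cal$stage4$u$mcmc)[, "tau"]
  ci <- quantile(post_tau, c(0.025, 0.975))
  expect_true(ci[1] <= d$tau_alpha && d$tau_alpha <= ci[2])
  # stage 5/6 produce a finite posterior and sensible coverage
  expect_true(all(is.finite(cal$stage5$fit$theta_hat)))
  expect_gte(cal$stage6$coverage95, 0.8)
})

test_that("staged calibration recovers snapshot scales and the adaptation timescale", {
  # noiseless constant-condition tables make stage-2 inversions exact
  nb <- ground_truth_bundle("normoxia_like")
  hb <- ground_truth_bundle("hypoxia_like")
  db <- ground_truth_bundle("deoxy_like")
  tab_n0 <- generate_dataset(nb$params,
                             experimental_design("normoxia", sigma = 0))
  snap <- snapshot_estimates_table(tab_n0, 21)
  iii <- snap$phase == "phase_iii" & !is.na(snap$phase)
  expect_true(any(iii))
  expect_equal(unique(round(snap$R_c[iii], 6)), nb$params$R_c,
               tolerance = 1e-6)
  # stage-4 style relaxation fit on per-snapshot estimates
  d <- db$params
  # early post-switch snapshots resolve the fast relaxation
  days <- rep(c(2.05, 2.1, 2.2, 2.35, 2.5, 3, 4, 6, 8), each = 6)
  truth <- relax(d$Rbar_n, d$Rbar_h, d$tau_Rbar, days, d$t_s)
  set.seed(17)
  vals <- truth + rnorm(length(days), 0, 3)
  rf <- fit_relaxation(days, vals, t_s = d$t_s,
                       lower = c(50, 50, 0.02), upper = c(300, 300, 5),
                       n_starts = 20,
                       mcmc = list(n_chains = 2, n_samples = 3000,
                                   burn_in = 800), seed = 9)
  post_tau <- posterior_samples(rf$mcmc)[, "tau"]
  ci <- quantile(post_tau, c(0.025, 0.975))
  expect_true(ci[1] <= d$tau_Rbar && d$tau_Rbar <= ci[2])
  expect_equal(rf$v_from, d$Rbar_n, tolerance = 0.15)
  expect_equal(rf$v_to, d$Rbar_h, tolerance = 0.15)
})
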