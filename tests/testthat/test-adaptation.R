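# Switching models: parameter relaxation, shell death / clearance terms,
# continuity across the switch, long-time limits and oracle agreement.

test_that("exponential relaxation has the stated values and limits", {
  expect_equal(relax(10, 4, 1, 3, 2), 4 + 6 / exp(1))
  expect_equal(relax(10, 4, 1, 3, 2), 6.207277, tolerance = 1e-6)
  expect_equal(relax(10, 4, 0.5, 2, 2), 10)          # continuity at switch
  expect_equal(relax(10, 4, 0.5, 100, 2), 4, tolerance = 1e-12)
  expect_error(relax(10, 4, 1, 1.5, 2), "t >= t_s")
})

test_that("shell death rate grows exponentially from its initial value", {
  expect_equal(lambda_hat(2, 0.3, 2, 2), 0.3)
  expect_equal(lambda_hat(4, 0.3, 2, 2), 0.3 * exp(1))
  tt <- seq(2, 10, by = 0.5)
  expect_true(all(diff(lambda_hat(tt, 0.3, 2, 2)) > 0))
  expect_error(lambda_hat(1, 0.3, 2, 2), "t >= t_s")
})

test_that("necrotic volume balance has its closed-form and fixed-point limits", {
  V_plus <- 4 * pi / 3 * 80^3
  # lambda = 0, constant coefficients: V_n(t) = V_plus (1 - exp(-3 lhat t))
  f <- function(t, V) necrotic_volume_rhs(V, 80, 0, 0.4)
  V_end <- rk4_path(f, 0, 0, 2, dt = 1e-4)
  expect_equal(V_end, V_plus * (1 - exp(-3 * 0.4 * 2)), tolerance = 1e-6)
  expect_equal(necrotic_volume_rhs(V_plus, 80, 0, 0.4), 0)
})

test_that("predicted necrotic radius jumps above the core at deoxygenation", {
  b <- ground_truth_bundle("deoxy_like")$params
  tr <- solve_deoxygenation(b, c(0, b$t_s, b$t_s + 1e-3, 8))
  at_switch <- tr[tr$time == b$t_s, ]
  expect_gt(at_switch$R_n_plus, at_switch$R_n)
  # also from phase (ii)/(iii) pre-switch states
  for (Ro in c(150, 220, 300)) {
    rn_pre <- necrotic_radius(Ro, b$R_c_n)
    rn_post <- predicted_necrotic_radius(Ro, sqrt(b$p_inf_post /
                                                    (b$p_inf_pre /
                                                       b$R_c_n^2)))
    expect_gt(rn_post, rn_pre)
  }
})

test_that("degenerate switch with equal endpoints reproduces the constant model", {
  g <- greenspan_params(100, s = 0.6, R_c = 250, gamma = 0.8, Q = 0.7)
  # endpoints equal, no shell death; ambient pressures chosen so the
  # lumped consumption is unchanged across the switch
  d <- deoxygenation_params(R_o0 = 100, R_c_n = 250, R_c_h = 250,
                            tau_alpha = 0.5, Rbar_n = 175, Rbar_h = 175,
                            tau_Rbar = 0.5, s_n = 0.6, s_h = 0.6,
                            tau_s = 0.5, lambda_n = 0.48, lambda_h = 0.48,
                            tau_lambda = 0.5, lambda_hat0 = 0,
                            tau_lambda_hat = 1, t_s = 2, p_inf_pre = 21,
                            p_inf_post = 21)
  # exact no-op over the window before the necrotic core forms (with no
  # shell death the switching model cannot seed a core, so the comparison
  # is exact only there)
  times <- c(0, 2, 3, 4, 4.5)
  trd <- solve_deoxygenation(d, times)
  trg <- solve_greenspan(g, times)
  expect_true(all(trg$R_n == 0))
  expect_equal(trd$R_o, trg$R_o, tolerance = 1e-6)
  expect_equal(trd$R_i, trg$R_i, tolerance = 1e-4)
  # with fast shell death the dynamic core tracks the algebraic one and the
  # full trajectories agree closely
  d2 <- deoxygenation_params(R_o0 = 100, R_c_n = 250, R_c_h = 250,
                             tau_alpha = 0.5, Rbar_n = 175, Rbar_h = 175,
                             tau_Rbar = 0.5, s_n = 0.6, s_h = 0.6,
                             tau_s = 0.5, lambda_n = 0.48,
                             lambda_h = 0.48, tau_lambda = 0.5,
                             lambda_hat0 = 100, tau_lambda_hat = 1,
                             t_s = 2, p_inf_pre = 21, p_inf_post = 21)
  times2 <- c(0, 2, 4, 6, 8)
  trd2 <- solve_deoxygenation(d2, times2)
  trg2 <- solve_greenspan(g, times2)
  expect_equal(trd2$R_o, trg2$R_o, tolerance = 0.01)
  expect_equal(trd2$R_n, trg2$R_n, tolerance = 0.02)
})

test_that("state and coefficients are continuous across the switch", {
  b <- ground_truth_bundle("deoxy_like")$params
  eps <- 1e-6
  tr <- solve_deoxygenation(b, c(0, b$t_s - eps, b$t_s + eps, 8))
  expect_lt(abs(tr$R_o[3] - tr$R_o[2]), 1e-3)
  # core volume grows at most at its initial shell-death rate over eps
  v_plus <- 4 * pi / 3 * tr$R_n_plus[3]^3
  expect_lt(abs(tr$V_n[3] - tr$V_n[2]),
            2 * eps * 3 * b$lambda_hat0 * v_plus + 1e-6)
  expect_equal(tr$s_t[3], b$s_n, tolerance = 1e-4)
  expect_equal(tr$lambda_t[3], b$lambda_n, tolerance = 1e-4)
  expect_equal(tr$Rbar_t[3], b$Rbar_n, tolerance = 1e-3)
  expect_equal(tr$R_c_t[3], sqrt(b$p_inf_post / (b$p_inf_pre / b$R_c_n^2)),
               tolerance = 1e-3)
})

test_that("deoxygenation relaxes to the hypoxia endpoints with core tracking", {
  b <- ground_truth_bundle("deoxy_like")$params
  t_end <- b$t_s + 20 * b$tau_lambda_hat
  tr <- solve_deoxygenation(b, c(0, b$t_s, t_end))
  last <- tr[nrow(tr), ]
  expect_equal(last$s_t, b$s_h, tolerance = 1e-6)
  expect_equal(last$lambda_t, b$lambda_h, tolerance = 1e-6)
  expect_equal(last$Rbar_t, b$Rbar_h, tolerance = 1e-6)
  expect_equal(last$R_c_t, b$R_c_h, tolerance = 1e-6)
  expect_lt(abs(last$R_n - last$R_n_plus), 0.5)
  # structure fractions approach the pure-hypoxia constant-model values
  gh <- greenspan_params(b$R_o0, s = b$s_h, R_c = b$R_c_h,
                         lambda = b$lambda_h, Rbar = b$Rbar_h)
  trh <- solve_greenspan(gh, c(0, 50))
  trd <- solve_deoxygenation(b, c(0, b$t_s, 50))
  i <- nrow(trd); j <- nrow(trh)
  expect_lt(abs(trd$R_n[i] / trd$R_o[i] - trh$R_n[j] / trh$R_o[j]), 0.02)
  expect_lt(abs(trd$R_i[i] / trd$R_o[i] - trh$R_i[j] / trh$R_o[j]), 0.02)
})

test_that("deoxygenation matches an independent lsoda integration post-switch", {
  set.seed(41)
  for (i in 1:5) {
    p <- deoxygenation_params(
      R_o0 = runif(1, 80, 130), R_c_n = runif(1, 200, 300),
      R_c_h = runif(1, 100, 150), tau_alpha = runif(1, 0.1, 1),
      Rbar_n = runif(1, 150, 200), Rbar_h = runif(1, 80, 120),
      tau_Rbar = runif(1, 0.1, 1), s_n = runif(1, 0.4, 0.8),
      s_h = runif(1, 0.5, 1), tau_s = runif(1, 0.5, 2),
      lambda_n = runif(1, 0.3, 0.7), lambda_h = runif(1, 0.5, 1.2),
      tau_lambda = runif(1, 0.5, 2), lambda_hat0 = runif(1, 0.1, 0.5),
      tau_lambda_hat = runif(1, 1, 3), t_s = 2)
    tr <- solve_deoxygenation(p, c(0, 2, 4, 6))
    start <- tr[tr$time == 2, ]
    sol <- deSolve::lsoda(c(start$R_o, start$V_n), c(2, 4, 6),
                          function(t, y, parms)
                            list(oracle_deoxy_rhs(t, y, parms)),
                          parms = p, rtol = 1e-10, atol = 1e-8)
    expect_equal(tr$R_o[tr$time %in% c(4, 6)], sol[2:3, 2],
                 tolerance = 1e-4)
    expect_equal(tr$V_n[tr$time %in% c(4, 6)], sol[2:3, 3],
                 tolerance = 1e-3)
  }
})

test_that("outer radius stalls after deoxygenation while the core fraction grows", {
  b <- ground_truth_bundle("deoxy_like")$params
  tr <- solve_deoxygenation(b, c(0, b$t_s, b$t_s + 6))
  i_s <- which(tr$time == b$t_s)
  i_e <- nrow(tr)
  expect_lt(abs(tr$R_o[i_e] / tr$R_o[i_s] - 1), 0.15)
  expect_gt(tr$R_n[i_e] / tr$R_o[i_e] - tr$R_n[i_s] / tr$R_o[i_s], 0.2)
})

test_that("re-oxygenation clears the core monotonically when nothing recovers", {
  b <- ground_truth_bundle("reoxy_like")$params
  p0 <- reoxygenation_params(
    R_o0 = b$R_o0, R_n0 = b$R_n0, R_c_n = b$R_c_n, R_c_h = b$R_c_h,
    tau_alpha = b$tau_alpha, Rbar_n = b$Rbar_n, Rbar_h = b$Rbar_h,
    tau_Rbar = b$tau_Rbar, s_n = b$s_n, s_h = b$s_h, tau_s = b$tau_s,
    lambda_n = b$lambda_n, lambda_h = b$lambda_h,
    tau_lambda = b$tau_lambda, lambda_tilde0 = 40,
    tau_lambda_tilde = b$tau_lambda_tilde, nu = 0, t_s = b$t_s,
    p_inf_pre = b$p_inf_pre, p_inf_post = b$p_inf_post)
  tt <- seq(b$t_s, b$t_s + 1.5, by = 0.02)
  tr <- solve_reoxygenation(p0, c(0, tt))
  post <- tr[tr$time >= b$t_s, ]
  shrinking <- post$R_n > post$R_n_plus + 1e-6
  expect_true(all(diff(post$V_n)[shrinking[-1]] <= 1e-6))
  expect_true(all(post$V_n >= 0))
})

test_that("volume bookkeeping balances exactly when all cleared volume recovers", {
  b <- ground_truth_bundle("reoxy_like")$params
  p1 <- reoxygenation_params(
    R_o0 = b$R_o0, R_n0 = b$R_n0, R_c_n = b$R_c_n, R_c_h = b$R_c_h,
    tau_alpha = b$tau_alpha, Rbar_n = b$Rbar_n, Rbar_h = b$Rbar_h,
    tau_Rbar = b$tau_Rbar, s_n = b$s_n, s_h = b$s_h, tau_s = b$tau_s,
    lambda_n = b$lambda_n, lambda_h = b$lambda_h,
    tau_lambda = b$tau_lambda, lambda_tilde0 = b$lambda_tilde0,
    tau_lambda_tilde = b$tau_lambda_tilde, nu = 1, t_s = b$t_s,
    p_inf_pre = b$p_inf_pre, p_inf_post = b$p_inf_post)
  # audit: with nu = 1 the total-volume rate equals production minus
  # necrotic degradation, with no clearance leakage
  h <- 1e-5
  for (t0 in b$t_s + c(0.05, 0.15, 0.4)) {
    tr <- solve_reoxygenation(p1, c(0, t0 - h, t0, t0 + h))
    Vo <- 4 * pi / 3 * tr$R_o^3
    dVo <- (Vo[4] - Vo[2]) / (2 * h)
    mid <- tr[3, ]
    expected <- mid$s_t * (4 * pi / 3) *
      (mid$R_o^3 - max(mid$R_i, mid$R_n)^3) -
      3 * mid$lambda_t * mid$V_n
    expect_equal(dVo, expected, tolerance = 1e-5)
  }
})

test_that("re-oxygenation preset passes through the growth phases in reverse", {
  r <- ground_truth_bundle("reoxy_like")
  tv <- solve_reoxygenation(r$params, seq(0, 8, by = 0.02))
  post <- tv[tv$time >= r$params$t_s, ]
  seqs <- rle(post$phase)$values
  expect_equal(seqs[1], "phase_iii")
  # the reversal and regrowth: iii -> ii -> i -> ii -> iii
  expect_true(all(c("phase_iii", "phase_ii", "phase_i", "phase_ii",
                    "phase_iii") == seqs))
})

test_that("instant and frozen adaptation limits behave as the timescales dictate", {
  b <- ground_truth_bundle("deoxy_like")$params
  make <- function(tau) deoxygenation_params(
    R_o0 = b$R_o0, R_c_n = b$R_c_n, R_c_h = b$R_c_h, tau_alpha = tau,
    Rbar_n = b$Rbar_n, Rbar_h = b$Rbar_h, tau_Rbar = tau, s_n = b$s_n,
    s_h = b$s_h, tau_s = tau, lambda_n = b$lambda_n,
    lambda_h = b$lambda_h, tau_lambda = tau, lambda_hat0 = b$lambda_hat0,
    tau_lambda_hat = b$tau_lambda_hat, t_s = b$t_s,
    p_inf_pre = b$p_inf_pre, p_inf_post = b$p_inf_post)
  t_eval <- c(0, b$t_s, b$t_s + 0.5, 8)
  fast <- solve_deoxygenation(make(1e-6), t_eval)
  frozen <- solve_deoxygenation(make(1e6), t_eval)
  i <- 3
  expect_equal(fast$s_t[i], b$s_h, tolerance = 1e-9)
  expect_equal(fast$Rbar_t[i], b$Rbar_h, tolerance = 1e-6)
  expect_equal(frozen$s_t[i], b$s_n, tolerance = 1e-6)
  expect_equal(frozen$Rbar_t[i], b$Rbar_n, tolerance = 1e-3)
})

test_that("core radius and volume stay mutually consistent", {
  b <- ground_truth_bundle("deoxy_like")$params
  tr <- solve_deoxygenation(b, seq(0, 8, by = 0.5))
  expect_equal(tr$R_n, (3 * tr$V_n / (4 * pi))^(1 / 3), tolerance = 1e-9)
  expect_true(all(tr$V_n >= 0))
})
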