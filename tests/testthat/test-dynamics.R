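test_that("pure decay and fixed points match the closed forms", {
  zero_in <- build_input(shock_schedule(NULL, 200), 0, 0, 1)
  pp <- cell_params(1, 0.1, 2, 0.01)
  st <- simulate_expression(pp, zero_in, c(0, log(2) / 0.01, 200),
                            init = c(0, 100))
  expect_equal(st$p[2], 50, tolerance = 1e-12)
  # constant u = 1: steady state m* = k_m/g_m, p* = k_p m*/g_p
  st2 <- simulate_expression(pp, const_input(1, 3000, 10),
                             seq(0, 3000, 50))
  expect_equal(tail(st2$m, 1), 10, tolerance = 1e-6)
  expect_equal(tail(st2$p, 1), 2000, tolerance = 1e-3)
})

test_that("exact propagation matches the fine-step RK4 oracle", {
  set.seed(11)
  for (rep in 1:5) {
    sched <- shock_schedule(cbind(c(20, 80), c(20, 80) + runif(2, 4, 10)),
                            150)
    inp <- build_input(sched, 2, runif(1, 0, 4), 0.5)
    pp <- cell_params(exp(rnorm(1, log(4), 0.4)),
                      exp(rnorm(1, log(0.08), 0.3)),
                      exp(rnorm(1, log(1), 0.3)),
                      exp(rnorm(1, log(0.006), 0.3)))
    tt <- seq(0, 150, 3)
    a <- simulate_expression(pp, inp, tt)
    b <- simulate_rk4(pp, inp, tt, h = 0.001)
    expect_lt(max(abs(a$p - b$p)) / max(abs(b$p)), 1e-6)
    expect_lt(max(abs(a$m - b$m)) / max(abs(b$m)), 1e-6)
  }
})

test_that("degenerate equal decay rates use the stable limit branch", {
  inp <- const_input(1, 100, 1)
  pp <- cell_params(1, 0.05, 1, 0.05)
  tt <- seq(0, 100, 2)
  a <- simulate_expression(pp, inp, tt)
  b <- simulate_rk4(pp, inp, tt, h = 0.001)
  expect_lt(max(abs(a$p - b$p)) / max(abs(b$p)), 1e-6)
  # near-degenerate must agree with degenerate continuously
  pp2 <- cell_params(1, 0.05, 1, 0.05 * (1 + 1e-9))
  a2 <- simulate_expression(pp2, inp, tt)
  expect_equal(a2$p, a$p, tolerance = 1e-6)
})

test_that("refining the grid beyond the input breakpoints changes nothing", {
  inp <- build_input(toy_schedule(), 2, 2, 0.5)
  pp <- cell_params(4, 0.08, 1, 0.006)
  coarse <- seq(0, 200, 10)
  fine <- seq(0, 200, 0.25)
  a <- simulate_expression(pp, inp, coarse)
  b <- simulate_expression(pp, inp, fine)
  expect_equal(a$p, b$p[match(coarse, fine)], tolerance = 1e-12)
})

test_that("scaling symmetry: (c k_m, k_p/c) leaves p and loglik invariant", {
  inp <- build_input(toy_schedule(), 2, 2, 0.5)
  tt <- seq(0, 200, 6)
  base <- cell_params(4, 0.08, 1, 0.006)
  p_ref <- simulate_expression(base, inp, tt)$p
  set.seed(3)
  traj <- cell_trajectory("c1", tt,
                          p_ref * (1 + 0.1 * rnorm(length(tt))) +
                            5 * rnorm(length(tt)))
  err <- error_model(5, 0.1)
  ll_ref <- cell_loglik(traj, base, 6, err, inp)
  for (cc in c(0.1, 10)) {
    sc <- cell_params(cc * 4, 0.08, 1 / cc, 0.006)
    st <- simulate_expression(sc, inp, tt)
    expect_equal(st$p, p_ref, tolerance = 1e-12)
    expect_equal(st$m, cc * simulate_expression(base, inp, tt)$m,
                 tolerance = 1e-12)
    expect_equal(cell_loglik(traj, sc, 6, err, inp), ll_ref,
                 tolerance = 1e-12)
  }
})

test_that("observation model has the stated moments and is seed-stable", {
  inp <- const_input(0, 100, 1)
  pp <- cell_params(1e-6, 0.1, 1e-6, 0.01)
  st <- simulate_expression(pp, inp, seq(0, 100, 1), init = c(0, 50))
  st$p[] <- 50  # constant protein level
  err <- error_model(3, 0.2)
  set.seed(42)
  y <- replicate(2000, observe_fluorescence(st, 6, seq(10, 90, 10), err))
  sd_th <- sqrt(3^2 + 50^2 * 0.2^2)
  expect_equal(mean(y), 50, tolerance = 4 * sd_th / sqrt(length(y)))
  expect_equal(sd(y), sd_th, tolerance = 0.05 * sd_th)
  # near-zero noise reproduces the delayed protein level
  tiny <- error_model(1e-12, 0)
  y0 <- observe_fluorescence(st, 6, c(20, 40), tiny)
  expect_equal(y0, c(50, 50), tolerance = 1e-9)
  # determinism under a fixed seed
  set.seed(7); a <- observe_fluorescence(st, 6, seq(0, 90, 6), err)
  set.seed(7); b <- observe_fluorescence(st, 6, seq(0, 90, 6), err)
  expect_identical(a, b)
})

test_that("loglik equals the brute-force Gaussian density sum", {
  inp <- build_input(toy_schedule(), 2, 2, 0.5)
  pp <- cell_params(4, 0.08, 1, 0.006)
  tt <- seq(0, 60, 6)
  tau <- 6
  err <- error_model(2, 0.05)
  set.seed(5)
  yv <- abs(rnorm(length(tt), 50, 20))
  traj <- cell_trajectory("c1", tt, yv)
  # independent oracle: simulate, delay, per-point dnorm summation
  st <- simulate_expression(pp, inp, seq(0, 60, 0.5), init = c(0, yv[1]))
  pd <- approx(st$times, st$p, xout = pmax(tt - tau, 0), rule = 2)$y
  oracle <- sum(dnorm(yv, pd, sqrt(2^2 + 0.05^2 * pd^2), log = TRUE))
  expect_equal(cell_loglik(traj, pp, tau, err, inp,
                           init_policy = c(0, yv[1])),
               oracle, tolerance = 1e-10)
})

test_that("zero residuals give the pure normalization term", {
  inp <- const_input(0, 100, 1)
  tt <- seq(0, 90, 10)
  traj <- cell_trajectory("c1", tt, rep(0, length(tt)))
  pp <- cell_params(1e-9, 0.1, 1e-9, 0.01)
  ll1 <- cell_loglik(traj, pp, 0, error_model(1, 0), inp,
                     init_policy = c(0, 0))
  expect_equal(ll1, -10 / 2 * log(2 * pi), tolerance = 1e-6)
  # doubling sigma_add with zero residuals strictly decreases loglik
  ll2 <- cell_loglik(traj, pp, 0, error_model(2, 0), inp,
                     init_policy = c(0, 0))
  expect_lt(ll2, ll1)
})
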