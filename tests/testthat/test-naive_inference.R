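# A tiny noise-light study used across the fitting tests: founders only so
# every cell shows the full response.
mini_study <- function(n = 15, seed = 71, sigma_add = 2,
                       sigma_mult = 0.02) {
  pop <- default_population(sigma_add = sigma_add, sigma_mult = sigma_mult)
  generate_study(study_config(n_cells = n, founder_frac = 1, gain_sd = 0,
                              population = pop), seed = seed)
}

test_that("per-cell ML fit is a fixed point at a noise-free optimum", {
  st <- mini_study(n = 3, sigma_add = 1e-6, sigma_mult = 1e-9)
  input <- build_input(st$schedule)
  tp <- st$truth$params
  i <- 1
  truth <- cell_params(tp$k_m[i], tp$g_m[i], tp$k_p[i], tp$g_p[i])
  set.seed(1)
  f <- fit_cell_ml(st$trajectories[[i]], input, truth, 12,
                   error_model(1e-3, 1e-6), n_restarts = 1)
  expect_true(f$converged)
  expect_equal(f$params[["k_mp"]], truth[["k_mp"]], tolerance = 1e-3)
  expect_equal(f$params[["g_p"]], truth[["g_p"]], tolerance = 1e-2)
})

test_that("scaling-degenerate starts reach equal loglik and equal k_mp", {
  st <- mini_study(n = 3)
  input <- build_input(st$schedule)
  tp <- st$truth$params
  i <- 2
  err <- error_model(2, 0.02)
  th0 <- cell_params(tp$k_m[i], tp$g_m[i], tp$k_p[i], tp$g_p[i])
  cc <- 3
  th1 <- cell_params(cc * tp$k_m[i], tp$g_m[i], tp$k_p[i] / cc, tp$g_p[i])
  set.seed(2)
  f0 <- fit_cell_ml(st$trajectories[[i]], input, th0, 12, err,
                    n_restarts = 1)
  f1 <- fit_cell_ml(st$trajectories[[i]], input, th1, 12, err,
                    n_restarts = 1)
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-4)
  expect_equal(f0$params[["k_mp"]], f1$params[["k_mp"]], tolerance = 1e-3)
})

test_that("a flat zero trajectory drives k_mp to the box boundary", {
  input <- build_input(toy_schedule())
  tt <- seq(0, 200, 6)
  traj <- cell_trajectory("flat", tt, rep(0, length(tt)))
  set.seed(3)
  f <- fit_cell_ml(traj, input, literature_params(), 6,
                   error_model(1, 0.01), n_restarts = 1)
  expect_true(f$at_bound)
  expect_lt(f$params[["k_mp"]], literature_params()[["k_mp"]] * exp(-5))
})

test_that("pooling matches a two-pass moment oracle and is permutation
           invariant", {
  set.seed(4)
  n <- 50
  Z <- matrix(rnorm(4 * n), n)
  pc <- data.frame(cell_id = as.character(1:n), k_m = exp(Z[, 1]),
                   g_m = exp(Z[, 2]), k_p = exp(Z[, 3]), g_p = exp(Z[, 4]),
                   loglik = rnorm(n), converged = TRUE)
  pool <- pool_population(pc, 12, error_model(10, 0.1))
  expect_equal(pool$mu, colMeans(Z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pool$sigma, cov(Z), tolerance = 1e-12, ignore_attr = TRUE)
  perm <- pool_population(pc[sample(n), ], 12, error_model(10, 0.1))
  expect_equal(perm$mu, pool$mu)
  expect_equal(perm$sigma, pool$sigma)
  # all-identical cells give a zero covariance
  pc1 <- pc; pc1[, 2:5] <- rep(as.numeric(pc1[1, 2:5]), each = n)
  expect_equal(max(abs(pool_population(pc1, 12,
                                       error_model(10, 0.1))$sigma)), 0)
  # too few cells is an error
  expect_error(pool_population(pc[1:4, ], 12, error_model(10, 0.1)),
               "fewer than 5")
})

test_that("mean-cell fit recovers the shared delay and predicts the
           median trajectory", {
  st <- mini_study(n = 20, seed = 72)
  input <- build_input(st$schedule)
  set.seed(5)
  mc <- fit_mean_cell(st, input, n_starts = 4)
  expect_false(mc$at_bound)
  expect_equal(mc$tau_min, 12, tolerance = 0.25)
  med <- mecell:::median_trajectory(st)
  pred <- predict_cells(structure(list(trajectories = list(med)),
                                  class = "study_dataset"),
                        data.frame(cell_id = "median_cell",
                                   k_m = mc$params[["k_m"]],
                                   g_m = mc$params[["g_m"]],
                                   k_p = mc$params[["k_p"]],
                                   g_p = mc$params[["g_p"]]),
                        population_model(log(unclass(mc$params)[1:4]),
                                         diag(4) * 0.01, mc$tau_min,
                                         mc$error),
                        input)
  rel <- abs(pred$median_cell - med$values) / max(med$values)
  expect_lt(mean(rel), 0.05)
  # determinism under the same seed
  set.seed(5)
  mc2 <- fit_mean_cell(st, input, n_starts = 4)
  expect_identical(mc2$params, mc$params)
})

test_that("fitted k_mp tracks the truth even though k_m alone does not", {
  st <- generate_study(study_config(n_cells = 60, founder_frac = 1,
                                    gain_sd = 0), seed = 73)
  input <- build_input(st$schedule)
  set.seed(6)
  nf <- fit_naive(st, input)
  mg <- merge(nf$per_cell, st$truth$params, by = "cell_id",
              suffixes = c("_fit", "_true"))
  rho_kmp <- cor(mg$k_mp_fit, mg$k_mp_true, method = "spearman")
  rho_km <- cor(mg$k_m_fit, mg$k_m_true, method = "spearman")
  expect_gt(rho_kmp, 0.8)
  expect_lt(rho_km, rho_kmp)
  # pooled covariance is at least as spread as the generating one
  vol_fit <- dispersion_metrics(nf$pooled)$ellipsoid_volume_95
  vol_true <- dispersion_metrics(st$truth$population)$ellipsoid_volume_95
  expect_gt(vol_fit, vol_true * 0.5)
})
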