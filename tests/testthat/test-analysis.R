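test_that("perceived shock averages the per-shock relative volume drops", {
  sched <- shock_schedule(cbind(c(60, 120, 180), c(68, 128, 188)), 300)
  tt <- seq(0, 300, 3)
  # constant volume: zero perceived shock
  expect_equal(perceived_shock(tt, rep(40, length(tt)), sched), 0)
  # exact 10% drop after each shock
  v <- rep(100, length(tt))
  for (s in c(60, 120, 180)) v[tt >= s & tt <= s + 9] <- 90
  expect_equal(perceived_shock(tt, v, sched), 0.10)
  # drops {5%, 15%, 10%} average to 10%
  v2 <- rep(100, length(tt))
  drops <- c(0.05, 0.15, 0.10)
  for (j in 1:3) {
    s <- c(60, 120, 180)[j]
    v2[tt >= s & tt <= s + 9] <- 100 * (1 - drops[j])
  }
  expect_equal(perceived_shock(tt, v2, sched), 0.10)
  # trace covering no shock
  expect_true(is.na(perceived_shock(seq(0, 30, 3), rep(1, 11), sched)))
})

test_that("feature correlations match rank oracles, including ties", {
  set.seed(31)
  n <- 40
  x <- rnorm(n)
  params <- data.frame(cell_id = sprintf("c%02d", 1:n),
                       k_mp = exp(x), g_m = exp(-x + 0.1 * rnorm(n)))
  features <- data.frame(cell_id = params$cell_id,
                         mono = exp(x),              # rho exactly 1
                         rev = rank(-x),             # rho exactly -1
                         tied = round(x),            # heavy ties
                         const = rep(1, n))
  cf <- correlate_features(params, features)
  expect_equal(cf$rho["k_mp", "mono"], 1)
  expect_equal(cf$rho["k_mp", "rev"], -1)
  # mid-rank oracle for the tied column
  oracle <- cor(rank(exp(x)), rank(round(x)))
  expect_equal(cf$rho["k_mp", "tied"], oracle, tolerance = 1e-12)
  expect_true(is.na(cf$rho["k_mp", "const"]))
  expect_true(all(cf$p[!is.na(cf$p)] >= 0 & cf$p[!is.na(cf$p)] <= 1))
})

test_that("exact reversed ranks on 5 points give rho = -1", {
  params <- data.frame(cell_id = letters[1:10], k_mp = 1:10)
  features <- data.frame(cell_id = letters[1:10], f = 10:1)
  cf <- correlate_features(params, features)
  expect_equal(cf$rho["k_mp", "f"], -1)
})

test_that("PCA variance fractions match the analytic eigenvalues", {
  set.seed(32)
  n <- 2000
  S <- matrix(c(2, 1, 1, 2), 2)
  Z <- MASS::mvrnorm(n, c(0, 0), S)
  params <- data.frame(cell_id = as.character(1:n),
                       k_mp = exp(Z[, 1]), g_m = exp(Z[, 2]))
  features <- data.frame(cell_id = params$cell_id, junk = rnorm(n))
  ps <- pca_rank(params, features, param_cols = c("k_mp", "g_m"))
  expect_equal(sum(ps$variance_fractions), 1, tolerance = 1e-12)
  expect_equal(unname(ps$variance_fractions), c(0.75, 0.25),
               tolerance = 0.03)
  # isotropic case: near-equal fractions
  Zi <- matrix(rnorm(2 * 1000), ncol = 2)
  pi_ <- data.frame(cell_id = as.character(1:1000),
                    k_mp = exp(Zi[, 1]), g_m = exp(Zi[, 2]))
  fi <- data.frame(cell_id = pi_$cell_id, junk = rnorm(1000))
  vfi <- pca_rank(pi_, fi, param_cols = c("k_mp", "g_m"))$variance_fractions
  expect_equal(unname(vfi), c(0.5, 0.5), tolerance = 0.05)
})

test_that("a feature equal to PC1 scores gets PC1's variance fraction", {
  set.seed(33)
  n <- 600
  Z <- MASS::mvrnorm(n, rep(0, 4), default_population()$sigma)
  params <- data.frame(cell_id = as.character(1:n), k_m = exp(Z[, 1]),
                       g_m = exp(Z[, 2]), k_p = exp(Z[, 3]),
                       g_p = exp(Z[, 4]))
  pc <- prcomp(Z, center = TRUE, scale. = TRUE)
  features <- data.frame(cell_id = params$cell_id, f = pc$x[, 1])
  ps <- pca_rank(params, features)
  expect_equal(unname(ps$feature_scores["f"]),
               unname(ps$variance_fractions[1]), tolerance = 0.02)
  # fractions are invariant to the feature table
  ps2 <- pca_rank(params, data.frame(cell_id = params$cell_id,
                                     g = rnorm(n)))
  expect_equal(ps2$variance_fractions, ps$variance_fractions)
})

test_that("perfect inheritance gives zero MD distance and tiny p", {
  n_m <- 30
  moms <- sprintf("m%02d", 1:n_m)
  kids <- sprintf("d%02d", 1:n_m)
  th <- exp(rnorm(n_m))
  params <- data.frame(cell_id = c(moms, kids), k_mp = c(th, th),
                       g_m = c(th, th) * 2, g_p = c(th, th) / 3)
  lineage <- data.frame(daughter_id = kids, mother_id = moms)
  rep <- inheritance_test(params, lineage, n_pairs = 20, n_boot = 500,
                          seed = 34)
  expect_true(all(rep$table$mean_md == 0))
  expect_true(all(rep$table$closeness_pct == 100))
  expect_true(all(rep$table$p_value <= 1 / 500))
})

test_that("inheritance p-values are invariant to cell relabeling", {
  set.seed(35)
  st <- generate_study(quick_config(n_cells = 120, rho_inherit = 0.5),
                       seed = 36)
  tp <- st$truth$params
  r1 <- inheritance_test(tp, st$lineage, n_pairs = 20, n_boot = 2000,
                         seed = 37)
  # relabel ids consistently in both tables
  map <- setNames(sprintf("x%04d", seq_len(nrow(tp))), tp$cell_id)
  tp2 <- tp; tp2$cell_id <- unname(map[tp$cell_id])
  lg2 <- st$lineage
  lg2$daughter_id <- unname(map[lg2$daughter_id])
  lg2$mother_id <- unname(map[lg2$mother_id])
  r2 <- inheritance_test(tp2, lg2, n_pairs = 20, n_boot = 2000, seed = 37)
  expect_equal(r1$table$p_value, r2$table$p_value)
  expect_equal(r1$table$closeness_pct, r2$table$closeness_pct)
})

test_that("mother/daughter feature comparison returns the planted ratio", {
  n <- 25
  moms <- sprintf("m%02d", 1:n)
  kids <- sprintf("d%02d", 1:n)
  fm <- runif(n, 0.05, 0.2)
  features <- data.frame(cell_id = c(moms, kids),
                         perceived_shock = c(fm, 1.14 * fm))
  lineage <- data.frame(daughter_id = kids, mother_id = moms)
  r <- md_feature_comparison(features, lineage)
  expect_equal(r$mean_rel_diff, 0.14, tolerance = 1e-12)
  expect_equal(r$rho, 1)   # monotone mapping: fully inherited ranks
  # anti-inheritance: reversed ranks
  f2 <- data.frame(cell_id = c(moms, kids),
                   perceived_shock = c(fm, max(fm) + min(fm) - fm))
  r2 <- md_feature_comparison(f2, lineage)
  expect_equal(r2$rho, -1)
})

test_that("independent features show null mother/daughter correlation", {
  set.seed(38)
  n <- 100
  moms <- sprintf("m%03d", 1:n)
  kids <- sprintf("d%03d", 1:n)
  features <- data.frame(cell_id = c(moms, kids),
                         perceived_shock = runif(2 * n, 0.05, 0.2))
  lineage <- data.frame(daughter_id = kids, mother_id = moms)
  r <- md_feature_comparison(features, lineage)
  expect_lt(abs(r$rho), 0.2)
})
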