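#' SAEM configuration
#'
#' Settings of the stochastic approximation EM estimator. During the
#' `n_burnin` exploratory iterations the stochastic-approximation step size
#' is `gamma_k = 1`; during the `n_sa` smoothing iterations it decays as
#' `1/(k - n_burnin)`, the standard schedule guaranteeing convergence of
#' the sufficient statistics.
#'
#' @param n_burnin,n_sa iteration counts for the two phases.
#' @param mcmc_steps Metropolis-Hastings updates per cell per iteration.
#' @param prop_scale initial random-walk scale, as a multiple of the
#'   current population log-SDs.
#' @param target_accept target acceptance rate of the adaptive walk.
#' @param fix_mean_lnkp clamp the population mean of `ln k_p` (resolves the
#'   k_m/k_p structural non-identifiability; the variance stays free).
#' @param fixed_lnkp_value the clamped value (default `log(1)`, the
#'   literature translation rate).
#' @param init_mu,init_sd,init_error,init_tau starting point of the search
#'   (log-means, log-SDs, `c(sigma_add, sigma_mult)`, delay in minutes).
#' @param tau_grid candidate delays for the periodic profile search.
#' @param tau_update_every profile the delay every this many iterations.
#' @param estimate_error,estimate_tau set `FALSE` to freeze the noise
#'   strengths / delay at their initial values (e.g. when known from a
#'   calibration).
#' @param anneal,anneal_factor keep each log-variance above
#'   `anneal_factor` times its previous value during burn-in (simulated
#'   annealing guarding against premature variance collapse).
#' @param seed integer RNG seed; the whole fit is deterministic given it.
#' @param convergence_window default window for [check_convergence()].
#' @export
saem_config <- function(n_burnin = 300, n_sa = 200, mcmc_steps = 4,
                        prop_scale = 0.4, target_accept = 0.3,
                        fix_mean_lnkp = TRUE, fixed_lnkp_value = log(1),
                        init_mu = log(c(3, 0.06, 1, 0.005)),
                        init_sd = c(0.5, 0.5, 0.5, 0.5),
                        init_error = c(15, 0.15), init_tau = 8,
                        tau_grid = seq(0, 30, by = 1),
                        tau_update_every = 20,
                        estimate_error = TRUE, estimate_tau = TRUE,
                        anneal = TRUE, anneal_factor = 0.95,
                        seed = 1, convergence_window = 40) {
  stopifnot(n_burnin >= 1, n_sa >= 1, mcmc_steps >= 1,
            length(init_mu) == 4, length(init_sd) == 4,
            all(init_sd > 0), all(init_error > 0), init_tau >= 0)
  structure(as.list(environment()), class = "saem_config")
}

# project a symmetric matrix to the PSD cone with an eigenvalue floor
psd_project <- function(S, floor = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

# joint MLE of (sigma_add, sigma_mult) given residuals e at predictions p
solve_error_mle <- function(e, p, start) {
  p2 <- p * p
  e2 <- e * e
  f <- function(x) {
    v <- exp(2 * x[1]) + exp(2 * x[2]) * p2
    sum(log(v) + e2 / v)
  }
  fit <- stats::optim(log(start), f, method = "Nelder-Mead",
                      control = list(maxit = 60))
  exp(fit$par)
}

#' Fit the mixed-effects population model by SAEM
#'
#' From-scratch stochastic approximation EM. Each iteration alternates:
#' an E-step in which every cell's log-parameter vector is updated by a few
#' adaptive Gaussian random-walk Metropolis-Hastings steps targeting its
#' conditional posterior `p(data_i | theta_i) p(theta_i | mu, sigma)`; a
#' stochastic-approximation update of the sufficient statistics of the
#' log-normal population model; and closed-form M-step updates of `mu` (the
#' `ln k_p` component optionally clamped) and `sigma` (projected to the PSD
#' cone), with the noise strengths refitted by maximum likelihood on the
#' current residuals and smoothed on the variance scale, and the shared
#' delay re-profiled periodically over a coarse grid.
#'
#' @param study a `study_dataset` that passed QC, with >= 10 cells.
#' @param input an `input_signal`.
#' @param config a [saem_config()].
#' @return list of class `saem_fit`: `population` ([population_model()]),
#'   `trace` (one row per iteration: population parameters, noise, delay,
#'   acceptance rate), `draws` (final per-cell log-parameters), `config`.
#' @export
fit_saem <- function(study, input, config = saem_config()) {
  stopifnot(inherits(config, "saem_config"))
  n <- length(study$trajectories)
  if (n < 10) stop("fit error: SAEM needs at least 10 cells")
  set.seed(config$seed)

  mu <- as.numeric(config$init_mu)
  Sigma <- diag(config$init_sd^2)
  sa <- config$init_error[1]
  sm <- config$init_error[2]
  tau <- config$init_tau
  fixi <- 3L   # index of ln k_p

  caches <- lapply(study$trajectories, make_cell_cache, input = input,
                   tau_min = tau)
  Z <- matrix(rep(mu, each = n), n)
  ll <- vapply(seq_len(n),
               function(i) loglik_cached(caches[[i]], exp(Z[i, ]), sa, sm),
               numeric(1))
  preds <- lapply(seq_len(n), function(i)
    predict_cached(caches[[i]], exp(Z[i, ])))

  n_iter <- config$n_burnin + config$n_sa
  .tau_scanned <- NULL
  S1 <- colSums(Z)
  S2 <- crossprod(Z)
  scale <- config$prop_scale
  prev_diag <- diag(Sigma)
  tr <- matrix(NA_real_, n_iter, 19)
  colnames(tr) <- c("iter", paste0("mu_", c("km", "gm", "kp", "gp")),
                    paste0("sd_", c("km", "gm", "kp", "gp")),
                    "corr_km_gm", "corr_km_kp", "corr_km_gp",
                    "corr_gm_kp", "corr_gm_gp", "corr_kp_gp",
                    "sigma_add", "sigma_mult", "tau", "accept")

  # Profile log-likelihood of a candidate delay. The delay trades off
  # against the composite production rate (about +13% k_mp per minute of
  # delay), so comparing candidates at the current draws is unfair to any
  # delay other than the current one. Since p(t) is affine in k_mp given
  # (g_m, g_p) and the anchor, the per-cell k_mp compensation is a
  # closed-form weighted least-squares rescaling.
  profile_ll <- function(tau_try) {
    cc <- lapply(study$trajectories, make_cell_cache, input = input,
                 tau_min = tau_try)
    tot <- 0
    for (i in seq_len(n)) {
      th <- exp(Z[i, ])
      ci <- cc[[i]]
      base <- cpp_predict(ci$grid, ci$u, 1e-300, th[2], th[3], th[4],
                          ci$m0, ci$p0, ci$qidx, ci$reset_idx)
      pc <- predict_cached(ci, th)
      h <- pc - base                   # k_mp-proportional component
      v <- sa^2 + sm^2 * pc * pc
      num <- sum((ci$y - base) * h / v)
      den <- sum(h * h / v)
      s <- if (den > 0) max(num / den, 1e-6) else 1
      ph <- base + s * h
      vh <- sa^2 + sm^2 * ph * ph
      tot <- tot + (-0.5 * sum(log(2 * pi * vh) +
                                 (ci$y - ph)^2 / vh))
    }
    tot
  }

  for (k in seq_len(n_iter)) {
    gamma <- if (k <= config$n_burnin) 1 else 1 / (k - config$n_burnin)

    ch <- tryCatch(chol(Sigma),
                   error = function(e) chol(Sigma + 1e-8 * diag(4)))
    Om <- chol2inv(ch)
    propL <- scale * t(ch)   # correlated random walk shaped like the
                             # current population covariance
    # cycle large/medium/small kernels: when the conditional posterior is
    # much tighter than the population prior (e.g. near-degenerate
    # populations) only the small moves are accepted, keeping the chain
    # mobile while the global scale adapts
    kernel_scales <- rep_len(c(1, 0.3, 0.1), config$mcmc_steps)
    n_acc <- 0L
    for (i in seq_len(n)) {
      zi <- Z[i, ]
      lli <- ll[i]
      dz <- zi - mu
      lpi <- -0.5 * drop(dz %*% Om %*% dz)
      changed <- FALSE
      for (s in seq_len(config$mcmc_steps)) {
        zn <- zi + kernel_scales[s] * drop(propL %*% stats::rnorm(4))
        lln <- loglik_cached(caches[[i]], exp(zn), sa, sm)
        dzn <- zn - mu
        lpn <- -0.5 * drop(dzn %*% Om %*% dzn)
        if (is.finite(lln) &&
            log(stats::runif(1)) < (lln + lpn) - (lli + lpi)) {
          zi <- zn; lli <- lln; lpi <- lpn
          n_acc <- n_acc + 1L
          changed <- TRUE
        }
      }
      if (changed) {
        Z[i, ] <- zi
        ll[i] <- lli
        preds[[i]] <- predict_cached(caches[[i]], exp(zi))
      }
    }
    acc <- n_acc / (n * config$mcmc_steps)
    # Robbins-Monro adaptation toward the target acceptance; kept active
    # through the SA phase (near-degenerate populations need the proposal
    # to keep shrinking with the posterior)
    scale <- scale * exp(0.2 * (acc - config$target_accept))
    if (acc < 0.01 && k > 5) {
      scale <- scale * 0.5
      warning("acceptance collapse at iteration ", k,
              "; proposal rescaled")
    }

    # stochastic approximation of the sufficient statistics
    S1 <- S1 + gamma * (colSums(Z) - S1)
    S2 <- S2 + gamma * (crossprod(Z) - S2)

    # M-step. The ln k_p mean constraint is enforced by reallocation: any
    # drift of the draws' ln k_p mean is transferred to ln k_m, preserving
    # the identified sum ln k_mp = ln k_m + ln k_p (the two means are only
    # jointly identified; clamping without reallocation would trap the
    # initialization error of mu_km on the flat ridge).
    m1 <- S1 / n
    mu <- m1
    if (config$fix_mean_lnkp) {
      mu[1] <- m1[1] + (m1[fixi] - config$fixed_lnkp_value)
      mu[fixi] <- config$fixed_lnkp_value
    }
    Sigma <- S2 / n - outer(m1, m1)
    Sigma <- psd_project(Sigma)
    if (config$anneal && k <= config$n_burnin) {
      d_tgt <- pmax(diag(Sigma), config$anneal_factor * prev_diag)
      sdv <- sqrt(pmax(diag(Sigma), 1e-12))
      C <- Sigma / outer(sdv, sdv)
      diag(C) <- 1
      Sigma <- psd_project(C * outer(sqrt(d_tgt), sqrt(d_tgt)))
    }
    prev_diag <- diag(Sigma)

    # Noise strengths: joint MLE on current residuals, SA-smoothed.
    # Updates only start once the annealing floor has decayed (second half
    # of burn-in): while the floor holds the random effects artificially
    # dispersed, the residual MLE soaks the transient misfit into
    # sigma_add, which then flattens the very likelihood features needed
    # to re-tighten the fit.
    if (config$estimate_error && k > config$n_burnin / 2) {
      pall <- unlist(preds)
      eall <- unlist(lapply(seq_len(n), function(i) caches[[i]]$y)) - pall
      est <- solve_error_mle(eall, pall, c(sa, sm))
      sa <- sqrt(sa^2 + gamma * (est[1]^2 - sa^2))
      sm <- sqrt(sm^2 + gamma * (est[2]^2 - sm^2))
    }

    # Periodic profile search for the shared delay. The first search scans
    # the full grid; later ones refine within +-3 grid steps.
    if (config$estimate_tau && k %% config$tau_update_every == 0) {
      cand <- if (is.null(.tau_scanned)) config$tau_grid
              else config$tau_grid[abs(config$tau_grid - tau) <=
                                     3 * max(diff(config$tau_grid))]
      .tau_scanned <- TRUE
      prof <- vapply(cand, profile_ll, numeric(1))
      tau_new <- cand[which.max(prof)]
      if (tau_new != tau) {
        tau <- tau_new
        caches <- lapply(study$trajectories, make_cell_cache,
                         input = input, tau_min = tau)
        ll <- vapply(seq_len(n),
                     function(i) loglik_cached(caches[[i]], exp(Z[i, ]),
                                               sa, sm),
                     numeric(1))
        preds <- lapply(seq_len(n), function(i)
          predict_cached(caches[[i]], exp(Z[i, ])))
      }
    }

    sdv <- sqrt(diag(Sigma))
    C <- Sigma / outer(sdv, sdv)
    tr[k, ] <- c(k, mu, sdv, C[1, 2], C[1, 3], C[1, 4], C[2, 3], C[2, 4],
                 C[3, 4], sa, sm, tau, acc)
  }

  pop <- population_model(mu, Sigma, tau, error_model(sa, sm),
                          fixed_mean_lnkp = config$fix_mean_lnkp)
  rownames(Z) <- names(study$trajectories)
  structure(list(population = pop, trace = as.data.frame(tr), draws = Z,
                 config = config),
            class = "saem_fit")
}

#' @export
print.saem_fit <- function(x, ...) {
  cat("SAEM fit,", nrow(x$trace), "iterations\n")
  print(x$population)
  invisible(x)
}

#' Convergence diagnostics of an SAEM trace
#'
#' For every tracked scalar, the relative drift over the last `window`
#' iterations is `(max - min) / |mean|`; the fit is flagged converged when
#' every drift is below `tol`.
#'
#' @param trace the `trace` data frame of a [fit_saem()] result.
#' @param window number of trailing iterations examined.
#' @param tol relative drift tolerance.
#' @return list: `converged`, `drift` (named vector).
#' @export
check_convergence <- function(trace, window = 40, tol = 0.02) {
  if (nrow(trace) < 2 * window)
    stop("argument error: trace must have at least 2 * window iterations")
  tail_tr <- trace[(nrow(trace) - window + 1):nrow(trace),
                   setdiff(colnames(trace), c("iter", "accept")),
                   drop = FALSE]
  drift <- vapply(tail_tr, function(v)
    (max(v) - min(v)) / max(abs(mean(v)), 1e-12), numeric(1))
  list(converged = all(drift < tol), drift = drift)
}
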