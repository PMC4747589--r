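#' Maximum a posteriori estimate of one cell's parameters
#'
#' Maximizes `loglik(data | theta) + log_prior(theta | population)` over
#' the log-parameters, the prior being the fitted log-normal population
#' model (Jacobian included, consistently with [log_prior()]). Multi-start:
#' the prior mean plus `n_draws` random prior draws. If every start fails,
#' the prior mean is returned with `converged = FALSE`.
#'
#' @param traj a `cell_trajectory` (post-QC).
#' @param pop a fitted [population_model()].
#' @param input an `input_signal`.
#' @param n_draws extra prior-draw starts (default 2).
#' @param low_info_obs cells with fewer observations than this are flagged
#'   low-information.
#' @return list: `cell_id`, `params`, `log_posterior`, `converged`,
#'   `low_info`.
#' @export
fit_map <- function(traj, pop, input, n_draws = 2, low_info_obs = 10) {
  cache <- make_cell_cache(traj, input, pop$tau_min)
  sa <- pop$error$sigma_add
  sm <- pop$error$sigma_mult
  Om <- tryCatch(chol2inv(chol(pop$sigma)),
                 error = function(e)
                   chol2inv(chol(pop$sigma + 1e-10 * diag(4))))
  ldet <- determinant(pop$sigma + 0 * diag(4), logarithm = TRUE)$modulus
  mu <- pop$mu
  neg_post <- function(z) {
    dz <- z - mu
    lp <- -0.5 * drop(dz %*% Om %*% dz) - 0.5 * ldet -
      2 * log(2 * pi) - sum(z)
    ll <- loglik_cached(cache, exp(z), sa, sm)
    if (!is.finite(ll)) return(1e12)
    -(ll + lp)
  }
  L <- msqrt(pop$sigma)
  starts <- c(list(mu),
              lapply(seq_len(n_draws),
                     function(i) mu + drop(L %*% stats::rnorm(4))))
  best <- NULL
  for (zs in starts) {
    fit <- tryCatch(stats::optim(zs, neg_post, method = "Nelder-Mead",
                                 control = list(maxit = 800,
                                                reltol = 1e-10)),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) {
    return(list(cell_id = traj$cell_id,
                params = cell_params(exp(mu[1]), exp(mu[2]), exp(mu[3]),
                                     exp(mu[4])),
                log_posterior = NA_real_, converged = FALSE,
                low_info = length(traj$values) < low_info_obs))
  }
  z <- best$par
  list(cell_id = traj$cell_id,
       params = cell_params(exp(z[1]), exp(z[2]), exp(z[3]), exp(z[4])),
       log_posterior = -best$value,
       converged = best$convergence == 0,
       low_info = length(traj$values) < low_info_obs)
}

#' MAP estimates for every cell of a study
#'
#' @param study a `study_dataset` (post-QC).
#' @param pop a fitted [population_model()].
#' @param input an `input_signal`.
#' @param ... passed to [fit_map()].
#' @return list of class `map_fit`: `estimates` (list of [fit_map()]
#'   results) and `table` (data frame with one row per cell:
#'   `cell_id, k_m, g_m, k_p, g_p, k_mp, log_posterior, converged,
#'   low_info`).
#' @export
fit_map_all <- function(study, pop, input, ...) {
  est <- lapply(study$trajectories, fit_map, pop = pop, input = input, ...)
  tab <- do.call(rbind, lapply(est, function(e)
    data.frame(cell_id = e$cell_id, k_m = e$params[["k_m"]],
               g_m = e$params[["g_m"]], k_p = e$params[["k_p"]],
               g_p = e$params[["g_p"]], k_mp = e$params[["k_mp"]],
               log_posterior = e$log_posterior, converged = e$converged,
               low_info = e$low_info, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  structure(list(estimates = est, table = tab), class = "map_fit")
}

#' Eta-shrinkage of the individual estimates
#'
#' For each log-parameter, `1 - var(MAP log-values) / sigma_kk`: near 0
#' when the data dominate the individual estimates, near 1 when they
#' collapse to the population mean (uninformative data). Parameters with
#' zero population variance are reported as `NA`.
#'
#' @param map a `map_fit` (or its `table`), with >= 10 converged cells.
#' @param pop the [population_model()] used as prior.
#' @return named numeric vector of length 4.
#' @export
shrinkage <- function(map, pop) {
  tab <- if (inherits(map, "map_fit")) map$table else map
  tab <- tab[tab$converged, , drop = FALSE]
  if (nrow(tab) < 10)
    stop("argument error: need at least 10 converged estimates")
  Z <- log(as.matrix(tab[, c("k_m", "g_m", "k_p", "g_p")]))
  v <- apply(Z, 2, stats::var)
  skk <- diag(pop$sigma)
  out <- 1 - v / skk
  out[skk == 0] <- NA_real_
  names(out) <- c("k_m", "g_m", "k_p", "g_p")
  out
}
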