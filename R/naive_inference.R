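#' Fit the mean-cell model (shared delay and noise strengths)
#'
#' Fits the expression model to the frame-wise median trajectory of the
#' study by seeded multi-start Nelder-Mead over the four log-rates, the
#' maturation delay (logistic-transformed onto `[0, tau_max]`) and the two
#' log noise strengths. The fitted delay and error model are frozen and
#' reused for every per-cell fit, mirroring the standard practice of not
#' letting noise/delay parameters float per cell.
#'
#' @param study a `study_dataset` (post-QC).
#' @param input an `input_signal`.
#' @param init a [cell_params()] starting point (defaults to
#'   literature-style rates).
#' @param n_starts number of random restarts around `init`.
#' @param tau_max upper bound of the delay search (minutes).
#' @param box half-width of the search box in log-units around `log(init)`.
#' @return list: `params` ([cell_params()]), `tau_min`, `error`
#'   ([error_model()]), `loglik`, `at_bound`.
#' @export
fit_mean_cell <- function(study, input, init = literature_params(),
                          n_starts = 8, tau_max = 30, box = 6) {
  if (length(study$trajectories) == 0) stop("fit error: empty study")
  med <- median_trajectory(study)
  z0 <- log(unclass(init)[1:4])
  sa0 <- max(stats::sd(med$values) * 0.1, 1e-3)
  x0 <- c(z0, 0, log(sa0), log(0.1))   # tau logit 0 -> tau_max/2
  obj <- function(x) {
    z <- x[1:4]
    pen <- sum(pmax(abs(z - z0) - box, 0)^2) * 1e6
    tau <- tau_max * stats::plogis(x[5])
    cache <- make_cell_cache(med, input, tau)
    ll <- tryCatch(loglik_cached(cache, exp(z), exp(x[6]), exp(x[7])),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll + pen
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    xs <- if (s == 1) x0
          else x0 + c(stats::rnorm(4, 0, 1), stats::rnorm(1, 0, 1.5),
                      stats::rnorm(2, 0, 0.5))
    fit <- tryCatch(stats::optim(xs, obj, method = "Nelder-Mead",
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("fit error: no finite-likelihood point found for the mean cell")
  z <- unname(best$par[1:4])
  list(params = cell_params(exp(z[1]), exp(z[2]), exp(z[3]), exp(z[4])),
       tau_min = unname(tau_max * stats::plogis(best$par[5])),
       error = error_model(exp(unname(best$par[6])),
                           exp(unname(best$par[7]))),
       loglik = -best$value,
       at_bound = any(abs(z - z0) > box - 0.05))
}

#' Per-cell maximum-likelihood fit
#'
#' Local Nelder-Mead maximization of the single-cell log-likelihood over
#' the four log-rates, with the delay and error model fixed for all cells.
#' The search is soft-bounded to `box` log-units around `log(init)` (a
#' positivity and multimodality hedge); restarts jitter the start point.
#'
#' @param traj a `cell_trajectory` (post-QC).
#' @param input an `input_signal`.
#' @param init a [cell_params()] starting point / box center.
#' @param tau_min,error shared delay and [error_model()].
#' @param n_restarts restarts (first start is `init` itself).
#' @param jitter_sd log-scale SD of restart jitter.
#' @param box search-box half-width (log-units).
#' @return list: `params`, `loglik`, `converged`, `at_bound`,
#'   `n_restarts`.
#' @export
fit_cell_ml <- function(traj, input, init, tau_min, error,
                        n_restarts = 3, jitter_sd = 0.5, box = 6) {
  cache <- make_cell_cache(traj, input, tau_min)
  z0 <- log(unclass(init)[1:4])
  obj <- function(z) {
    pen <- sum(pmax(abs(z - z0) - box, 0)^2) * 1e6
    ll <- loglik_cached(cache, exp(z), error$sigma_add, error$sigma_mult)
    if (!is.finite(ll)) return(1e12)
    -ll + pen
  }
  best <- NULL
  for (s in seq_len(n_restarts)) {
    zs <- if (s == 1) z0 else z0 + stats::rnorm(4, 0, jitter_sd)
    fit <- tryCatch(stats::optim(zs, obj, method = "Nelder-Mead",
                                 control = list(maxit = 800,
                                                reltol = 1e-10)),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    return(list(params = init, loglik = NA_real_, converged = FALSE,
                at_bound = FALSE, n_restarts = n_restarts))
  z <- best$par
  list(params = cell_params(exp(z[1]), exp(z[2]), exp(z[3]), exp(z[4])),
       loglik = -best$value,
       converged = best$convergence == 0,
       at_bound = any(abs(z - z0) > box - 0.05),
       n_restarts = n_restarts)
}

#' Pool per-cell estimates into an empirical population model
#'
#' The "naive" population distribution: log-parameter mean vector and
#' unbiased sample covariance of the successful per-cell fits, carrying the
#' shared delay and error model.
#'
#' @param per_cell data frame with columns `k_m, g_m, k_p, g_p` and
#'   logical `converged` (as produced by [fit_naive()]).
#' @param tau_min,error shared delay and [error_model()].
#' @export
pool_population <- function(per_cell, tau_min, error) {
  ok <- per_cell[per_cell$converged & is.finite(per_cell$loglik), ,
                 drop = FALSE]
  if (nrow(ok) < 5)
    stop("pooling error: fewer than 5 successful per-cell fits")
  Z <- log(as.matrix(ok[, c("k_m", "g_m", "k_p", "g_p")]))
  population_model(colMeans(Z), stats::cov(Z), tau_min, error,
                   fixed_mean_lnkp = FALSE)
}

#' Naive population inference: independent fits, then pooling
#'
#' The intuitive two-step approach: fit the mean cell to freeze the delay
#' and noise strengths, maximize each cell's likelihood independently, and
#' deduce the population distribution from the empirical statistics of the
#' per-cell estimates. Cells whose restarts all fail are excluded from the
#' pooling with a warning.
#'
#' @param study a `study_dataset` (post-QC).
#' @param input an `input_signal`.
#' @param mean_cell optionally, a precomputed [fit_mean_cell()] result.
#' @param n_starts restarts of the mean-cell fit.
#' @param ... passed on to [fit_cell_ml()].
#' @return list of class `naive_fit`: `per_cell` (data frame), `pooled`
#'   ([population_model()]), `mean_cell`.
#' @export
fit_naive <- function(study, input, mean_cell = NULL, n_starts = 8, ...) {
  if (is.null(mean_cell))
    mean_cell <- fit_mean_cell(study, input, n_starts = n_starts)
  rows <- lapply(study$trajectories, function(tr) {
    f <- fit_cell_ml(tr, input, mean_cell$params, mean_cell$tau_min,
                     mean_cell$error, ...)
    data.frame(cell_id = tr$cell_id, k_m = f$params[["k_m"]],
               g_m = f$params[["g_m"]], k_p = f$params[["k_p"]],
               g_p = f$params[["g_p"]], k_mp = f$params[["k_mp"]],
               loglik = f$loglik, converged = f$converged,
               at_bound = f$at_bound, n_restarts = f$n_restarts,
               stringsAsFactors = FALSE)
  })
  per_cell <- do.call(rbind, rows)
  rownames(per_cell) <- NULL
  n_fail <- sum(!per_cell$converged | !is.finite(per_cell$loglik))
  if (n_fail > 0)
    warning(n_fail, " cell(s) failed all restarts; excluded from pooling")
  structure(list(per_cell = per_cell,
                 pooled = pool_population(per_cell, mean_cell$tau_min,
                                          mean_cell$error),
                 mean_cell = mean_cell),
            class = "naive_fit")
}
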