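#' Single-cell kinetic parameters
#'
#' The two-state gene-expression model has four rates: mRNA synthesis `k_m`
#' (a.u. min^-1 per unit input activity), mRNA degradation `g_m` (min^-1),
#' protein synthesis per mRNA `k_p` (min^-1) and protein degradation/dilution
#' `g_p` (min^-1). The composite protein production rate `k_mp = k_m * k_p`
#' is carried along because it is the combination identifiable from
#' single-cell fluorescence (the individual factors are structurally
#' non-identifiable: scaling `k_m` by c and `k_p` by 1/c leaves the protein
#' trajectory unchanged).
#'
#' @param k_m,g_m,k_p,g_p strictly positive finite rates.
#' @return object of class `cell_params` (named numeric vector with a
#'   derived `k_mp` element).
#' @export
cell_params <- function(k_m, g_m, k_p, g_p) {
  th <- c(k_m = as.numeric(k_m), g_m = as.numeric(g_m),
          k_p = as.numeric(k_p), g_p = as.numeric(g_p))
  if (any(!is.finite(th)) || any(th <= 0))
    stop("argument error: all rates must be strictly positive and finite")
  structure(c(th, k_mp = unname(th["k_m"] * th["k_p"])),
            class = "cell_params")
}

#' Combined measurement error model
#'
#' Fluorescence observations carry additive and multiplicative white
#' Gaussian noise, with strengths shared by all cells:
#' `y = p * (1 + sigma_mult * e1) + sigma_add * e2`.
#'
#' @param sigma_add additive noise SD (a.u.).
#' @param sigma_mult multiplicative noise SD (dimensionless).
#' @export
error_model <- function(sigma_add, sigma_mult) {
  if (sigma_add < 0 || sigma_mult < 0)
    stop("argument error: noise strengths must be non-negative")
  if (sigma_add == 0 && sigma_mult == 0)
    stop("argument error: at least one noise strength must be positive")
  structure(list(sigma_add = as.numeric(sigma_add),
                 sigma_mult = as.numeric(sigma_mult)),
            class = "error_model")
}

#' Simulate the gene-expression ODEs under a piecewise-constant input
#'
#' Propagates `dm/dt = k_m u(t) - g_m m`, `dp/dt = k_p m - g_p p` exactly
#' over each interval on which u is constant, using the closed-form solution
#' of the linear system (a stable limit branch covers `g_m == g_p`). The
#' result is exact up to floating point on any grid that contains the
#' breakpoints of u.
#'
#' @param params a [cell_params()].
#' @param input an `input_signal` from [build_input()].
#' @param times strictly increasing output times (minutes), within the input
#'   grid span; the initial state is attached to `times[1]`.
#' @param init `c(m0, p0)`, non-negative initial state at `times[1]`.
#' @return list of class `state_trajectory`: `times`, `m`, `p`, `init`.
#' @export
simulate_expression <- function(params, input, times, init = c(0, 0)) {
  stopifnot(inherits(params, "cell_params"))
  if (any(init < 0)) stop("argument error: negative initial state")
  if (is.unsorted(times, strictly = TRUE))
    stop("argument error: times must be strictly increasing")
  span <- range(input$times)
  if (times[1] < span[1] - 1e-9 || times[length(times)] > span[2] + 1e-9)
    stop("argument error: times outside the input grid span")
  grid <- sort(unique(c(times,
                        input$times[input$times >= times[1] &
                                    input$times <= times[length(times)]])))
  u <- input_segments(input, if (length(grid) > 1) grid else c(grid, grid))
  res <- cpp_propagate(grid, if (length(grid) > 1) u else numeric(0),
                       params[["k_m"]], params[["g_m"]],
                       params[["k_p"]], params[["g_p"]],
                       init[1], init[2])
  keep <- match(times, grid)
  structure(list(times = times, m = res$m[keep], p = res$p[keep],
                 init = init), class = "state_trajectory")
}

#' Generate noisy fluorescence observations from a state trajectory
#'
#' Applies the maturation delay `tau_min` (fluorescence at time t reports
#' protein at t - tau) and the combined error model. Sample times whose
#' delayed lookup falls before the start of the trajectory are clipped to
#' the initial state. Deterministic given the RNG state.
#'
#' @param traj a `state_trajectory` (must cover the delayed sample times
#'   after clipping).
#' @param tau_min maturation delay (minutes).
#' @param sample_times observation times (minutes).
#' @param error an [error_model()].
#' @return numeric vector of fluorescence values (a.u.).
#' @export
observe_fluorescence <- function(traj, tau_min, sample_times, error) {
  tq <- pmax(sample_times - tau_min, traj$times[1])
  p <- stats::approx(traj$times, traj$p, xout = tq, rule = 2)$y
  n <- length(p)
  p * (1 + error$sigma_mult * stats::rnorm(n)) +
    error$sigma_add * stats::rnorm(n)
}

#' Log-likelihood of a cell's fluorescence trajectory
#'
#' Gaussian observation density with mean p(t - tau) and variance
#' `sigma_add^2 + sigma_mult^2 * p(t - tau)^2` (the multiplicative term uses
#' the model prediction, keeping the likelihood well defined at low signal).
#' Under the default `init_policy = "first_obs"`, the mRNA level is
#' propagated from the start of the stimulus history (where m = 0 holds:
#' the promoter is inactive before the first stimulus) and the protein
#' level is anchored to the first observed fluorescence value at the cell's
#' first observation — the only data-driven anchor for cells born during
#' the experiment. Predictions for observations whose delayed lookup falls
#' before the first observation are clipped to that anchor.
#'
#' @param traj a `cell_trajectory` (see [read_trajectories()]).
#' @param params a [cell_params()].
#' @param tau_min shared maturation delay (minutes).
#' @param error an [error_model()].
#' @param input an `input_signal`.
#' @param init_policy `"first_obs"` (default) or a numeric `c(m0, p0)`
#'   taken as the state at the first observation.
#' @return scalar log-likelihood.
#' @export
cell_loglik <- function(traj, params, tau_min, error, input,
                        init_policy = "first_obs") {
  cache <- make_cell_cache(traj, input, tau_min, init_policy)
  if (is.numeric(init_policy)) {
    cache$m0 <- init_policy[1]
    cache$p0 <- init_policy[2]
    cache$grid <- cache$grid[cache$reset_idx:length(cache$grid)]
    cache$u <- cache$u[cache$reset_idx:(length(cache$u))]
    cache$qidx <- cache$qidx - cache$reset_idx + 1L
    cache$reset_idx <- 1L
  }
  ll <- loglik_cached(cache, unclass(params)[1:4],
                      error$sigma_add, error$sigma_mult)
  if (!is.finite(ll))
    stop("numerical error: non-finite model prediction for cell ",
         traj$cell_id)
  ll
}

#' Reference Runge-Kutta simulation
#'
#' Fixed-step classical RK4 integration of the same model over the same
#' piecewise-constant input, with substeps aligned to the input breakpoints.
#' This is a deliberately independent numerical route used to verify the
#' exact propagation in [simulate_expression()].
#'
#' @inheritParams simulate_expression
#' @param h RK4 step (minutes).
#' @export
simulate_rk4 <- function(params, input, times, init = c(0, 0), h = 0.001) {
  grid <- sort(unique(c(times,
                        input$times[input$times >= times[1] &
                                    input$times <= times[length(times)]])))
  u <- input_segments(input, grid)
  res <- cpp_rk4(grid, u, params[["k_m"]], params[["g_m"]],
                 params[["k_p"]], params[["g_p"]], init[1], init[2], h)
  keep <- match(times, grid)
  structure(list(times = times, m = res$m[keep], p = res$p[keep],
                 init = init), class = "state_trajectory")
}
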