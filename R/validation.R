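#' Population envelope by resampling a fitted model
#'
#' Samples `n` virtual cells from the population distribution, simulates
#' each over the full experiment horizon (all virtual cells start at t = 0
#' with empty mRNA/protein state), and computes the time-wise median and
#' quantile band of the predicted fluorescence, with or without measurement
#' noise. The band is the standard population-level validation object: a
#' well-calibrated model's band should cover the observed single-cell data.
#'
#' @param pop a [population_model()].
#' @param schedule a [shock_schedule()].
#' @param n number of virtual cells (>= 100).
#' @param with_noise add observation noise (and then compare to raw data).
#' @param probs lower/upper band quantiles.
#' @param sample_dt output time step (minutes).
#' @param input optional prebuilt `input_signal` for the schedule.
#' @return list of class `population_envelope`: `times`, `median`,
#'   `lower`, `upper`, `n_virtual`, `probs`, and the full `values` matrix
#'   (n x time).
#' @export
predict_population <- function(pop, schedule, n = 10000,
                               with_noise = FALSE,
                               probs = c(0.025, 0.975), sample_dt = 6,
                               input = NULL) {
  stopifnot(n >= 100)
  if (is.null(input)) input <- build_input(schedule)
  T_end <- schedule$duration_min
  times <- seq(0, T_end, by = sample_dt)
  tau <- pop$tau_min
  tq <- pmax(times - tau, 0)
  grid <- sort(unique(c(0, tq, T_end,
                        input$times[input$times > 0 &
                                    input$times < T_end])))
  u <- input_segments(input, grid)
  qidx <- match(tq, grid)
  cells <- sample_cells(pop, n)
  vals <- matrix(NA_real_, n, length(times))
  for (i in seq_len(n)) {
    th <- unclass(cells[[i]])[1:4]
    vals[i, ] <- cpp_predict(grid, u, th[1], th[2], th[3], th[4], 0, 0,
                             qidx)
  }
  if (with_noise) {
    err <- pop$error
    vals <- vals * (1 + err$sigma_mult *
                      matrix(stats::rnorm(length(vals)), n)) +
      err$sigma_add * matrix(stats::rnorm(length(vals)), n)
  }
  qs <- apply(vals, 2, stats::quantile, probs = c(probs[1], 0.5, probs[2]),
              names = FALSE)
  structure(list(times = times, median = qs[2, ], lower = qs[1, ],
                 upper = qs[3, ], n_virtual = n, probs = probs,
                 values = vals),
            class = "population_envelope")
}

#' @export
plot.population_envelope <- function(x, ylim = NULL, ...) {
  if (is.null(ylim)) ylim <- range(x$lower, x$upper)
  graphics::plot(x$times / 60, x$median, type = "n", ylim = ylim,
                 xlab = "time (h)", ylab = "fluorescence (a.u.)", ...)
  graphics::polygon(c(x$times, rev(x$times)) / 60,
                    c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("pink", 0.6), border = NA)
  graphics::lines(x$times / 60, x$median, lty = 2)
  invisible(x)
}

#' Average relative absolute fit error
#'
#' Mean over all cells and observation times of `|pred - y| /
#' max(y_ref, floor)`, where `y_ref` is the cell's time-averaged
#' fluorescence and the floor is a fraction of the population's peak
#' frame-wise median fluorescence (guarding against division blow-up at low
#' signal). Reported in percent.
#'
#' @param study a `study_dataset` (post-QC).
#' @param predictions named list (by cell id) of predicted values aligned
#'   with each cell's observation times.
#' @param floor_frac relative floor (default 0.05).
#' @return percent scalar.
#' @export
fit_error <- function(study, predictions, floor_frac = 0.05) {
  med <- median_trajectory(study, min_n = 1)
  floor_val <- floor_frac * max(med$values)
  errs <- unlist(lapply(study$trajectories, function(tr) {
    pr <- predictions[[tr$cell_id]]
    if (is.null(pr)) return(NULL)
    if (length(pr) != length(tr$values))
      stop("argument error: prediction length mismatch for cell ",
           tr$cell_id)
    abs(pr - tr$values) / max(mean(tr$values), floor_val)
  }))
  if (length(errs) == 0)
    stop("argument error: no cell has aligned predictions")
  100 * mean(errs)
}

#' Model predictions at each cell's observation times
#'
#' Convenience helper: given a parameter table (MAP or per-cell ML
#' estimates), simulates every cell from its first observation and returns
#' the noise-free predicted fluorescence at its sample times, for use with
#' [fit_error()].
#'
#' @param study a `study_dataset` (post-QC).
#' @param params_table data frame with `cell_id, k_m, g_m, k_p, g_p`.
#' @param pop the [population_model()] supplying delay and error model.
#' @param input an `input_signal`.
#' @export
predict_cells <- function(study, params_table, pop, input) {
  out <- list()
  for (tr in study$trajectories) {
    row <- params_table[params_table$cell_id == tr$cell_id, ]
    if (nrow(row) != 1) next
    cache <- make_cell_cache(tr, input, pop$tau_min)
    out[[tr$cell_id]] <- predict_cached(
      cache, c(row$k_m, row$g_m, row$k_p, row$g_p))
  }
  out
}

#' Fraction of data points inside a population envelope
#'
#' @param study a `study_dataset`.
#' @param env a `population_envelope` spanning the study horizon.
#' @return fraction in \[0, 1\].
#' @export
envelope_coverage <- function(study, env) {
  lo_f <- stats::approxfun(env$times, env$lower, rule = 2)
  up_f <- stats::approxfun(env$times, env$upper, rule = 2)
  inside <- unlist(lapply(study$trajectories, function(tr)
    tr$values >= lo_f(tr$times) & tr$values <= up_f(tr$times)))
  mean(inside)
}

#' Robustness of the SAEM fit to cell count and learning horizon
#'
#' Re-runs the SAEM fit on seeded random subsets of cells and/or on
#' trajectories truncated to a shorter learning horizon, and reports for
#' each condition the recovery error of the population log-means (when the
#' study carries its generating truth) and the envelope coverage of the
#' full-horizon data.
#'
#' @param study a post-QC `study_dataset`.
#' @param input an `input_signal`.
#' @param config a [saem_config()].
#' @param cell_counts cell counts to test; `NA` means all cells.
#' @param horizons_h learning horizons in hours.
#' @param n_virtual virtual cells per envelope.
#' @param seed subsampling seed.
#' @return data frame: `n_cells, horizon_h, mu_err, coverage`, where
#'   `mu_err` is the mean absolute error of the free log-mean components
#'   (NA without truth).
#' @export
robustness_experiment <- function(study, input, config = saem_config(),
                                  cell_counts = c(32, 64, 128, NA),
                                  horizons_h = 10, n_virtual = 2000,
                                  seed = 1) {
  truth_mu <- if (!is.null(study$truth)) study$truth$population$mu else NULL
  free <- c(1, 2, 4)   # ln k_p mean is clamped during estimation
  rows <- list()
  for (nc in cell_counts) for (hz in horizons_h) {
    set.seed(seed + 17 * length(rows))
    sub <- study
    if (!is.na(nc)) {
      ids <- sample(names(study$trajectories),
                    min(nc, length(study$trajectories)))
      sub$trajectories <- study$trajectories[sort(ids)]
    }
    sub$trajectories <- lapply(sub$trajectories, function(tr) {
      sel <- tr$times <= hz * 60
      tr$times <- tr$times[sel]
      tr$values <- tr$values[sel]
      tr
    })
    fit <- fit_saem(sub, input, config)
    env <- predict_population(fit$population, study$schedule,
                              n = n_virtual, with_noise = TRUE,
                              input = input)
    rows[[length(rows) + 1]] <- data.frame(
      n_cells = if (is.na(nc)) length(study$trajectories) else nc,
      horizon_h = hz,
      mu_err = if (is.null(truth_mu)) NA_real_
               else mean(abs(fit$population$mu[free] - truth_mu[free])),
      coverage = envelope_coverage(study, env))
  }
  do.call(rbind, rows)
}
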