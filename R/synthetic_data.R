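# symmetric PSD square root (chol fails on semi-definite matrices)
msqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Configuration of a synthetic single-cell study
#'
#' Defaults emulate a 10-hour repeated-osmotic-shock microscopy experiment:
#' ~300 cells sampled every 6 min, hour-spaced 8-min shocks, log-normal
#' parameters with strong cross-correlations ([default_population()]),
#' lineage-correlated parameters (an AR(1)-style mixture with coefficient
#' `rho_inherit` on the log scale), a per-cell latent shock gain that scales
#' the perceived stimulus and shifts `ln k_m` and `ln g_m` (so the composite
#' production rate and the mRNA degradation rate both correlate with the
#' perceived-shock feature), and physiological features statistically
#' coupled to `ln k_mp`.
#'
#' @param n_cells number of cells.
#' @param schedule a [shock_schedule()].
#' @param population a [population_model()] (the generating truth).
#' @param rho_inherit mother-daughter log-parameter correlation in \[0, 1).
#' @param founder_frac fraction of cells present at t = 0.
#' @param birth_range daughter birth-time range (minutes).
#' @param gain_sd SD of the latent per-cell log shock gain.
#' @param gain_coupling length-2 coupling of the log gain onto
#'   (`ln k_m`, `ln g_m`).
#' @param feature_coupling correlations of (density, size, age) with
#'   `ln k_mp`.
#' @param divrate_noise_sd relative noise on the division-rate feature
#'   (which equals `g_p / ln 2` up to this noise).
#' @param perceived_base,perceived_noise_sd scale and relative noise of the
#'   perceived-shock feature.
#' @param sample_dt fluorescence sampling interval (minutes).
#' @param min_mother_age minimal mother age at a division (minutes).
#' @param transport_delay_min,lag_min,grid_step_min input-signal settings
#'   passed to [build_input()].
#' @export
study_config <- function(n_cells = 300,
                         schedule = default_schedule(),
                         population = default_population(),
                         rho_inherit = 0.3,
                         founder_frac = 0.35,
                         birth_range = c(60, 540),
                         gain_sd = 0.15,
                         gain_coupling = c(1, 0.8),
                         feature_coupling = c(density = 0.3, size = 0.25,
                                              age = 0),
                         divrate_noise_sd = 0.05,
                         perceived_base = 0.10,
                         perceived_noise_sd = 0.10,
                         sample_dt = 6,
                         min_mother_age = 45,
                         transport_delay_min = 2,
                         lag_min = 2,
                         grid_step_min = 0.5) {
  if (rho_inherit < 0 || rho_inherit >= 1)
    stop("config error: rho_inherit must be in [0, 1)")
  if (gain_sd < 0 || divrate_noise_sd < 0 || perceived_noise_sd < 0)
    stop("config error: negative SDs")
  if (n_cells < 1) stop("config error: n_cells must be >= 1")
  if (any(abs(feature_coupling) > 1))
    stop("config error: feature couplings are correlations in [-1, 1]")
  structure(as.list(environment()), class = "study_config")
}

# feature = corr * standardized target + orthogonal noise
couple_to <- function(target, corr, n) {
  zt <- as.numeric(scale(target))
  if (stats::sd(target) == 0) zt <- rep(0, n)
  corr * zt + sqrt(1 - corr^2) * stats::rnorm(n)
}

#' Generate a complete synthetic study
#'
#' Draws founder log-parameters from the population, propagates them to
#' daughters through the lineage mixture, applies the latent shock gain,
#' simulates every cell's protein trajectory (daughters inherit their
#' mother's mRNA/protein state at birth), and observes fluorescence through
#' the delay + combined-noise model. Per-cell features and the lineage table
#' are generated alongside; the generating truth (per-cell parameters and
#' the population model) is attached.
#'
#' @param config a [study_config()].
#' @param seed optional integer seed (set before any draw).
#' @return object of class `study_dataset` with fields `trajectories`
#'   (named list of `cell_trajectory`), `features`, `lineage`, `truth`
#'   (list: `params` data frame, `gain`, `population`), `schedule`, `input`,
#'   `config`.
#' @export
generate_study <- function(config = study_config(), seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(seed)) set.seed(seed)
  pop <- config$population
  n <- config$n_cells
  T_end <- config$schedule$duration_min
  input <- build_input(config$schedule, config$transport_delay_min,
                       config$lag_min, config$grid_step_min)
  tau <- pop$tau_min
  err <- pop$error
  n_f <- max(1L, round(config$founder_frac * n))
  births <- c(rep(0, n_f),
              sort(stats::runif(n - n_f, config$birth_range[1],
                                min(config$birth_range[2], T_end))))
  ids <- sprintf("c%04d", seq_len(n))
  L <- msqrt(pop$sigma)
  rho <- config$rho_inherit

  z_base <- matrix(NA_real_, n, 4)
  mothers <- rep(NA_character_, n)
  z_base[seq_len(n_f), ] <- matrix(rep(pop$mu, each = n_f), n_f) +
    matrix(stats::rnorm(4 * n_f), n_f) %*% t(L)
  if (n > n_f) {
    for (i in (n_f + 1L):n) {
      eligible <- which(births <= births[i] - config$min_mother_age &
                        seq_len(n) < i)
      mi <- if (length(eligible) == 1L) eligible
            else sample(eligible, 1L)
      mothers[i] <- ids[mi]
      z_base[i, ] <- pop$mu + rho * (z_base[mi, ] - pop$mu) +
        sqrt(1 - rho^2) * drop(L %*% stats::rnorm(4))
    }
  }
  ln_s <- stats::rnorm(n, 0, config$gain_sd)
  z <- z_base
  z[, 1] <- z[, 1] + config$gain_coupling[1] * ln_s
  z[, 2] <- z[, 2] + config$gain_coupling[2] * ln_s

  frames <- seq(0, T_end, by = config$sample_dt)
  trajectories <- vector("list", n)
  names(trajectories) <- ids
  states <- vector("list", n)
  for (i in seq_len(n)) {
    pars <- cell_params(exp(z[i, 1]), exp(z[i, 2]), exp(z[i, 3]),
                        exp(z[i, 4]))
    b <- births[i]
    stimes <- frames[frames >= b]
    kid_births <- births[which(mothers == ids[i])]
    grid <- sort(unique(c(b, stimes, pmax(stimes - tau, b), kid_births,
                          T_end,
                          input$times[input$times > b &
                                      input$times < T_end])))
    init <- if (b == 0) c(0, 0) else {
      mi <- match(mothers[i], ids)
      stm <- states[[mi]]
      j <- match(b, stm$times)
      c(stm$m[j], stm$p[j])
    }
    st <- simulate_expression(pars, input, grid, init)
    states[[i]] <- st
    y <- observe_fluorescence(st, tau, stimes, err)
    trajectories[[i]] <- cell_trajectory(ids[i], stimes, y,
                                         birth_time_min = b,
                                         end_time_min = T_end)
  }

  lnkmp <- z[, 1] + z[, 3]
  fc <- config$feature_coupling
  features <- data.frame(
    cell_id = ids,
    mean_size = 20 * exp(0.15 * couple_to(lnkmp, fc[["size"]], n)),
    mean_age = pmax(0.2, 2 + 0.8 * couple_to(lnkmp, fc[["age"]], n)),
    mean_density = stats::plogis(0.8 * couple_to(lnkmp, fc[["density"]], n)),
    division_rate = exp(z[, 4]) / log(2) *
      (1 + stats::rnorm(n, 0, config$divrate_noise_sd)),
    perceived_shock = config$perceived_base * exp(ln_s) *
      (1 + stats::rnorm(n, 0, config$perceived_noise_sd)),
    stringsAsFactors = FALSE)

  keep <- !is.na(mothers)
  lineage <- data.frame(daughter_id = ids[keep], mother_id = mothers[keep],
                        birth_time_min = births[keep],
                        stringsAsFactors = FALSE)
  truth_params <- data.frame(cell_id = ids, k_m = exp(z[, 1]),
                             g_m = exp(z[, 2]), k_p = exp(z[, 3]),
                             g_p = exp(z[, 4]),
                             k_mp = exp(z[, 1] + z[, 3]),
                             stringsAsFactors = FALSE)
  structure(list(trajectories = trajectories, features = features,
                 lineage = lineage,
                 truth = list(params = truth_params, gain = exp(ln_s),
                              population = pop),
                 schedule = config$schedule, input = input,
                 config = config),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(if (!is.null(x$truth)) "Study dataset (with generating truth):"
      else "Study dataset:",
      length(x$trajectories), "cells,",
      nrow(x$lineage), "lineage links\n")
  invisible(x)
}

#' Quality-control filters on a study
#'
#' Applies the two standard filters used for identification: cells imaged
#' for more than `min_hours` (strictly) are kept, all others removed; and
#' for cells born after t = 0, samples acquired within the first
#' `newborn_discard_hours` after birth are dropped (newly detected buds show
#' quantification artifacts). Features, lineage and truth tables are subset
#' to the surviving cells; lineage rows referencing a removed mother or
#' daughter are dropped.
#'
#' @param study a `study_dataset`.
#' @param min_hours minimal observation window (hours, strict).
#' @param newborn_discard_hours initial window discarded for cells born
#'   during the experiment (hours).
#' @export
apply_qc_filters <- function(study, min_hours = 5,
                             newborn_discard_hours = 2) {
  keep <- vapply(study$trajectories, function(tr)
    (tr$end_time_min - tr$birth_time_min) > min_hours * 60, logical(1))
  trajs <- study$trajectories[keep]
  trajs <- lapply(trajs, function(tr) {
    if (tr$birth_time_min > 0) {
      sel <- (tr$times - tr$birth_time_min) >= newborn_discard_hours * 60
      tr$times <- tr$times[sel]
      tr$values <- tr$values[sel]
    }
    tr
  })
  ids <- names(trajs)
  study$trajectories <- trajs
  study$features <- study$features[study$features$cell_id %in% ids, ,
                                   drop = FALSE]
  rownames(study$features) <- NULL
  study$lineage <- study$lineage[study$lineage$daughter_id %in% ids &
                                 study$lineage$mother_id %in% ids, ,
                                 drop = FALSE]
  rownames(study$lineage) <- NULL
  if (!is.null(study$truth)) {
    study$truth$gain <- study$truth$gain[study$truth$params$cell_id %in% ids]
    study$truth$params <-
      study$truth$params[study$truth$params$cell_id %in% ids, ,
                         drop = FALSE]
    rownames(study$truth$params) <- NULL
  }
  study
}
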