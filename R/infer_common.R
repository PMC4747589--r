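# Shared machinery for the likelihood-based fitting stages.
#
# A "cell cache" freezes everything about one cell's likelihood that does
# not depend on the kinetic parameters: the merged simulation grid (input
# breakpoints + delayed observation times), the piecewise-constant input on
# it, the grid indices of the delayed observation times, the data, and the
# initial state. Re-evaluating the likelihood for new parameters is then a
# single compiled propagation plus a Gaussian density sum.

make_cell_cache <- function(traj, input, tau_min,
                            init_policy = "first_obs") {
  t_start <- min(input$times[1], traj$times[1])
  t_end <- traj$times[length(traj$times)]
  # the first observation measures matured protein at t1 - tau: that is
  # where the protein anchor belongs
  t0 <- max(traj$times[1] - tau_min, t_start)
  tq <- pmax(traj$times - tau_min, t0)
  grid <- sort(unique(c(t_start, t0, tq, t_end,
                        input$times[input$times > t_start &
                                    input$times < t_end])))
  init <- if (is.numeric(init_policy)) init_policy
          else c(0, max(traj$values[1], 0))
  list(cell_id = traj$cell_id,
       grid = grid,
       u = input_segments(input, grid),
       qidx = match(tq, grid),
       # mRNA propagates from the start of the stimulus history (m = 0
       # before the first stimulus); protein is re-anchored at the delayed
       # time of the cell's first observation
       reset_idx = match(t0, grid),
       y = traj$values,
       m0 = init[1], p0 = init[2],
       n_obs = length(traj$values))
}

predict_cached <- function(cache, th) {
  cpp_predict(cache$grid, cache$u, th[1], th[2], th[3], th[4],
              cache$m0, cache$p0, cache$qidx, cache$reset_idx)
}

loglik_cached <- function(cache, th, sigma_add, sigma_mult) {
  p <- predict_cached(cache, th)
  v <- sigma_add^2 + sigma_mult^2 * p * p
  r <- cache$y - p
  -0.5 * sum(log(2 * pi * v) + r * r / v)
}

# default literature-style rate means used to initialize searches
literature_params <- function() {
  cell_params(k_m = 3, g_m = 0.06, k_p = 1, g_p = 0.005)
}

# frame-wise median trajectory across cells (frames observed by >= min_n
# cells), used by the mean-cell fit
median_trajectory <- function(study, min_n = 5) {
  all_t <- sort(unique(unlist(lapply(study$trajectories, `[[`, "times"))))
  med <- counts <- numeric(length(all_t))
  for (k in seq_along(all_t)) {
    v <- unlist(lapply(study$trajectories, function(tr) {
      j <- match(all_t[k], tr$times)
      if (is.na(j)) NULL else tr$values[j]
    }))
    counts[k] <- length(v)
    med[k] <- if (length(v)) stats::median(v) else NA_real_
  }
  keep <- counts >= min_n & !is.na(med)
  if (!any(keep)) stop("fit error: no frames observed by enough cells")
  cell_trajectory("median_cell", all_t[keep], med[keep])
}
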