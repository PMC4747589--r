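#' Shock schedule: valve on/off intervals
#'
#' Describes the temporal pattern of hyperosmotic stimulation in a
#' microfluidic experiment: an ordered set of intervals during which the
#' valve delivers hyperosmotic medium, within an experiment of total length
#' `duration_min`.
#'
#' @param intervals numeric matrix (or 2-column coercible object) with one
#'   row per shock, columns `start_min` and `end_min`. May have zero rows.
#' @param duration_min total experiment length in minutes.
#' @return an object of class `shock_schedule`.
#' @examples
#' sched <- shock_schedule(cbind(c(30, 90), c(38, 98)), duration_min = 200)
#' @export
shock_schedule <- function(intervals, duration_min) {
  if (is.null(intervals) || length(intervals) == 0L) {
    intervals <- matrix(numeric(0), ncol = 2)
  }
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2)
    stop("schedule error: intervals must have two columns (start_min, end_min)")
  storage.mode(intervals) <- "double"
  colnames(intervals) <- c("start_min", "end_min")
  if (!is.numeric(duration_min) || length(duration_min) != 1 ||
      !is.finite(duration_min) || duration_min <= 0)
    stop("schedule error: duration_min must be a positive scalar")
  if (nrow(intervals) > 0) {
    if (any(!is.finite(intervals)))
      stop("schedule error: non-finite interval bounds")
    if (any(intervals[, 1] >= intervals[, 2]))
      stop("schedule error: every interval must have start < end")
    if (any(intervals[, 1] < 0) || any(intervals[, 2] > duration_min))
      stop("schedule error: intervals must lie within [0, duration_min]")
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    if (nrow(intervals) > 1 &&
        any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
      stop("schedule error: intervals overlap")
  }
  structure(list(intervals = intervals, duration_min = duration_min),
            class = "shock_schedule")
}

#' Default repeated-shock schedule
#'
#' Eight 8-minute shocks, one every 60 minutes starting at t = 30 min, in a
#' 10-hour experiment. This mimics the cadence of hour-spaced repeated
#' osmotic shocks used in long time-lapse experiments.
#'
#' @param n_shocks number of shocks.
#' @param shock_min shock duration (minutes).
#' @param period_min time between shock onsets (minutes).
#' @param first_min onset of the first shock (minutes).
#' @param duration_min experiment length (minutes).
#' @export
default_schedule <- function(n_shocks = 8, shock_min = 8, period_min = 60,
                             first_min = 30, duration_min = 600) {
  starts <- first_min + period_min * seq_len(n_shocks) - period_min
  shock_schedule(cbind(starts, starts + shock_min), duration_min)
}

#' @export
print.shock_schedule <- function(x, ...) {
  cat("Shock schedule:", nrow(x$intervals), "shock(s) over",
      x$duration_min, "min\n")
  if (nrow(x$intervals) > 0) {
    cat(paste0("  [", x$intervals[, 1], ", ", x$intervals[, 2], ") min",
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read / write a shock schedule (JSON)
#'
#' The on-disk format is `{"intervals": [[start,end], ...],
#' "duration_min": T}`; numbers round-trip at full double precision.
#'
#' @param path file path.
#' @export
read_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- x$intervals
  if (is.null(iv) || length(iv) == 0L) iv <- matrix(numeric(0), ncol = 2)
  shock_schedule(iv, x$duration_min)
}

#' @rdname read_schedule
#' @param schedule a `shock_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  iv <- schedule$intervals
  dimnames(iv) <- NULL
  jsonlite::write_json(list(intervals = iv,
                            duration_min = schedule$duration_min),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Transcription-factor activity signal driving the expression model
#'
#' Converts the valve schedule into the normalized activity signal u(t) in
#' \[0,1\] that multiplies the transcription rate. The valve indicator is
#' shifted by the fluid transport delay and passed through a first-order lag
#' (time constant `lag_min`) standing in for the diffusion-limited exchange
#' of the imaging chamber and the sensing/signaling response; `lag_min = 0`
#' gives the pure shifted indicator.
#'
#' The signal is stored piecewise-constant on a grid that contains all
#' (shifted) valve switching times plus a regular grid of step
#' `grid_step_min`. Each stored value is the exact time average of the
#' continuous lagged response over its grid cell, so the discrete signal
#' carries exactly the integral of the continuous one (the lag filter has
#' unit DC gain: the activity mass of a pulse equals the valve-open time).
#'
#' @param schedule a [shock_schedule()].
#' @param transport_delay_min delay between valve switch and chamber
#'   osmolarity change (minutes); default 2, the typical fluid transit time.
#' @param lag_min first-order lag time constant (minutes).
#' @param grid_step_min regular grid step (minutes).
#' @return an object of class `input_signal` with fields `times` (grid,
#'   covering \[0, duration\]) and `values` (`values[k]` holds on
#'   `[times[k], times[k+1])`; `length(values) == length(times)`, the last
#'   value extends to the end of the grid).
#' @export
build_input <- function(schedule, transport_delay_min = 2, lag_min = 2,
                        grid_step_min = 0.5) {
  if (!inherits(schedule, "shock_schedule"))
    stop("schedule error: not a shock_schedule")
  if (!is.numeric(grid_step_min) || grid_step_min <= 0)
    stop("argument error: grid_step_min must be positive")
  if (transport_delay_min < 0 || lag_min < 0)
    stop("argument error: delay and lag must be non-negative")
  T_end <- schedule$duration_min
  iv <- schedule$intervals
  breaks <- sort(unique(c(
    seq(0, T_end, by = grid_step_min), T_end,
    pmin(pmax(as.vector(iv + transport_delay_min), 0), T_end))))
  nseg <- length(breaks) - 1L
  # valve indicator (shifted) per segment
  seg_start <- breaks[-length(breaks)]
  v <- rep(0, nseg)
  if (nrow(iv) > 0) {
    s <- iv[, 1] + transport_delay_min
    e <- iv[, 2] + transport_delay_min
    for (j in seq_len(nrow(iv))) v[seg_start >= s[j] & seg_start < e[j]] <- 1
  }
  if (lag_min == 0) {
    avg <- v
  } else {
    avg <- numeric(nseg)
    u0 <- 0
    for (k in seq_len(nseg)) {
      dt <- breaks[k + 1L] - breaks[k]
      E <- exp(-dt / lag_min)
      avg[k] <- v[k] + (u0 - v[k]) * lag_min * (1 - E) / dt
      u0 <- v[k] + (u0 - v[k]) * E
    }
  }
  values <- c(avg, avg[nseg])  # hold last value at the terminal grid point
  structure(list(times = breaks, values = values), class = "input_signal")
}

#' Total activity mass of an input signal
#'
#' Integral of the piecewise-constant signal over its grid; with zero lag
#' this equals total valve-open time exactly, and with lag it equals the
#' valve-open time minus the (exponentially small) mass carried past the end
#' of the grid.
#'
#' @param input an `input_signal`.
#' @export
input_mass <- function(input) {
  dt <- diff(input$times)
  sum(dt * input$values[seq_along(dt)])
}

# piecewise-constant segment values of u for an arbitrary breakpoint grid
# `grid` (must be a refinement compatible with input$times)
input_segments <- function(input, grid) {
  idx <- findInterval(grid[-length(grid)], input$times,
                      rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  input$values[idx]
}
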