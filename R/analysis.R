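spikes_of <- function(x, layer = "V1") {
  if (inherits(x, "sim_result")) {
    st <- x$spikes$time_ms[x$spikes$layer == layer]
  } else if (is.data.frame(x)) {
    st <- if ("layer" %in% names(x)) x$time_ms[x$layer == layer] else x$time_ms
  } else {
    st <- as.numeric(x)
  }
  sort(st)
}

#' Moving-bin population spike count
#'
#' The model's response measure: the total number of spikes N_sp of a layer
#' inside a sliding window of width T_bin (50 ms by default), evaluated on a
#' regular grid of window start times. With step = T_bin the windows tile
#' the run and the counts sum to the total spike count.
#'
#' @param x a \code{sim_result}, a spikes data.frame, or a numeric vector of
#'   spike times (ms).
#' @param T_bin window width (ms).
#' @param step spacing of window start times (ms); default 1 ms.
#' @param layer which layer to count ("V1" or "LGN").
#' @param t_start,t_end analysis range (ms); windows start at
#'   \code{t_start, t_start + step, ...} up to \code{t_end - T_bin}.
#' @return object of class \code{response_trace}: data.frame(time_ms, count)
#'   where \code{time_ms} is the window START; the window covers
#'   \[time_ms, time_ms + T_bin).
#' @examples
#' tr <- moving_bin_counts(c(100), T_bin = 50, step = 1, t_end = 200)
#' range(tr$time_ms[tr$count == 1])  # windows starting in (50, 100]
#' @export
moving_bin_counts <- function(x, T_bin = 50, step = 1, layer = "V1",
                              t_start = 0, t_end = NULL) {
  stopifnot(T_bin > 0, step > 0)
  if (is.null(t_end)) {
    t_end <- if (inherits(x, "sim_result")) x$protocol$duration
      else max(c(spikes_of(x, layer), t_start + T_bin))
  }
  st <- spikes_of(x, layer)
  t0 <- seq(t_start, t_end - T_bin, by = step)
  # spikes in [t, t + T_bin): strictly fewer than t counts subtracted
  n_lt <- function(v) findInterval(v - 1e-9, st)
  counts <- n_lt(t0 + T_bin) - n_lt(t0)
  structure(data.frame(time_ms = t0, count = counts),
            class = c("response_trace", "data.frame"),
            T_bin = T_bin, step = step, layer = layer)
}

#' @export
print.response_trace <- function(x, ...) {
  cat(sprintf("Response trace: %d windows of %g ms (step %g ms), layer %s\n",
              nrow(x), attr(x, "T_bin"), attr(x, "step"), attr(x, "layer")))
  cat(sprintf("  peak N_sp = %d, mean = %.2f\n", max(x$count), mean(x$count)))
  invisible(x)
}

#' @export
plot.response_trace <- function(x, ...) {
  graphics::plot(x$time_ms, x$count, type = "l", xlab = "time (ms)",
                 ylab = sprintf("N_sp per %g ms bin", attr(x, "T_bin")), ...)
  invisible(x)
}

#' Per-neuron spike counts in one window
#'
#' Spatial response profile: the spike count N_sp(i) of each neuron of a
#' layer inside the window \[at_time, at_time + T_bin). Summing over neurons
#' reproduces the population count of the same window.
#'
#' @param x a \code{sim_result} or spikes data.frame.
#' @param at_time window start (ms).
#' @param T_bin window width (ms).
#' @param layer layer to count.
#' @param N neuron count (taken from the sim result when available).
#' @return integer vector of length N.
#' @export
per_neuron_bin_counts <- function(x, at_time, T_bin = 50, layer = "V1",
                                  N = NULL) {
  if (inherits(x, "sim_result")) {
    if (is.null(N)) N <- x$params$N
    df <- x$spikes
  } else df <- x
  if (is.null(N)) N <- max(df$neuron)
  sel <- df$layer == layer & df$time_ms >= at_time &
    df$time_ms < at_time + T_bin
  tabulate(df$neuron[sel], nbins = N)
}

#' Post-event response peak
#'
#' Maximum moving-bin count in the window (event_time, event_time + window\].
#'
#' @param trace a \code{response_trace}.
#' @param event_time event onset (ms).
#' @param window search window after the event (ms); the 200 ms default
#'   brackets the transient response without reaching the next event of a
#'   4 Hz train.
#' @return peak N_sp (0 for an empty window).
#' @export
response_peak <- function(trace, event_time, window = 200) {
  stopifnot(window > 0)
  if (event_time + window > max(trace$time_ms) + attr(trace, "step"))
    warning("search window extends beyond the trace; truncated")
  sel <- trace$time_ms > event_time & trace$time_ms <= event_time + window
  if (!any(sel)) return(0)
  max(trace$count[sel])
}

#' Time to complete fading after an event
#'
#' Time, relative to the event, at which the population response first
#' returns to zero (an entire T_bin window without a spike) after the
#' post-event peak. Returns 0 with the flag "no_activity" when the event
#' evoked nothing, and NA with the flag "never_fades" when the count never
#' returns to zero within the trace.
#'
#' @param trace a \code{response_trace}.
#' @param event_time event onset (ms).
#' @param window window passed to \code{\link{response_peak}}.
#' @return fading time (ms) with attribute \code{flag} ("ok", "no_activity",
#'   or "never_fades").
#' @export
fading_time <- function(trace, event_time, window = 200) {
  peak <- response_peak(trace, event_time, window)
  if (peak == 0)
    return(structure(0, flag = "no_activity"))
  sel <- which(trace$time_ms > event_time & trace$time_ms <= event_time + window)
  t_peak <- trace$time_ms[sel[which.max(trace$count[sel])]]
  after <- which(trace$time_ms > t_peak & trace$count == 0)
  if (length(after) == 0)
    return(structure(NA_real_, flag = "never_fades"))
  structure(trace$time_ms[after[1]] - event_time, flag = "ok")
}

#' Average population activity
#'
#' Mean moving-bin count after discarding an initial transient (500 ms by
#' default, enough to exclude the fixation-onset response).
#'
#' @param trace a \code{response_trace}.
#' @param discard initial transient to drop (ms).
#' @return mean N_sp.
#' @export
average_activity <- function(trace, discard = 500) {
  sel <- trace$time_ms >= discard
  if (!any(sel)) stop("trace shorter than the discard interval", call. = FALSE)
  mean(trace$count[sel])
}

#' Sensitivity of average activity to a swept parameter
#'
#' Finite-difference slope of the mean response versus the sweep parameter:
#' central differences in the interior, one-sided at the edges.
#'
#' @param sweep a \code{sweep_result} (or data.frame with columns param and
#'   mean).
#' @return data.frame(param, slope).
#' @export
sensitivity_curve <- function(sweep) {
  s <- if (inherits(sweep, "sweep_result")) sweep$summary else sweep
  stopifnot(nrow(s) >= 3)
  xv <- s$param; yv <- s$mean
  n <- length(xv)
  slope <- numeric(n)
  slope[1] <- (yv[2] - yv[1]) / (xv[2] - xv[1])
  slope[n] <- (yv[n] - yv[n - 1]) / (xv[n] - xv[n - 1])
  if (n > 2)
    slope[2:(n - 1)] <- (yv[3:n] - yv[1:(n - 2)]) / (xv[3:n] - xv[1:(n - 2)])
  data.frame(param = xv, slope = slope)
}
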