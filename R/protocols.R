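#' @title Stimulus and microsaccade protocols
#' @description Constructors for the time course of the fixated-dot
#'   brightness A(t) and position x_f(t). A protocol holds piecewise-constant
#'   brightness segments, an ordered list of microsaccade events (onset,
#'   magnitude, direction, duration), and the flash-onset times. Microsaccades
#'   are instantaneous displacements by default; events with a positive
#'   duration move the dot at constant velocity (the finite-velocity mode,
#'   with the canonical 15 ms saccade duration).
#' @name protocols
NULL

new_protocol <- function(duration, brightness, events, flash_onsets, label) {
  stopifnot(duration > 0)
  events <- validate_events(events, duration)
  structure(list(duration = duration, brightness = brightness,
                 events = events, flash_onsets = flash_onsets, label = label),
            class = "protocol")
}

validate_events <- function(events, duration = Inf) {
  if (is.null(events) || nrow(events) == 0)
    return(data.frame(onset = numeric(0), magnitude = numeric(0),
                      direction = numeric(0), duration = numeric(0)))
  stopifnot(all(c("onset", "magnitude", "direction", "duration") %in% names(events)))
  if (is.unsorted(events$onset)) stop("events must be sorted by onset", call. = FALSE)
  if (any(events$onset < 0) || any(events$onset >= duration))
    stop("event onsets must lie within [0, duration)", call. = FALSE)
  if (any(events$magnitude < 0)) stop("event magnitudes must be >= 0", call. = FALSE)
  if (any(events$duration < 0)) stop("event durations must be >= 0", call. = FALSE)
  if (!all(events$direction %in% c(-1, 1)))
    stop("event directions must be +1 or -1", call. = FALSE)
  n <- nrow(events)
  if (n > 1) {
    ends <- events$onset + events$duration
    if (any(ends[-n] > events$onset[-1]))
      stop("finite-duration events overlap", call. = FALSE)
  }
  events
}

#' Stationary stimulus protocol
#'
#' The fixated dot is permanently on at brightness A, at position 0, with no
#' microsaccades (add events with \code{\link{add_saccades}}).
#'
#' @param duration total simulated time (ms).
#' @param A stimulus brightness: peak LGN rate (spikes/s).
#' @return a \code{protocol} object.
#' @examples
#' stationary_protocol(1000, A = 50)
#' @export
stationary_protocol <- function(duration, A = 50) {
  new_protocol(duration,
               brightness = data.frame(t_start = 0, A = A),
               events = NULL, flash_onsets = 0, label = "stationary")
}

#' Periodically flashing stimulus protocol
#'
#' Brightness cycles between A for T_on and 0 for T_off, starting with an
#' on-phase at t = 0. With T_off = 0 the protocol reduces to the stationary
#' stimulus.
#'
#' @param T_on on-phase duration (ms), > 0.
#' @param T_off off-phase duration (ms), >= 0.
#' @param duration total simulated time (ms).
#' @param A on-phase brightness (spikes/s).
#' @return a \code{protocol} object whose \code{flash_onsets} lists every
#'   on-phase start.
#' @examples
#' p <- flashing_protocol(T_on = 1000, T_off = 1000, duration = 4000)
#' p$flash_onsets  # 0 2000
#' @export
flashing_protocol <- function(T_on, T_off, duration, A = 50) {
  stopifnot(T_on > 0, T_off >= 0)
  if (T_off == 0) {
    p <- stationary_protocol(duration, A)
    p$label <- "flashing"
    return(p)
  }
  cycle <- T_on + T_off
  starts <- (0:ceiling(duration / cycle)) * cycle
  starts <- starts[starts < duration - 1e-9]
  t_start <- sort(c(starts, starts + T_on))
  t_start <- t_start[t_start < duration]
  Avec <- ifelse((t_start %% cycle) < T_on, A, 0)
  new_protocol(duration,
               brightness = data.frame(t_start = t_start, A = Avec),
               events = NULL, flash_onsets = starts, label = "flashing")
}

#' A single microsaccade event
#'
#' @param t_m onset time (ms).
#' @param delta_M microsaccade magnitude (position units), >= 0.
#' @param direction +1 or -1.
#' @param duration movement duration (ms); 0 = instantaneous displacement,
#'   positive values give a constant-velocity trajectory.
#' @return one-row event data.frame.
#' @examples
#' single_saccade(2000, delta_M = 2.0)
#' @export
single_saccade <- function(t_m, delta_M, direction = 1, duration = 0) {
  stopifnot(t_m >= 0)
  data.frame(onset = t_m, magnitude = delta_M,
             direction = direction, duration = duration)
}

saccade_directions <- function(n, policy) {
  if (is.numeric(policy)) return(rep_len(policy, n))
  switch(policy,
         random = sample(c(-1, 1), n, replace = TRUE),
         alternating = rep_len(c(1, -1), n),
         fixed = rep(1, n),
         stop("unknown direction policy: ", policy, call. = FALSE))
}

#' Periodic microsaccade train
#'
#' Events at times t_start, t_start + 1000/F, ... (ms) up to the duration.
#'
#' @param F_hz microsaccade frequency (Hz), > 0.
#' @param delta_M magnitude of every event.
#' @param duration schedule length (ms).
#' @param t_start time of the first event (ms).
#' @param direction "random" (uniform, the default), "alternating", "fixed",
#'   or a numeric vector of +1/-1 recycled over events. The random policy
#'   consumes the R RNG stream.
#' @return event data.frame.
#' @examples
#' nrow(periodic_saccades(4, 2.0, duration = 2000))  # 8 events
#' @export
periodic_saccades <- function(F_hz, delta_M, duration, t_start = 0,
                              direction = "random") {
  stopifnot(F_hz > 0)
  onsets <- t_start + (0:ceiling((duration - t_start) * F_hz / 1000)) *
    (1000 / F_hz)
  onsets <- onsets[onsets < duration - 1e-9]
  data.frame(onset = onsets, magnitude = delta_M,
             direction = saccade_directions(length(onsets), direction),
             duration = 0)
}

#' Poisson microsaccade train
#'
#' Onsets drawn from a homogeneous Poisson process at rate F; reproducible
#' for a fixed seed. Trains are truncated at the duration and no minimum
#' inter-event interval is imposed.
#'
#' @inheritParams periodic_saccades
#' @param t_start events are drawn on \[t_start, duration\].
#' @param seed optional integer seed; when given the caller's RNG state is
#'   saved and restored.
#' @return event data.frame.
#' @export
poisson_saccades <- function(F_hz, delta_M, duration, t_start = 0,
                             direction = "random", seed = NULL) {
  stopifnot(F_hz > 0)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  span <- duration - t_start
  n_draw <- max(16, ceiling(F_hz / 1000 * span + 6 * sqrt(F_hz / 1000 * span)))
  gaps <- stats::rexp(n_draw, rate = F_hz / 1000)
  while (sum(gaps) < span)
    gaps <- c(gaps, stats::rexp(n_draw, rate = F_hz / 1000))
  onsets <- t_start + cumsum(gaps)
  onsets <- onsets[onsets < duration]
  data.frame(onset = onsets, magnitude = delta_M,
             direction = saccade_directions(length(onsets), direction),
             duration = 0)
}

#' Give microsaccade events a finite constant-velocity trajectory
#'
#' Sets every event's movement duration (default 15 ms, the canonical human
#' microsaccade duration), so that x_f ramps linearly from the pre- to the
#' post-saccadic position; the velocity is magnitude/duration. Events must
#' not overlap once widened.
#'
#' @param events event data.frame.
#' @param duration_per_saccade movement duration (ms).
#' @return event data.frame with the duration column set.
#' @export
finite_velocity_events <- function(events, duration_per_saccade = 15) {
  stopifnot(duration_per_saccade >= 0)
  events$duration <- duration_per_saccade
  validate_events(events)
}

#' Attach microsaccade events to a protocol
#'
#' @param protocol a \code{protocol} object.
#' @param events event data.frame (rows are merged with any existing events
#'   and sorted by onset).
#' @return the protocol with events attached.
#' @export
add_saccades <- function(protocol, events) {
  stopifnot(inherits(protocol, "protocol"))
  ev <- rbind(protocol$events, events)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  protocol$events <- validate_events(ev, protocol$duration)
  protocol
}

#' Evaluate the fixation path x_f(t) of a protocol
#'
#' Piecewise-constant (instantaneous events) or continuous piecewise-linear
#' (finite-velocity events) raw displacement path, starting at 0. Positions
#' are wrapped onto the ring only when rates are evaluated, so the raw path
#' records the cumulative displacement.
#'
#' @param protocol a \code{protocol} object.
#' @param t times (ms).
#' @param L optional half-width; when given, the wrapped position is
#'   returned.
#' @return x_f at each t.
#' @export
fixation_path <- function(protocol, t, L = NULL) {
  ev <- protocol$events
  x <- numeric(length(t))
  for (k in seq_len(nrow(ev))) {
    on <- ev$onset[k]; dur <- ev$duration[k]
    amp <- ev$direction[k] * ev$magnitude[k]
    x <- x + if (dur == 0) amp * (t >= on)
      else amp * pmin(pmax((t - on) / dur, 0), 1)
  }
  if (!is.null(L)) x <- wrap_position(x, L)
  x
}

# Compile a protocol into the segment table consumed by the C++ core:
# rows (t0, t1, xf0, slope, A) with piecewise-linear raw x_f and piecewise-
# constant brightness.
compile_protocol <- function(protocol) {
  ev <- protocol$events
  dur <- protocol$duration
  breaks <- c(0, protocol$brightness$t_start, ev$onset,
              ev$onset + ev$duration, dur)
  breaks <- sort(unique(breaks[breaks >= 0 & breaks <= dur]))
  t0 <- breaks[-length(breaks)]
  t1 <- breaks[-1]
  xf0 <- fixation_path(protocol, t0)
  slope <- numeric(length(t0))
  for (k in seq_len(nrow(ev))) {
    if (ev$duration[k] > 0) {
      act <- t0 >= ev$onset[k] & t0 < ev$onset[k] + ev$duration[k]
      slope[act] <- slope[act] + ev$direction[k] * ev$magnitude[k] / ev$duration[k]
    }
  }
  bidx <- findInterval(t0, protocol$brightness$t_start)
  A <- protocol$brightness$A[pmax(bidx, 1)]
  cbind(t0 = t0, t1 = t1, xf0 = xf0, slope = slope, A = A)
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("Protocol '%s': %g ms, %d microsaccade event(s), %d flash onset(s)\n",
              x$label, x$duration, nrow(x$events), length(x$flash_onsets)))
  if (nrow(x$events) > 0) {
    m <- utils::head(x$events, 5)
    cat(sprintf("  first events at %s ms (Delta_M = %s)\n",
                paste(signif(m$onset, 6), collapse = ", "),
                paste(unique(x$events$magnitude), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize / restore a protocol as JSON
#'
#' @param protocol a \code{protocol} object.
#' @param path file path; for \code{protocol_to_json} the target file.
#' @return \code{protocol_from_json} returns the restored protocol.
#' @export
protocol_to_json <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname protocol_to_json
#' @export
protocol_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_protocol(raw$duration,
               brightness = as.data.frame(raw$brightness),
               events = if (length(raw$events$onset) > 0) as.data.frame(raw$events) else NULL,
               flash_onsets = raw$flash_onsets, label = raw$label)
}
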