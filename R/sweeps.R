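new_sweep_result <- function(data, param_name, measure, extra = list()) {
  agg <- stats::aggregate(value ~ param, data, function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  summary <- data.frame(param = agg$param,
                        mean = agg$value[, "mean"],
                        sd = agg$value[, "sd"],
                        n = agg$value[, "n"])
  structure(c(list(data = data, summary = summary,
                   param_name = param_name, measure = measure), extra),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep of %s (%d values), measure: %s, %d replicate(s)\n",
              x$param_name, nrow(x$summary), x$measure, max(x$summary$n)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$param, s$mean, type = "b", pch = 19,
                 xlab = x$param_name, ylab = x$measure, ...)
  if (max(s$n) > 1) {
    se <- s$sd / sqrt(s$n)
    graphics::arrows(s$param, s$mean - se, s$param, s$mean + se,
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

run_with_events <- function(params, protocol, events, seed, network,
                            sample_every = 0) {
  protocol <- add_saccades(protocol, events)
  run_simulation(params, protocol, seed = derive_seed(seed, 2),
                 sample_every = sample_every, network = network)
}

#' Average V1 activity versus microsaccade frequency
#'
#' For each frequency F, microsaccades of fixed magnitude are generated as a
#' Poisson (or periodic) train over a stationary stimulus and the average
#' moving-bin V1 activity after the onset transient is measured, replicated
#' over seeds. The returned object also carries the finite-difference
#' sensitivity of the mean activity to F.
#'
#' @param params a \code{std_params} object.
#' @param F_grid microsaccade frequencies (Hz).
#' @param delta_M microsaccade magnitude.
#' @param mode "poisson" or "periodic" event trains.
#' @param seeds integer vector of replicate seeds.
#' @param duration run length per simulation (ms).
#' @param discard onset transient excluded from the average (ms).
#' @param network optional prebuilt network.
#' @return \code{sweep_result} with element \code{sensitivity}.
#' @export
frequency_sweep <- function(params, F_grid, delta_M = 2.0, mode = "poisson",
                            seeds = 1:20, duration = 30000, discard = 500,
                            network = NULL) {
  stopifnot(all(F_grid > 0))
  if (is.null(network)) network <- build_network(params)
  rows <- list()
  for (F_hz in F_grid) {
    for (s in seeds) {
      set.seed(derive_seed(s, 1))
      ev <- if (mode == "poisson")
        poisson_saccades(F_hz, delta_M, duration)
      else periodic_saccades(F_hz, delta_M, duration)
      sim <- run_with_events(params, stationary_protocol(duration, params$A),
                             ev, s, network)
      tr <- moving_bin_counts(sim, T_bin = params$T_bin)
      rows[[length(rows) + 1]] <-
        data.frame(param = F_hz, seed = s,
                   value = average_activity(tr, discard))
    }
  }
  res <- new_sweep_result(do.call(rbind, rows), "F (Hz)", "average N_sp")
  if (nrow(res$summary) >= 3) res$sensitivity <- sensitivity_curve(res)
  res
}

#' Response peak versus microsaccade magnitude
#'
#' From the adapted state (a stationary warm-up), a single instantaneous
#' microsaccade of each magnitude is applied and the post-saccade response
#' peak measured, averaged over seeds. Defaults follow the
#' large-response condition (g = 0.2, A = 100) under which the saturation of
#' the peak for large magnitudes is probed.
#'
#' @param params a \code{std_params} object; default g = 0.2, A = 100.
#' @param delta_M_grid magnitudes to test (position units).
#' @param seeds replicate seeds.
#' @param warmup stationary adaptation time before the saccade (ms).
#' @param window peak search window (ms).
#' @param network optional prebuilt network.
#' @return \code{sweep_result}.
#' @export
magnitude_sweep <- function(params = model_parameters(g = 0.2, A = 100),
                            delta_M_grid = c(0.5, 1, 2, 3, 4.5, 6, 9),
                            seeds = 1:20, warmup = 2000, window = 200,
                            network = NULL) {
  if (is.null(network)) network <- build_network(params)
  duration <- warmup + window + 300
  rows <- list()
  for (dm in delta_M_grid) {
    for (s in seeds) {
      set.seed(derive_seed(s, 1))
      sim <- run_with_events(params, stationary_protocol(duration, params$A),
                             single_saccade(warmup, dm), s, network)
      tr <- moving_bin_counts(sim, T_bin = params$T_bin)
      rows[[length(rows) + 1]] <-
        data.frame(param = dm, seed = s,
                   value = response_peak(tr, warmup, window))
    }
  }
  new_sweep_result(do.call(rbind, rows), "Delta_M", "peak N_sp")
}

#' Response peak versus microsaccade velocity
#'
#' Constant-velocity microsaccades with a fixed 15 ms duration: each
#' velocity v is realised as a single saccade of magnitude v * 15 whose
#' trajectory ramps linearly over the 15 ms, applied from the adapted state.
#'
#' @param params a \code{std_params} object; default g = 0.2, A = 100.
#' @param velocity_grid velocities (position units / ms).
#' @param seeds replicate seeds.
#' @param saccade_duration movement duration (ms).
#' @param warmup stationary adaptation time (ms).
#' @param window peak search window (ms).
#' @param network optional prebuilt network.
#' @return \code{sweep_result}.
#' @export
velocity_sweep <- function(params = model_parameters(g = 0.2, A = 100),
                           velocity_grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4),
                           seeds = 1:20, saccade_duration = 15,
                           warmup = 2000, window = 200, network = NULL) {
  if (is.null(network)) network <- build_network(params)
  duration <- warmup + window + 300
  rows <- list()
  for (v in velocity_grid) {
    for (s in seeds) {
      set.seed(derive_seed(s, 1))
      ev <- single_saccade(warmup, v * saccade_duration,
                           duration = saccade_duration)
      sim <- run_with_events(params, stationary_protocol(duration, params$A),
                             ev, s, network)
      tr <- moving_bin_counts(sim, T_bin = params$T_bin)
      rows[[length(rows) + 1]] <-
        data.frame(param = v, seed = s,
                   value = response_peak(tr, warmup, window))
    }
  }
  new_sweep_result(do.call(rbind, rows), "velocity (units/ms)", "peak N_sp")
}

#' Microsaccade response versus time since flash onset
#'
#' Runs the flashing stimulus to its cyclic steady state, then places one
#' microsaccade at each interval t_m - t_on after an on-phase onset and
#' measures the response peak and the network-averaged synaptic strength at
#' the saccade time. Also reports the grid mean of the peaks (the expected
#' response to randomly timed saccades during the on-phase) and the
#' stationary-stimulus baseline that the peak approaches at large intervals.
#'
#' @param params a \code{std_params} object.
#' @param t_grid intervals t_m - t_on (ms), within \[0, T_on\].
#' @param T_on,T_off flash cycle durations (ms).
#' @param delta_M saccade magnitude.
#' @param seeds replicate seeds.
#' @param warm_cycles full flash cycles run before the probed onset.
#' @param window peak search window (ms).
#' @param network optional prebuilt network.
#' @return \code{sweep_result} with columns S_at_tm in \code{data}, and
#'   elements \code{grid_mean} and \code{baseline}.
#' @export
flash_interval_analysis <- function(params, t_grid, T_on = 1000, T_off = 1000,
                                    delta_M = 1.0, seeds = 1:20,
                                    warm_cycles = 2, window = 200,
                                    network = NULL) {
  if (any(t_grid < 0) || any(t_grid > T_on))
    stop("intervals must lie within [0, T_on]", call. = FALSE)
  if (is.null(network)) network <- build_network(params)
  cycle <- T_on + T_off
  t_on <- warm_cycles * cycle
  duration <- t_on + cycle
  rows <- list()
  for (itv in t_grid) {
    t_m <- t_on + itv
    for (s in seeds) {
      set.seed(derive_seed(s, 1))
      sim <- run_with_events(params,
                             flashing_protocol(T_on, T_off, duration, params$A),
                             single_saccade(t_m, delta_M), s, network,
                             sample_every = 1)
      tr <- moving_bin_counts(sim, T_bin = params$T_bin)
      S_at <- sim$trace$S_mean[which.min(abs(sim$trace$time_ms - t_m))]
      rows[[length(rows) + 1]] <-
        data.frame(param = itv, seed = s,
                   value = response_peak(tr, t_m, window), S_at_tm = S_at)
    }
  }
  data <- do.call(rbind, rows)
  # stationary-stimulus reference: same adaptation time, one saccade
  base <- vapply(seeds, function(s) {
    set.seed(derive_seed(s, 1))
    sim <- run_with_events(params, stationary_protocol(duration, params$A),
                           single_saccade(t_on + T_on / 2, delta_M), s, network)
    response_peak(moving_bin_counts(sim, T_bin = params$T_bin),
                  t_on + T_on / 2, window)
  }, numeric(1))
  res <- new_sweep_result(data, "t_m - t_on (ms)", "peak N_sp",
                          extra = list(grid_mean = NA, baseline = mean(base)))
  res$grid_mean <- mean(res$summary$mean)
  res$S_summary <- stats::aggregate(S_at_tm ~ param, data, mean)
  res
}

#' Response peak after a flash onset
#'
#' Measures the population response peak following an on-phase onset of the
#' flashing stimulus (no microsaccade), after at least one full off-phase of
#' synaptic recovery, averaged over seeds.
#'
#' @param params a \code{std_params} object.
#' @param T_off off-phase duration (ms).
#' @param seeds replicate seeds.
#' @param T_on on-phase duration (ms).
#' @param warm_cycles flash cycles before the probed onset.
#' @param window peak search window (ms).
#' @param network optional prebuilt network.
#' @return numeric vector of per-seed onset peaks.
#' @export
flash_onset_peak <- function(params, T_off = 1000, seeds = 1:20, T_on = 1000,
                             warm_cycles = 2, window = 200, network = NULL) {
  stopifnot(T_off > 0)
  if (is.null(network)) network <- build_network(params)
  cycle <- T_on + T_off
  t_on <- warm_cycles * cycle
  duration <- t_on + T_on
  vapply(seeds, function(s) {
    sim <- run_simulation(params,
                          flashing_protocol(T_on, T_off, duration, params$A),
                          seed = derive_seed(s, 2), network = network)
    response_peak(moving_bin_counts(sim, T_bin = params$T_bin), t_on, window)
  }, numeric(1))
}

#' Flashing versus stationary microsaccade responses
#'
#' Paired comparison of microsaccade-evoked response peaks under a flashing
#' and a stationary stimulus, using the same Poisson saccade train for both
#' conditions of each seed. Returns, per seed, the mean peak over saccades
#' that fall in on-phases of the flashing stimulus, the mean peak over the
#' same-rate saccades under the stationary stimulus, and the mean flash-onset
#' peak.
#'
#' @param params a \code{std_params} object.
#' @param T_on,T_off flash cycle durations (ms).
#' @param delta_M saccade magnitude.
#' @param rate_hz Poisson saccade rate (Hz); the canonical 1.5 Hz keeps
#'   consecutive responses largely non-overlapping.
#' @param duration run length per condition (ms).
#' @param seeds replicate seeds.
#' @param window peak search window (ms).
#' @param discard onset transient excluded (ms).
#' @param network optional prebuilt network.
#' @return data.frame(seed, flash_peak, stationary_peak, onset_peak,
#'   n_saccades_on).
#' @export
flashing_vs_stationary <- function(params, T_on = 1000, T_off = 1000,
                                   delta_M = 1.0, rate_hz = 1.5,
                                   duration = 100000, seeds = 1:20,
                                   window = 200, discard = 500,
                                   network = NULL) {
  if (is.null(network)) network <- build_network(params)
  cycle <- T_on + T_off
  out <- lapply(seeds, function(s) {
    set.seed(derive_seed(s, 1))
    ev <- poisson_saccades(rate_hz, delta_M, duration)
    ok <- ev$onset >= discard & ev$onset + window + params$T_bin <= duration
    in_on <- (ev$onset %% cycle) < T_on

    sim_f <- run_with_events(params,
                             flashing_protocol(T_on, T_off, duration, params$A),
                             ev, s, network)
    tr_f <- moving_bin_counts(sim_f, T_bin = params$T_bin)
    sim_s <- run_with_events(params, stationary_protocol(duration, params$A),
                             ev, s, network)
    tr_s <- moving_bin_counts(sim_s, T_bin = params$T_bin)

    peaks_f <- vapply(ev$onset[ok & in_on],
                      function(t) response_peak(tr_f, t, window), numeric(1))
    peaks_s <- vapply(ev$onset[ok],
                      function(t) response_peak(tr_s, t, window), numeric(1))
    onsets <- seq(0, duration - T_on, by = cycle)
    onsets <- onsets[onsets >= discard]
    peaks_on <- vapply(onsets,
                       function(t) response_peak(tr_f, t, window), numeric(1))
    data.frame(seed = s, flash_peak = mean(peaks_f),
               stationary_peak = mean(peaks_s),
               onset_peak = mean(peaks_on),
               n_saccades_on = sum(ok & in_on))
  })
  do.call(rbind, out)
}

#' Response-peak phase diagram over the flash cycle
#'
#' Microsaccade-evoked response peak under the flashing stimulus for every
#' combination of T_on and T_off, with Poisson-placed saccades evaluated in
#' on-phases, plus the ratio of each cell to the stationary-stimulus peak
#' (computed once per seed).
#'
#' @param params a \code{std_params} object.
#' @param T_on_grid,T_off_grid cycle durations to cross (ms).
#' @param delta_M saccade magnitude.
#' @param rate_hz Poisson saccade rate (Hz).
#' @param duration run length per cell (ms).
#' @param seeds replicate seeds.
#' @param window peak search window (ms).
#' @param discard onset transient excluded (ms).
#' @param network optional prebuilt network.
#' @return list with matrices \code{peak} and \code{ratio}
#'   (rows = T_off_grid, cols = T_on_grid) and the scalar
#'   \code{stationary_peak}.
#' @export
phase_diagram <- function(params, T_on_grid = c(500, 1000, 2000),
                          T_off_grid = c(250, 500, 1000, 2000),
                          delta_M = 1.0, rate_hz = 1.5, duration = 20000,
                          seeds = 1:5, window = 200, discard = 500,
                          network = NULL) {
  if (is.null(network)) network <- build_network(params)
  mean_peaks <- function(tr, onsets) {
    if (length(onsets) == 0) return(NA_real_)
    mean(vapply(onsets, function(t) response_peak(tr, t, window), numeric(1)))
  }
  stat <- vapply(seeds, function(s) {
    set.seed(derive_seed(s, 1))
    ev <- poisson_saccades(rate_hz, delta_M, duration)
    ok <- ev$onset >= discard & ev$onset + window + params$T_bin <= duration
    sim <- run_with_events(params, stationary_protocol(duration, params$A),
                           ev, s, network)
    mean_peaks(moving_bin_counts(sim, T_bin = params$T_bin), ev$onset[ok])
  }, numeric(1))
  peak <- matrix(NA_real_, length(T_off_grid), length(T_on_grid),
                 dimnames = list(T_off = T_off_grid, T_on = T_on_grid))
  for (i in seq_along(T_off_grid)) for (j in seq_along(T_on_grid)) {
    T_off <- T_off_grid[i]; T_on <- T_on_grid[j]
    cycle <- T_on + T_off
    vals <- vapply(seeds, function(s) {
      set.seed(derive_seed(s, 1))
      ev <- poisson_saccades(rate_hz, delta_M, duration)
      ok <- ev$onset >= discard & ev$onset + window + params$T_bin <= duration &
        (ev$onset %% cycle) < T_on
      sim <- run_with_events(params,
                             flashing_protocol(T_on, T_off, duration, params$A),
                             ev, s, network)
      mean_peaks(moving_bin_counts(sim, T_bin = params$T_bin), ev$onset[ok])
    }, numeric(1))
    peak[i, j] <- mean(vals, na.rm = TRUE)
  }
  list(peak = peak, ratio = peak / mean(stat), stationary_peak = mean(stat))
}
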