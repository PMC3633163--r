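#' Exact leak decay of the membrane potential
#'
#' Closed-form solution of the leak-only membrane equation over a step:
#' \code{V0 + (V - V0) * exp(-dt / tau_m)}. The reference implementation
#' used by the documentation and tests; the simulation core applies the same
#' expression.
#'
#' @param V membrane potential (mV).
#' @param dt elapsed time (ms).
#' @param tau_m membrane time constant (ms).
#' @param V0 resting potential (mV).
#' @return decayed potential (mV).
#' @examples
#' leak_decay(-58, 30, 30, -70)  # -70 + 12/e
#' @export
leak_decay <- function(V, dt, tau_m, V0) {
  V0 + (V - V0) * exp(-dt / tau_m)
}

#' Conductance jump from one presynaptic spike
#'
#' The delta-pulse synapse drives the membrane toward the excitatory
#' reversal potential: \code{V + (g * W * S / tau_m) * (VE - V)}, evaluated
#' at the pre-jump V and with the pre-depletion synaptic strength S. Because
#' the jump is proportional to (VE - V) it can approach but never cross VE.
#'
#' @param V pre-jump membrane potential (mV).
#' @param g maximal synaptic conductance.
#' @param W connection weight.
#' @param S synaptic strength.
#' @param VE excitatory reversal potential (mV).
#' @param tau_m membrane time constant (ms).
#' @return post-jump potential (mV).
#' @examples
#' spike_jump(-70, g = 0.15, W = 1, S = 1, VE = 0, tau_m = 30)  # -69.65
#' @export
spike_jump <- function(V, g, W, S, VE, tau_m) {
  V + (g * W * S / tau_m) * (VE - V)
}

#' One step of Bernoulli-thinned Poisson spiking
#'
#' Each LGN neuron fires independently with probability R_j * dt (at most
#' one spike per step). Requires max(R) * dt < 0.1 so the per-step Bernoulli
#' draw is a valid thinning of the Poisson process.
#'
#' @param rates per-neuron rates (spikes/s).
#' @param dt step size (ms).
#' @return logical vector, TRUE where the neuron fires in this step.
#' @export
poisson_spikes <- function(rates, dt) {
  p <- rates * dt / 1000
  if (max(p) >= 0.1)
    stop("dt too large for peak rate: R*dt must stay below 0.1", call. = FALSE)
  stats::runif(length(p)) < p
}

# Deterministic sub-seed derivation so independent components (saccade-train
# generation, LGN spiking) can draw from separate streams of one global seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 2654435) %% 2147483647)
}

#' Run the feedforward LGN-V1 simulation
#'
#' Time-stepped integration of the conductance-pulse integrate-and-fire
#' dynamics with short-term depression in the thalamocortical synapses. Per
#' step: the protocol fixes the fixated-dot position and brightness; LGN
#' neurons fire Bernoulli-thinned Poisson spikes; each spike drives all V1
#' membranes toward the excitatory reversal with its pre-depletion synaptic
#' strength; fired synapses deplete by the factor f; all synapses recover
#' exponentially over dt; V1 neurons at or above threshold emit a spike and
#' reset. Runs are deterministic for a fixed seed.
#'
#' @param params a \code{std_params} object.
#' @param protocol a \code{protocol} object.
#' @param seed integer seed, or NULL to continue the current RNG stream.
#' @param record_lgn record LGN spike events (off by default; they are
#'   voluminous).
#' @param sample_every sampling interval for state traces (ms); 0 disables
#'   tracing. The network-averaged synaptic strength is always traced when
#'   sampling is on.
#' @param record_S also record the full per-synapse strength matrix at each
#'   sample (memory heavy; intended for small N).
#' @param record_V integer indices of V1 neurons whose membrane potential is
#'   traced.
#' @param network optional prebuilt \code{\link{build_network}} result,
#'   reused across runs in sweeps.
#' @param init optional list(V, S) of initial membrane potentials and
#'   synaptic strengths (defaults: V = V0, S = 1, the fully recovered state
#'   at the start of fixation).
#' @return object of class \code{sim_result} with elements \code{spikes}
#'   (data.frame layer/neuron/time_ms), \code{trace} (data.frame time_ms,
#'   S_mean, and optional V columns), \code{S_full}, \code{final} (list V,
#'   S), \code{params}, \code{protocol}, \code{seed}.
#' @examples
#' p <- model_parameters(N = 50, L = 10)
#' pr <- add_saccades(stationary_protocol(500, A = 50), single_saccade(250, 2))
#' r <- run_simulation(p, pr, seed = 1)
#' summary(r)
#' @export
run_simulation <- function(params, protocol, seed = NULL,
                           record_lgn = FALSE, sample_every = 0,
                           record_S = FALSE, record_V = integer(0),
                           network = NULL, init = NULL) {
  stopifnot(inherits(params, "std_params"), inherits(protocol, "protocol"))
  validate_params(params)
  n_steps <- protocol$duration / params$dt
  if (abs(n_steps - round(n_steps)) > 1e-6)
    stop("protocol duration must be a multiple of dt", call. = FALSE)
  if (is.null(network)) network <- build_network(params)
  if (!identical(length(network$positions), length(params$N)) &&
      length(network$positions) != params$N)
    stop("network size does not match params$N", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  init_V <- if (!is.null(init$V)) init$V else rep(params$V0, params$N)
  init_S <- if (!is.null(init$S)) init$S else rep(1.0, params$N)
  stopifnot(length(init_V) == params$N, length(init_S) == params$N)
  if (any(init_S <= 0) || any(init_S > 1))
    stop("initial synaptic strengths must lie in (0, 1]", call. = FALSE)

  seg <- compile_protocol(protocol)
  raw <- sim_core(network$positions, network$W, unclass(params), seg,
                  protocol$duration, record_lgn, sample_every, record_S,
                  as.integer(record_V), init_V, init_S)

  spikes <- data.frame(
    layer = rep(c("LGN", "V1"), c(length(raw$lgn_time), length(raw$v1_time))),
    neuron = c(raw$lgn_neuron, raw$v1_neuron),
    time_ms = c(raw$lgn_time, raw$v1_time))
  spikes <- spikes[order(spikes$time_ms, spikes$layer, spikes$neuron), ]
  rownames(spikes) <- NULL

  trace <- NULL
  if (sample_every > 0) {
    trace <- data.frame(time_ms = raw$trace_time, S_mean = raw$S_mean)
    if (length(record_V) > 0) {
      Vt <- raw$V_trace
      colnames(Vt) <- paste0("V", record_V)
      trace <- cbind(trace, Vt)
    }
  }

  structure(list(spikes = spikes, trace = trace,
                 S_full = raw$S_full,
                 final = list(V = raw$final_V, S = raw$final_S),
                 params = params, protocol = protocol, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  n_v1 <- sum(x$spikes$layer == "V1")
  n_lgn <- sum(x$spikes$layer == "LGN")
  cat(sprintf("LGN-V1 simulation: %g ms ('%s' protocol), seed %s\n",
              x$protocol$duration, x$protocol$label,
              if (is.null(x$seed)) "<none>" else x$seed))
  cat(sprintf("  V1 spikes: %d%s\n", n_v1,
              if (n_lgn > 0) sprintf("; LGN spikes: %d", n_lgn) else ""))
  invisible(x)
}

#' @export
summary.sim_result <- function(object, ...) {
  v1 <- object$spikes[object$spikes$layer == "V1", ]
  out <- list(
    duration_ms = object$protocol$duration,
    n_events = nrow(object$protocol$events),
    v1_spikes = nrow(v1),
    v1_active_neurons = length(unique(v1$neuron)),
    mean_S_final = mean(object$final$S),
    seed = object$seed)
  class(out) <- "summary.sim_result"
  out
}

#' @export
print.summary.sim_result <- function(x, ...) {
  cat(sprintf(paste0("Simulation of %g ms with %d microsaccade event(s)\n",
                     "  V1 spikes: %d from %d neurons\n",
                     "  final network-averaged synaptic strength: %.4f\n"),
              x$duration_ms, x$n_events, x$v1_spikes,
              x$v1_active_neurons, x$mean_S_final))
  invisible(x)
}

#' Raster and population-response plot of a simulation
#'
#' Top panel: V1 spike raster with microsaccade onsets marked; bottom panel:
#' moving-bin population spike count.
#'
#' @param x a \code{sim_result}.
#' @param ... ignored.
#' @export
plot.sim_result <- function(x, ...) {
  v1 <- x$spikes[x$spikes$layer == "V1", ]
  tr <- moving_bin_counts(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(v1$time_ms, v1$neuron, pch = ".", cex = 2,
                 xlim = c(0, x$protocol$duration),
                 xlab = "time (ms)", ylab = "V1 neuron", main = "spike raster")
  graphics::abline(v = x$protocol$events$onset, col = "red", lty = 3)
  graphics::plot(tr$time_ms, tr$count, type = "l",
                 xlab = "time (ms)", ylab = "N_sp per 50 ms bin",
                 main = "population response")
  graphics::abline(v = x$protocol$events$onset, col = "red", lty = 3)
  invisible(x)
}
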