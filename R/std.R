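#' Per-spike synaptic depletion
#'
#' Multiplicative depletion of the synaptic resource at a presynaptic spike:
#' S is reduced to f*S immediately after the spike. The conductance delivered
#' by the spike itself uses the pre-depletion strength.
#'
#' @param S synaptic strength(s) in (0, 1\].
#' @param f depletion ratio, 0 < f < 1.
#' @return depleted strength f*S.
#' @examples
#' std_deplete(1, 0.75)
#' @export
std_deplete <- function(S, f) {
  if (any(f <= 0) || any(f >= 1)) stop("f must satisfy 0 < f < 1", call. = FALSE)
  f * S
}

#' Exponential recovery from depression
#'
#' Closed-form solution of dS/dt = (1 - S)/tau_S over an interval dt:
#' \code{1 - (1 - S0) * exp(-dt / tau_S)}. Monotone nondecreasing in dt,
#' approaching full strength 1 as dt grows.
#'
#' @param S0 strength at the start of the interval.
#' @param dt elapsed time (ms), >= 0.
#' @param tau_S recovery time constant (ms).
#' @return recovered strength.
#' @examples
#' std_recover(0.75, dt = 200, tau_S = 200)  # 1 - 0.25/e
#' @export
std_recover <- function(S0, dt, tau_S) {
  if (any(dt < 0)) stop("dt must be >= 0", call. = FALSE)
  1 - (1 - S0) * exp(-dt / tau_S)
}

#' High-rate steady-state synaptic strength
#'
#' The approximate steady state reached under sustained presynaptic drive at
#' rate R: \code{1 / (f + (1 - f) * R * tau_S)} with tau_S converted to
#' seconds. This is the high-rate limit of the periodic-drive fixed point
#' (\code{\link{std_steady_state_periodic}}) and is only valid for high
#' rates; at R = 0 it returns 1/f > 1, outside the admissible range, and a
#' warning is issued whenever the result exceeds 1.
#'
#' @param R presynaptic rate (spikes/s).
#' @param f depletion ratio.
#' @param tau_S recovery time constant (ms).
#' @return approximate steady-state strength.
#' @examples
#' std_steady_state_highrate(50, 0.75, 200)  # 1/3.25
#' @export
std_steady_state_highrate <- function(R, f, tau_S) {
  if (any(R < 0)) stop("R must be >= 0", call. = FALSE)
  s <- 1 / (f + (1 - f) * R * tau_S / 1000)
  if (any(s > 1))
    warning("high-rate steady state exceeds 1: formula is out of its domain at low rates")
  s
}

#' Exact fixed point of STD under deterministic periodic drive
#'
#' For spikes arriving at exact intervals Delta = 1/R, the pre-spike strength
#' converges to \code{S* = (1 - e) / (1 - f * e)} with
#' \code{e = exp(-Delta / tau_S)}. This is the exact reference against which
#' the high-rate approximation \code{\link{std_steady_state_highrate}} is
#' judged.
#'
#' @param R presynaptic rate (spikes/s), > 0.
#' @param f depletion ratio.
#' @param tau_S recovery time constant (ms).
#' @return exact pre-spike fixed-point strength in (0, 1).
#' @examples
#' std_steady_state_periodic(50, 0.75, 200)  # ~0.2961
#' @export
std_steady_state_periodic <- function(R, f, tau_S) {
  if (any(R <= 0)) stop("R must be > 0", call. = FALSE)
  e <- exp(-(1000 / R) / tau_S)
  (1 - e) / (1 - f * e)
}

#' Event-driven evolution of a synapse over a spike train
#'
#' Exact closed-form evolution: exponential recovery between events and
#' multiplicative depletion at each event. The pre-depletion strength is the
#' one reported at (and delivered by) the spike; depletion applies
#' immediately after.
#'
#' @param S0 initial strength at t = 0.
#' @param spike_times sorted presynaptic spike times (ms) within \[0, t_end\].
#' @param f depletion ratio.
#' @param tau_S recovery time constant (ms).
#' @param t_end end of the evolution (ms).
#' @return list with \code{events}: data.frame(time, S_pre, S_post), and
#'   \code{S_end}: strength at t_end after the final recovery interval.
#' @examples
#' tr <- std_evolve_train(1, spike_times = 0, f = 0.75, tau_S = 200, t_end = 200)
#' tr$events$S_post  # 0.75
#' tr$S_end          # ~0.908
#' @export
std_evolve_train <- function(S0, spike_times, f, tau_S, t_end) {
  if (is.unsorted(spike_times)) stop("spike times must be sorted", call. = FALSE)
  if (length(spike_times) > 0 &&
      (spike_times[1] < 0 || spike_times[length(spike_times)] > t_end))
    stop("spike times must lie within [0, t_end]", call. = FALSE)
  n <- length(spike_times)
  S_pre <- S_post <- numeric(n)
  S <- S0; t_prev <- 0
  for (k in seq_len(n)) {
    S <- std_recover(S, spike_times[k] - t_prev, tau_S)
    S_pre[k] <- S
    S <- std_deplete(S, f)
    S_post[k] <- S
    t_prev <- spike_times[k]
  }
  S_end <- std_recover(S, t_end - t_prev, tau_S)
  list(events = data.frame(time = spike_times, S_pre = S_pre, S_post = S_post),
       S_end = S_end)
}

#' Time-averaged synaptic strength over a spike train
#'
#' Exact time integral of S(t) under event-driven evolution, divided by
#' t_end. Between events S recovers exponentially, so each segment's
#' integral has the closed form
#' \code{d - (1 - S) * tau_S * (1 - exp(-d / tau_S))}.
#'
#' @inheritParams std_evolve_train
#' @return mean of S(t) over \[0, t_end\].
#' @export
std_train_time_average <- function(S0, spike_times, f, tau_S, t_end) {
  if (is.unsorted(spike_times)) stop("spike times must be sorted", call. = FALSE)
  seg_int <- function(S, d) d - (1 - S) * tau_S * (1 - exp(-d / tau_S))
  S <- S0; t_prev <- 0; acc <- 0
  for (t in spike_times) {
    d <- t - t_prev
    acc <- acc + seg_int(S, d)
    S <- std_deplete(std_recover(S, d, tau_S), f)
    t_prev <- t
  }
  acc <- acc + seg_int(S, t_end - t_prev)
  acc / t_end
}

#' Analytic recovery time from a depressed state
#'
#' Time for a synapse starting at strength S0 to recover to within
#' \code{epsilon} of full strength: \code{tau_S * log((1 - S0) / epsilon)}.
#' Used to check that recovery from the adapted steady state is essentially
#' complete within a typical flash-off period.
#'
#' @param S0 starting strength (< 1).
#' @param tau_S recovery time constant (ms).
#' @param epsilon remaining deficit 1 - S at the target (default 0.01).
#' @return recovery time (ms); 0 when S0 is already within epsilon of 1.
#' @examples
#' s_ad <- std_steady_state_highrate(50, 0.75, 200)
#' std_recovery_time(s_ad, 200)  # well under 1000 ms
#' @export
std_recovery_time <- function(S0, tau_S, epsilon = 0.01) {
  pmax(0, tau_S * log((1 - S0) / epsilon))
}

#' Recover STD parameters from an observed strength trajectory
#'
#' Least-squares fit of the depletion ratio f and recovery time constant
#' tau_S to observed pre-spike strengths, using one-step-ahead predictions
#' from the closed-form depletion/recovery map
#' \code{S_pre[k+1] = 1 - (1 - f * S_pre[k]) * exp(-dt_k / tau_S)}.
#'
#' @param spike_times sorted spike times (ms).
#' @param S_pre observed pre-spike strengths (same length).
#' @param init named start values c(f = , tau_S = ).
#' @return list with \code{f}, \code{tau_S}, \code{sse}, and the
#'   \code{\link[stats]{optim}} convergence code.
#' @export
fit_std <- function(spike_times, S_pre, init = c(f = 0.5, tau_S = 100)) {
  stopifnot(length(spike_times) == length(S_pre), length(S_pre) >= 3)
  dt <- diff(spike_times)
  s_from <- S_pre[-length(S_pre)]
  s_to <- S_pre[-1]
  sse <- function(par) {
    pred <- 1 - (1 - par[1] * s_from) * exp(-dt / par[2])
    sum((pred - s_to)^2)
  }
  fit <- stats::optim(init, sse, method = "L-BFGS-B",
                      lower = c(1e-3, 1), upper = c(0.999, 1e4))
  list(f = unname(fit$par[1]), tau_S = unname(fit$par[2]),
       sse = fit$value, convergence = fit$convergence)
}
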