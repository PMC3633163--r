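#' Model parameters for the feedforward LGN-V1 network
#'
#' Collects every scalar constant of the model: network geometry, Gaussian
#' tuning widths, synaptic conductance, short-term depression (STD) kinetics,
#' leaky integrate-and-fire membrane constants, and the numerical step sizes.
#' Defaults are the reference values used throughout: a ring of N = 1000
#' neurons per layer spanning \[-L, L\] with L = 10, membrane time constant
#' 30 ms, resting potential -70 mV, excitatory reversal 0 mV, threshold
#' -55 mV, reset -58 mV, depletion ratio f = 0.75 and recovery time constant
#' tau_S = 200 ms.
#'
#' @param N neuron count per layer (>= 2).
#' @param L half-width of the position range; receptive-field centres live on
#'   the ring \[-L, L\] with circumference 2L (position units).
#' @param g maximal synaptic conductance (dimensionless).
#' @param A stimulus amplitude: peak LGN Poisson rate at the fixated position
#'   (spikes/s).
#' @param sigma1 width of the LGN input tuning curve (position units).
#' @param sigma2 width of the LGN-to-V1 weight tuning curve (position units).
#' @param f STD depletion ratio, the fraction of synaptic resources remaining
#'   immediately after a presynaptic spike (0 < f < 1).
#' @param tau_S STD recovery time constant (ms).
#' @param tau_m membrane time constant (ms).
#' @param V0 resting potential (mV).
#' @param VE excitatory reversal potential (mV).
#' @param V_th spike threshold (mV).
#' @param V_reset post-spike reset potential (mV).
#' @param dt integration time step (ms). Must keep max(R)*dt < 0.1 for the
#'   per-step Bernoulli approximation of the Poisson input to be valid.
#' @param T_bin response bin width for spike-count analysis (ms).
#' @return An object of class \code{std_params}: a validated named list.
#' @examples
#' p <- model_parameters()
#' p$tau_m
#' model_parameters(N = 100, g = 0.2, A = 100)
#' @export
model_parameters <- function(N = 1000, L = 10, g = 0.15, A = 50,
                             sigma1 = 1.5, sigma2 = 1.5,
                             f = 0.75, tau_S = 200, tau_m = 30,
                             V0 = -70, VE = 0, V_th = -55, V_reset = -58,
                             dt = 0.1, T_bin = 50) {
  p <- list(N = as.integer(N), L = L, g = g, A = A, sigma1 = sigma1,
            sigma2 = sigma2, f = f, tau_S = tau_S, tau_m = tau_m,
            V0 = V0, VE = VE, V_th = V_th, V_reset = V_reset,
            dt = dt, T_bin = T_bin)
  validate_params(p)
  class(p) <- "std_params"
  p
}

validate_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameter: ", msg, call. = FALSE)
  chk(is.numeric(p$N) && p$N >= 2 && p$N == round(p$N), "N must be an integer >= 2")
  chk(p$L > 0, "L must be > 0")
  chk(p$sigma1 > 0 && p$sigma2 > 0, "sigma1 and sigma2 must be > 0")
  chk(p$A >= 0, "A must be >= 0")
  chk(p$g >= 0, "g must be >= 0")
  chk(p$f > 0 && p$f < 1, "f must satisfy 0 < f < 1")
  chk(p$tau_S > 0, "tau_S must be > 0")
  chk(p$tau_m > 0, "tau_m must be > 0")
  chk(p$dt > 0, "dt must be > 0")
  chk(p$T_bin > 0, "T_bin must be > 0")
  chk(p$V0 < p$V_reset, "potential ordering requires V0 < V_reset")
  chk(p$V_reset < p$V_th, "potential ordering requires V_reset < V_th")
  chk(p$V_th < p$VE, "potential ordering requires V_th < VE")
  chk(p$A * p$dt / 1000 < 0.1, "dt too large for peak rate A: A*dt/1000 must be < 0.1")
  invisible(p)
}

#' @export
print.std_params <- function(x, ...) {
  cat("Feedforward LGN-V1 model parameters\n")
  cat(sprintf("  geometry : N = %d per layer on [-L, L], L = %g\n", x$N, x$L))
  cat(sprintf("  tuning   : sigma1 = %g (input), sigma2 = %g (weights)\n",
              x$sigma1, x$sigma2))
  cat(sprintf("  input    : A = %g spikes/s peak, g = %g\n", x$A, x$g))
  cat(sprintf("  STD      : f = %g, tau_S = %g ms\n", x$f, x$tau_S))
  cat(sprintf("  membrane : tau_m = %g ms, V0 = %g, VE = %g, V_th = %g, V_reset = %g mV\n",
              x$tau_m, x$V0, x$VE, x$V_th, x$V_reset))
  cat(sprintf("  numerics : dt = %g ms, T_bin = %g ms\n", x$dt, x$T_bin))
  invisible(x)
}

#' Load model parameters from a YAML or JSON config file
#'
#' Keys must match the argument names of \code{\link{model_parameters}}
#' exactly; unknown keys are rejected with an error naming the key, and
#' missing keys fall back to the defaults. An empty file yields the full
#' default parameter set.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated \code{std_params} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (expected YAML or JSON)", call. = FALSE)
  }
  if (is.null(raw)) raw <- list()
  known <- names(formals(model_parameters))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(model_parameters, raw)
}
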