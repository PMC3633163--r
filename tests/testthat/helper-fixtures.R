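# Shared fixtures: the reference parameter set and a prebuilt full-size
# network (built once per test run; construction is the expensive part).

ref_params <- model_parameters()                      # g = 0.15, A = 50
big_params <- model_parameters(g = 0.2, A = 100)      # strong-response set

.net_cache <- new.env()
get_network <- function(params = ref_params) {
  key <- sprintf("N%d_s%g_L%g", params$N, params$sigma2, params$L)
  if (is.null(.net_cache[[key]])) .net_cache[[key]] <- build_network(params)
  .net_cache[[key]]
}

# Small network for state-trace oracle tests (weak drive, no V1 firing).
small_params <- model_parameters(N = 60, L = 10)

# One saccade from the adapted state; returns the sim and its response trace.
run_single_saccade <- function(seed, params = ref_params, delta_M = 2.0,
                               warmup = 2000, post = 1500,
                               network = get_network(params), ...) {
  pr <- add_saccades(stationary_protocol(warmup + post, params$A),
                     single_saccade(warmup, delta_M))
  sim <- run_simulation(params, pr, seed = seed, network = network, ...)
  list(sim = sim,
       trace = moving_bin_counts(sim, T_bin = params$T_bin,
                                 t_start = warmup - 250))
}
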