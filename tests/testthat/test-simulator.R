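test_that("leak decay and conductance jumps follow the closed forms", {
  expect_equal(leak_decay(-58, 30, 30, -70), -70 + 12 * exp(-1))
  expect_equal(leak_decay(-70, 17, 30, -70), -70)
  expect_equal(leak_decay(-60, 0, 30, -70), -60)

  expect_equal(spike_jump(-70, 0.15, 1, 1, 0, 30), -69.65)
  expect_equal(spike_jump(-63, 0.15, 0.5, 0, 0, 30), -63)    # S = 0: no effect
  # repeated jumps approach VE monotonically, never crossing it
  V <- -70
  for (k in 1:5000) {
    V_new <- spike_jump(V, 0.2, 1, 1, 0, 30)
    expect_gt(V_new, V)
    V <- V_new
  }
  expect_lt(V, 0)
})

test_that("per-step Bernoulli spiking reproduces the Poisson rate", {
  expect_false(any(poisson_spikes(rep(0, 100), 0.1)))
  expect_error(poisson_spikes(2000, 0.1), "dt too large")
  # single neuron at 50 spikes/s over 10^6 steps of 0.1 ms (100 s)
  set.seed(101)
  hits <- sum(replicate(100, sum(poisson_spikes(rep(50, 1e4), 0.1))))
  rate <- hits / 100
  expect_lt(abs(rate - 50), 3 * sqrt(50 / 100))
})

test_that("simulation is deterministic per seed and null without stimulus", {
  pr <- add_saccades(stationary_protocol(600, ref_params$A),
                     single_saccade(300, 2))
  net <- get_network()
  a <- run_simulation(ref_params, pr, seed = 42, network = net)
  b <- run_simulation(ref_params, pr, seed = 42, network = net)
  expect_identical(a$spikes, b$spikes)
  c <- run_simulation(ref_params, pr, seed = 43, network = net)
  expect_false(identical(a$spikes, c$spikes))

  # A = 0: no spikes anywhere, synapses stay at full strength
  null <- run_simulation(ref_params, stationary_protocol(500, 0), seed = 1,
                         network = net, record_lgn = TRUE)
  expect_equal(nrow(null$spikes), 0)
  expect_equal(null$final$S, rep(1, 1000))
  expect_equal(null$final$V, rep(-70, 1000))
})

test_that("membrane potentials stay within [V0, V_th] at sample times", {
  pr <- add_saccades(stationary_protocol(1200, ref_params$A),
                     single_saccade(800, 2))
  sim <- run_simulation(ref_params, pr, seed = 7, network = get_network(),
                        sample_every = 1, record_V = c(1, 250, 500, 900))
  V <- as.matrix(sim$trace[, c("V1", "V250", "V500", "V900")])
  expect_gte(min(V), ref_params$V0)
  expect_lt(max(V), ref_params$V_th)
})

test_that("synaptic strengths stay in (0, 1] throughout a run", {
  pr <- add_saccades(stationary_protocol(1500, ref_params$A),
                     single_saccade(1000, 2))
  sim <- run_simulation(ref_params, pr, seed = 3, network = get_network(),
                        sample_every = 5, record_S = TRUE)
  expect_true(all(sim$S_full > 0 & sim$S_full <= 1))
  expect_true(all(sim$final$S > 0 & sim$final$S <= 1))
  # strengths start fully recovered
  expect_equal(sim$S_full[1, ], rep(1, 1000))
})

test_that("time-stepped S trajectory equals the event-driven closed form", {
  sim <- run_simulation(small_params, stationary_protocol(2000, 50), seed = 5,
                        record_lgn = TRUE, sample_every = 500, record_S = TRUE)
  lgn <- sim$spikes[sim$spikes$layer == "LGN", ]
  for (j in c(20, 30, 31, 45)) {
    st <- lgn$time_ms[lgn$neuron == j]
    oracle <- std_evolve_train(1, st, small_params$f, small_params$tau_S,
                               2000)$S_end
    expect_equal(sim$final$S[j], oracle, tolerance = 1e-9)
  }
})

test_that("V1 spike counts are conserved across representations", {
  res <- run_single_saccade(17)
  v1 <- sum(res$sim$spikes$layer == "V1")
  tr <- moving_bin_counts(res$sim, T_bin = 50, step = 50, t_start = 0,
                          t_end = 3500)
  expect_equal(sum(tr$count), v1)
})

test_that("the adapted state is marginal: sparse firing that a synapse
           reset turns into an immediate volley", {
  net <- get_network()
  warm <- run_simulation(ref_params, stationary_protocol(2000, 50), seed = 31,
                         network = net)
  v1 <- warm$spikes[warm$spikes$layer == "V1", ]
  adapted_rate <- sum(v1$time_ms >= 1000) / 1           # spikes/s, population
  expect_lt(adapted_rate, 400)                          # orders below a volley

  # same membrane state, synapses reset to full strength -> strong firing
  # within 50 ms
  fresh <- run_simulation(ref_params, stationary_protocol(100, 50), seed = 32,
                          network = net,
                          init = list(V = warm$final$V, S = rep(1, 1000)))
  burst <- sum(fresh$spikes$layer == "V1" & fresh$spikes$time_ms <= 50)
  expect_gt(burst, 100)

  # continuing in the adapted state instead stays sparse
  cont <- run_simulation(ref_params, stationary_protocol(100, 50), seed = 32,
                         network = net,
                         init = list(V = warm$final$V, S = warm$final$S))
  expect_lt(sum(cont$spikes$layer == "V1" & cont$spikes$time_ms <= 50),
            burst / 10)
})

test_that("halving the time step leaves the saccade response peak intact", {
  peaks <- vapply(1:20, function(s) {
    fine <- model_parameters(dt = 0.05)
    p1 <- run_single_saccade(s, warmup = 1500, post = 800)$trace
    p2 <- run_single_saccade(s, params = fine, warmup = 1500, post = 800,
                             network = get_network())$trace
    c(response_peak(p1, 1500), response_peak(p2, 1500))
  }, numeric(2))
  rel <- abs(mean(peaks[2, ]) - mean(peaks[1, ])) / mean(peaks[1, ])
  expect_lt(rel, 0.10)
})

test_that("responses are symmetric under reflection of the saccade", {
  peak_of <- function(s, dir) {
    pr <- add_saccades(stationary_protocol(2300, 50),
                       single_saccade(1800, 2.0, direction = dir))
    sim <- run_simulation(ref_params, pr, seed = s, network = get_network())
    response_peak(moving_bin_counts(sim, t_start = 1500), 1800)
  }
  up <- vapply(1:12, peak_of, numeric(1), dir = 1)
  dn <- vapply(1:12, peak_of, numeric(1), dir = -1)
  expect_lt(abs(mean(up) - mean(dn)) / mean(c(up, dn)), 0.25)
})

test_that("the population response is translation equivariant on the ring", {
  peak_at <- function(s, offset) {
    ev <- single_saccade(1800, 2.0)
    if (offset != 0) ev <- rbind(single_saccade(0, offset), ev)
    pr <- add_saccades(stationary_protocol(2300, 50), ev)
    sim <- run_simulation(ref_params, pr, seed = s, network = get_network())
    response_peak(moving_bin_counts(sim, t_start = 1500), 1800)
  }
  base <- vapply(1:12, peak_at, numeric(1), offset = 0)
  shif <- vapply(1:12, peak_at, numeric(1), offset = 5)
  expect_lt(abs(mean(base) - mean(shif)) / mean(c(base, shif)), 0.25)
})
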