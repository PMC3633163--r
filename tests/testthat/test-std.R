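test_that("depletion is multiplicative and recovery exponential", {
  expect_equal(std_deplete(1, 0.75), 0.75)
  expect_equal(std_deplete(0.75, 0.75), 0.5625)
  expect_equal(std_deplete(0.4, 0.999), 0.4 * 0.999)  # f -> 1: no depression
  expect_error(std_deplete(1, 1.2), "0 < f < 1")

  expect_equal(std_recover(0.75, 200, 200), 1 - 0.25 * exp(-1))
  expect_equal(std_recover(0.3, 0, 200), 0.3)
  expect_equal(std_recover(1, 5000, 200), 1)          # fixed point
  d <- seq(0, 2000, by = 50)
  expect_true(all(diff(std_recover(0.2, d, 200)) > 0))
  expect_equal(std_recover(0.2, 1e6, 200), 1)
  expect_error(std_recover(0.5, -1, 200), "dt must be")
})

test_that("steady states: high-rate formula vs exact periodic fixed point", {
  expect_equal(std_steady_state_highrate(50, 0.75, 200), 1 / 3.25)
  expect_equal(std_steady_state_highrate(1e9, 0.75, 200), 0, tolerance = 1e-6)
  expect_warning(s0 <- std_steady_state_highrate(0, 0.75, 200), "out of its domain")
  expect_equal(s0, 1 / 0.75)

  # exact fixed point at R = 50: Delta = 20 ms
  e <- exp(-0.1)
  expect_equal(std_steady_state_periodic(50, 0.75, 200),
               (1 - e) / (1 - 0.75 * e), tolerance = 1e-12)
  # independent oracle: iterate the depletion+recovery map to convergence
  S <- 0.5
  for (k in 1:500) S <- 1 - (1 - 0.75 * S) * exp(-20 / 200)
  expect_equal(std_steady_state_periodic(50, 0.75, 200), S, tolerance = 1e-10)
  expect_equal(round(std_steady_state_periodic(50, 0.75, 200), 5), 0.29611)

  # limits
  expect_equal(std_steady_state_periodic(50, 0.9999, 200), 1, tolerance = 1e-3)
  expect_equal(std_steady_state_periodic(0.001, 0.75, 200), 1, tolerance = 1e-6)
  expect_error(std_steady_state_periodic(0, 0.75, 200), "R must be")

  # the two closed forms agree within 5% at R*tau_S = 10
  hr <- std_steady_state_highrate(50, 0.75, 200)
  pf <- std_steady_state_periodic(50, 0.75, 200)
  expect_lt(abs(hr - pf) / hr, 0.05)

  # strictly decreasing in R and in (1 - f)
  R <- c(5, 10, 20, 50, 100)
  expect_true(all(diff(std_steady_state_periodic(R, 0.75, 200)) < 0))
  expect_true(all(diff(suppressWarnings(
    std_steady_state_highrate(R, 0.75, 200))) < 0))
  fs <- c(0.9, 0.8, 0.7, 0.5)   # increasing depression 1 - f
  expect_true(all(diff(std_steady_state_periodic(50, fs, 200)) < 0))
})

test_that("event-driven evolution composes the two closed forms exactly", {
  # no spikes: pure recovery to 1
  tr <- std_evolve_train(0.5, numeric(0), 0.75, 200, 1e5)
  expect_equal(tr$S_end, 1)
  expect_equal(nrow(tr$events), 0)

  # single spike at t = 0
  tr <- std_evolve_train(1, 0, 0.75, 200, 200)
  expect_equal(tr$events$S_pre, 1)
  expect_equal(tr$events$S_post, 0.75)
  expect_equal(tr$S_end, 1 - 0.25 * exp(-1), tolerance = 1e-12)

  expect_error(std_evolve_train(1, c(10, 5), 0.75, 200, 100), "sorted")
  expect_error(std_evolve_train(1, c(5, 150), 0.75, 200, 100), "within")

  # strengths stay in (0, 1] along a long random train
  set.seed(11)
  st <- sort(runif(500, 0, 1e4))
  tr <- std_evolve_train(1, st, 0.75, 200, 1e4)
  expect_true(all(tr$events$S_pre > 0 & tr$events$S_pre <= 1))
  expect_true(all(tr$events$S_post > 0 & tr$events$S_post <= 1))
})

test_that("Poisson-drive time average matches the stationary mean", {
  # Exact stationary mean under Poisson drive is 1/(1 + (1-f) R tau_S):
  # the depletion term is linear in S so the mean obeys the deterministic
  # balance, and Poisson arrivals see the time-stationary distribution.
  f <- 0.75; tau <- 200; R <- 50
  analytic <- 1 / (1 + (1 - f) * R * tau / 1000)
  avg <- vapply(1:20, function(s) {
    set.seed(s)
    st <- cumsum(rexp(7000, R / 1000))
    st <- st[st <= 1e5]
    std_train_time_average(1, st, f, tau, 1e5)
  }, numeric(1))
  expect_equal(mean(avg), analytic, tolerance = 0.02)
  # under deterministic periodic drive the pre-spike values converge to the
  # exact fixed point
  st <- seq(20, 1e4, by = 20)
  tr <- std_evolve_train(1, st, f, tau, 1e4)
  expect_equal(tail(tr$events$S_pre, 1),
               std_steady_state_periodic(50, f, tau), tolerance = 1e-8)
})

test_that("analytic recovery time is consistent with the recovery map", {
  s_ad <- std_steady_state_highrate(50, 0.75, 200)
  t99 <- std_recovery_time(s_ad, 200, epsilon = 0.01)
  expect_equal(std_recover(s_ad, t99, 200), 0.99, tolerance = 1e-12)
  expect_equal(std_recovery_time(0.995, 200), 0)
})

test_that("(f, tau_S) are recovered from an observed strength trajectory", {
  set.seed(21)
  st <- cumsum(rexp(6000, 50 / 1000))   # ~100 s at 50 spikes/s
  st <- st[st <= 1e5]
  tr <- std_evolve_train(1, st, 0.75, 200, 1e5)
  fit <- fit_std(st, tr$events$S_pre)
  expect_equal(fit$f, 0.75, tolerance = 0.05 / 0.75)
  expect_equal(fit$tau_S, 200, tolerance = 20 / 200)
  expect_lt(fit$sse, 1e-10)             # noiseless data: near-exact fit
})
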