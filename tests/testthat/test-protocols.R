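test_that("stationary and flashing protocols define the brightness cycle", {
  p <- stationary_protocol(1000, A = 50)
  expect_equal(p$brightness$A, 50)
  expect_equal(nrow(p$events), 0)
  expect_equal(p$flash_onsets, 0)

  fl <- flashing_protocol(1000, 1000, 4000, A = 50)
  expect_equal(fl$flash_onsets, c(0, 2000))
  seg <- saccstd:::compile_protocol(fl)
  on_at <- function(t) seg[findInterval(t, seg[, "t0"]), "A"]
  expect_equal(on_at(c(10, 999, 1000, 1999, 2000, 3500)),
               c(50, 50, 0, 0, 50, 0))
  # brightness integral over one cycle = A * T_on
  expect_equal(sum((seg[, "t1"] - seg[, "t0"]) * seg[, "A"]), 2 * 50 * 1000)

  # T_off = 0 degenerates to the stationary stimulus
  fl0 <- flashing_protocol(1000, 0, 3000, A = 50)
  expect_equal(nrow(fl0$brightness), 1)
  expect_equal(fl0$brightness$A, 50)
})

test_that("saccade events displace the fixation path as specified", {
  pr <- add_saccades(stationary_protocol(4000), single_saccade(2000, 2.0))
  expect_equal(fixation_path(pr, c(0, 1999, 2000, 3999)), c(0, 0, 2, 2))

  pr2 <- add_saccades(stationary_protocol(4000),
                      single_saccade(2000, 2.0, direction = -1))
  expect_equal(fixation_path(pr2, 3000), -2)

  pr3 <- add_saccades(stationary_protocol(4000), single_saccade(2000, 0))
  expect_equal(fixation_path(pr3, c(100, 3900)), c(0, 0))

  # repeated saccades accumulate and wrap onto the ring
  ev <- periodic_saccades(4, 6, 4000, direction = "fixed")
  pr4 <- add_saccades(stationary_protocol(4000), ev)
  xw <- fixation_path(pr4, seq(0, 3999, by = 10), L = 10)
  expect_true(all(xw >= -10 & xw < 10))

  expect_error(add_saccades(stationary_protocol(1000),
                            single_saccade(1500, 1)), "within")
})

test_that("periodic trains have the stated event count and spacing", {
  ev <- periodic_saccades(4, 2.0, 2000)
  expect_equal(nrow(ev), 8)
  expect_equal(ev$onset, seq(0, 1750, by = 250))
  expect_true(all(ev$direction %in% c(-1, 1)))
  # 1/F longer than the schedule: at most one event
  expect_lte(nrow(periodic_saccades(0.2, 2, 2000)), 1)
  ev2 <- periodic_saccades(2, 1, 5000, direction = "alternating")
  expect_equal(ev2$direction, rep(c(1, -1), 5))
})

test_that("Poisson trains are reproducible and exponential", {
  e1 <- poisson_saccades(1.5, 1, 1e5, seed = 5)
  e2 <- poisson_saccades(1.5, 1, 1e5, seed = 5)
  expect_identical(e1, e2)
  e3 <- poisson_saccades(1.5, 1, 1e5, seed = 6)
  expect_false(identical(e1$onset, e3$onset))

  # count statistics at rate F over duration D: mean F*D/1000
  n <- nrow(poisson_saccades(1.5, 1, 1e6, seed = 7))
  expect_lt(abs(n - 1500), 3 * sqrt(1500))

  # inter-onset intervals pass a KS test against the exponential law
  big <- poisson_saccades(10, 1, 1.02e6, seed = 8)
  gaps <- diff(big$onset)
  expect_gte(length(gaps), 1e4)
  expect_gt(stats::ks.test(gaps, "pexp", rate = 10 / 1000)$p.value, 0.01)
})

test_that("finite-velocity events ramp linearly over the movement", {
  ev <- finite_velocity_events(single_saccade(1000, 3.0))
  expect_equal(ev$duration, 15)
  pr <- add_saccades(stationary_protocol(3000), ev)
  expect_equal(fixation_path(pr, 1000 + 7.5), 1.5)  # midpoint
  expect_equal(fixation_path(pr, 1015), 3.0)        # full displacement
  expect_equal(fixation_path(pr, 999), 0)
  # velocity = magnitude / duration
  x <- fixation_path(pr, c(1003, 1004))
  expect_equal(diff(x), 3 / 15, tolerance = 1e-12)

  # zero duration recovers the instantaneous jump
  ev0 <- finite_velocity_events(single_saccade(1000, 3.0), 0)
  pr0 <- add_saccades(stationary_protocol(3000), ev0)
  expect_equal(fixation_path(pr0, c(999, 1000.01)), c(0, 3))

  # overlapping widened events are rejected
  two <- rbind(single_saccade(1000, 1), single_saccade(1010, 1))
  expect_error(finite_velocity_events(two), "overlap")
})

test_that("protocols survive a JSON round trip", {
  pr <- add_saccades(flashing_protocol(500, 250, 3000, A = 40),
                     poisson_saccades(2, 1.5, 3000, seed = 3))
  path <- tempfile(fileext = ".json")
  protocol_to_json(pr, path)
  back <- protocol_from_json(path)
  expect_equal(back$duration, pr$duration)
  expect_equal(back$brightness, pr$brightness)
  expect_equal(back$events, pr$events, tolerance = 1e-12)
  expect_equal(back$flash_onsets, pr$flash_onsets)
  unlink(path)
})
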