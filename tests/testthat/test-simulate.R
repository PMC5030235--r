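quiet_init <- function(n, params, g = 0) {
  list(v = rep(params$v_rest, n), g = rep(g, n), ref = rep(0, n),
       yw = rep(0L, n), t = 0)
}

test_that("resting potential with zero conductance is a fixed point", {
  p <- neuron_params()
  cpl <- coupling_strengths(2, 0.001, 0)
  spk <- simulate_network(cpl, duration = 100, params = p,
                          init = quiet_init(2, p), record_traces = TRUE,
                          trace_stride = 100L)
  expect_equal(nrow(spk), 0)
  expect_equal(attr(spk, "final_state")$v, rep(p$v_rest, 2))
  expect_true(all(attr(spk, "trace_v") == p$v_rest))
})

test_that("conductance decays exactly exponentially between increments", {
  p <- neuron_params()
  cpl <- coupling_strengths(2, 0.001, 0)
  g0 <- 0.1 # below the ignition level: no spikes, hence no increments
  spk <- simulate_network(cpl, duration = 30, params = p,
                          init = quiet_init(2, p, g = g0),
                          record_traces = TRUE, trace_stride = 1L)
  expect_equal(nrow(spk), 0)
  tt <- attr(spk, "trace_time")
  gg <- attr(spk, "trace_g")[, 1]
  expect_equal(gg, g0 * exp(-tt / p$tau_ex), tolerance = 1e-13)
})

test_that("a presynaptic spike increments the target conductance by K_i", {
  # N = 2 and uniform weights: Delta g_2 = K_2 / (N - 1) = K_2
  p <- neuron_params()
  cpl <- tibble::tibble(neuron_id = 1:2, k = c(0.5, 0.7),
                        k_offset = c(-1, 1), k_rank = c(0.5, 1))
  init <- list(v = c(p$v_rest, p$v_rest), g = c(5, 0), ref = c(0, 0),
               yw = c(0L, 0L), t = 0)
  spk <- simulate_network(cpl, duration = 20, params = p, init = init,
                          record_traces = TRUE, trace_stride = 1L)
  expect_gte(nrow(spk), 1)
  first <- spk[1, ]
  expect_equal(first$neuron_id, 1L)
  step <- round(first$time_ms / attr(spk, "dt"))
  g2 <- attr(spk, "trace_g")[, 2]
  expect_equal(g2[step], 0.7)       # increment lands at the spiking step
  expect_equal(g2[step - 1], 0)     # and not before
})

test_that("explicit uniform weights reproduce the mean-field fast path", {
  cpl <- coupling_strengths(20, 3, 1)
  a <- simulate_network(cpl, duration = 1500, seed = 6)
  b <- simulate_network(cpl, duration = 1500, seed = 6,
                        weights = weight_matrix(20))
  expect_identical(a$neuron_id, b$neuron_id)
  expect_identical(a$time_ms, b$time_ms)
})

test_that("refractory neurons stay clamped at rest while the clock runs down", {
  p <- neuron_params()
  cpl <- coupling_strengths(2, 0.001, 0)
  init <- list(v = c(p$v_rest, p$v_rest), g = c(0.5, 0), ref = c(3, 0),
               yw = c(0L, 0L), t = 0)
  spk <- simulate_network(cpl, duration = 2, params = p, init = init,
                          record_traces = TRUE, trace_stride = 1L)
  v1 <- attr(spk, "trace_v")[, 1]
  expect_true(all(v1 == p$v_rest)) # still refractory for the whole 2 ms
  expect_equal(attr(spk, "final_state")$ref[1], 1, tolerance = 1e-9)
})

test_that("identical seeds reproduce spike tables bit-for-bit", {
  cpl <- coupling_strengths(50, 3, 1.8)
  a <- simulate_network(cpl, duration = 2000, seed = 123)
  b <- simulate_network(cpl, duration = 2000, seed = 123)
  expect_identical(a$time_ms, b$time_ms)
  expect_identical(a$neuron_id, b$neuron_id)
  c <- simulate_network(cpl, duration = 2000, seed = 124)
  expect_false(identical(a$time_ms, c$time_ms))

  # with membrane noise the same holds
  an <- simulate_network(cpl, duration = 500, seed = 9, noise_sd = 0.5)
  bn <- simulate_network(cpl, duration = 500, seed = 9, noise_sd = 0.5)
  expect_identical(an$time_ms, bn$time_ms)
})

test_that("Euler error scales linearly in dt against the closed-form membrane solution", {
  # freeze g by making its decay negligible over the run
  p <- neuron_params(tau_ex = 1e12)
  cpl <- coupling_strengths(2, 0.001, 0)
  g0 <- 0.15 # subthreshold: V_inf = -60/1.15 > v_theta is false, no spikes
  errs <- vapply(c(0.01, 0.001), function(dt) {
    spk <- simulate_network(cpl, duration = 20, params = p, dt = dt,
                            init = quiet_init(2, p, g = g0),
                            record_traces = TRUE, trace_stride = 1L)
    tt <- attr(spk, "trace_time")
    vv <- attr(spk, "trace_v")[, 1]
    a <- (p$v_rest + g0 * p$e_ex) / p$tau
    b <- (1 + g0) / p$tau
    exact <- a / b + (p$v_rest - a / b) * exp(-b * tt)
    max(abs(vv - exact))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 8)
  expect_lt(errs[1] / errs[2], 12)
})

test_that("same-neuron interspike intervals never undercut the refractory period", {
  spk <- anchor_run(3.0, 0.6)
  iv <- isi_intervals(spk)
  p <- attr(spk, "params")
  expect_gte(min(iv$isi_ms), p$t_ref)
})

test_that("continuation restarts are exact", {
  cpl <- coupling_strengths(30, 3, 1.5)
  whole <- simulate_network(cpl, duration = 1000, seed = 2)
  first <- simulate_network(cpl, duration = 600, seed = 2)
  rest <- continue_simulation(first, duration = 400)
  glued <- rbind(as.data.frame(first), as.data.frame(rest))
  expect_equal(glued$time_ms, whole$time_ms)
  expect_equal(glued$neuron_id, whole$neuron_id)
})

test_that("invalid schedules and event floods raise errors", {
  cpl <- coupling_strengths(10, 2, 1)
  expect_error(
    simulate_network(cpl, duration = 10,
                     schedule = data.frame(time_ms = 0, k_mean = 1,
                                           delta_k = 2)),
    "delta_k")
  expect_error(
    simulate_network(cpl, duration = 2000, seed = 1, max_events = 50),
    "event cap")
})
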