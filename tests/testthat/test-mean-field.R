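test_that("steady conductance is the product of tau_ex, coupling and mean field", {
  expect_equal(steady_conductance(5, 0), 0)
  expect_equal(steady_conductance(2, 0.1), 1.0)
  expect_equal(steady_conductance(c(1, 2), 0.05), c(0.25, 0.5))
  expect_error(steady_conductance(-1, 0.1), "nonnegative")
  expect_error(time_to_threshold(1, -0.1), "nonnegative")
})

test_that("the firing bound separates finite from infinite threshold times", {
  expect_equal(firing_bound(), (1 / 5) * (10 / 50))
  expect_equal(time_to_threshold(2, 0), Inf)
  b <- firing_bound()
  expect_equal(time_to_threshold(1, b), Inf)       # exactly at the bound
  near <- time_to_threshold(1, b * (1 + 1e-8))
  nearer <- time_to_threshold(1, b * (1 + 1e-12))
  expect_lt(near, Inf)                             # just above: finite...
  expect_gt(near, 100)                             # ...but long, and growing
  expect_gt(nearer, near)                          # (log divergence at the bound)
})

test_that("closed-form threshold time matches adaptive ODE integration", {
  testthat::skip_if_not_installed("deSolve")
  for (k in c(0.5, 2, 8)) {
    for (r in c(0.05, 0.1, 0.18)) {
      if (k * r <= firing_bound()) next
      expect_equal(time_to_threshold(k, r), ode_time_to_threshold(k, r),
                   tolerance = 1e-8)
    }
  }
})

test_that("the self-consistency map is nondecreasing and refractory-bounded", {
  k <- coupling_strengths(50, 3, 1.5)$k
  rs <- seq(0, 0.2, length.out = 81)
  m <- smf_map(rs, k)
  expect_equal(m[1], 0)
  expect_true(all(diff(m) >= -1e-14))
  expect_true(all(m <= 1 / neuron_params()$t_ref))
  # per-neuron rate tends to the refractory ceiling at huge drive
  expect_equal(smf_rate(5, 1e6), 0.2, tolerance = 1e-4)
  expect_lte(smf_rate(5, 1e6), 0.2)
})

test_that("weak networks have only the silent fixed point", {
  sol <- solve_smf(coupling_strengths(100, 0.1, 0.05))
  expect_equal(sol$r_bar, 0)
  expect_equal(sol$roots, 0)
  expect_false(any(sol$neurons$fires))
})

test_that("the active fixed point is self-consistent to solver tolerance", {
  cpl <- coupling_strengths(100, 3, 1.8)
  sol <- solve_smf(cpl)
  expect_gt(sol$r_bar_hz, 0)
  expect_lt(abs(sol$residual), 1e-9)
  expect_equal(smf_map(sol$r_bar, cpl$k), sol$r_bar, tolerance = 1e-8)
  expect_equal(sol$r_bar, mean(1000 * smf_rate(cpl$k, sol$r_bar)) / 1000)
  expect_true(all(sol$neurons$rate_hz[sol$neurons$fires] < 1000 / 5))
  expect_equal(sol$neurons$g_star,
               neuron_params()$tau_ex * cpl$k * sol$r_bar)
  # tidy/glance accessors
  expect_equal(nrow(tidy(sol)), 100)
  expect_equal(glance(sol)$n_active, sum(sol$neurons$fires))
})

test_that("threshold time falls and rate rises with drive above the bound", {
  drives <- seq(0.05, 0.5, length.out = 40)
  ts <- time_to_threshold(drives, 1)
  expect_true(all(diff(ts) < 0))
  expect_true(all(diff(smf_rate(drives, 1)) > 0))
})

test_that("steady conductance matches the simulated time average in the drifting state", {
  cpl <- coupling_strengths(100, 2.0, 1.2)
  spk <- cached("gtrace_2_06", {
    simulate_network(cpl, duration = 8000, seed = 13,
                     record_traces = TRUE, trace_stride = 50L)
  })
  prof <- spike_rates(spk, t_transient = 2000, t_measure = 6000)
  r_sim <- mean(prof$rate_hz) / 1000
  tt <- attr(spk, "trace_time")
  sel <- tt > 2000
  for (i in c(30, 60, 90)) {
    g_avg <- mean(attr(spk, "trace_g")[sel, i])
    expect_equal(g_avg, steady_conductance(cpl$k[i], r_sim),
                 tolerance = 0.02)
  }
})

test_that("finite-N solutions converge to the thermodynamic-limit quadrature", {
  thermo <- solve_smf_limit(3, 1.8)
  expect_lt(abs(thermo$residual), 1e-9)
  err <- vapply(c(50, 200, 800), function(n) {
    abs(solve_smf(coupling_strengths(n, 3, 1.8))$r_bar - thermo$r_bar)
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3] / thermo$r_bar, 1e-3)
  # degenerate spread reduces to the single-K self-consistency
  expect_equal(solve_smf_limit(5, 0)$r_bar,
               solve_smf(rep(5, 2))$r_bar, tolerance = 1e-8)
})

test_that("mean-field phase boundaries behave at the degenerate and mixed limits", {
  b0 <- smf_boundaries(0, n = 50)
  expect_equal(b0$k_onset, b0$k_all_active, tolerance = 1e-3)

  # a partially inactive state lies strictly between the two curves
  br <- smf_boundaries(0.9, n = 100, spread = "relative")
  expect_lt(br$k_onset, 2.0)
  expect_gt(br$k_all_active, 2.0)
})

test_that("simulation confirms the activity-onset boundary within grid resolution", {
  b <- smf_boundaries(1.0, n = 100)
  below <- coupling_strengths(100, b$k_onset - 0.15, 1.0)
  above <- coupling_strengths(100, b$k_onset + 0.15, 1.0)
  p_below <- spike_rates(simulate_network(below, 6000, seed = 23),
                         t_transient = 2000, t_measure = 4000)
  p_above <- spike_rates(simulate_network(above, 6000, seed = 23),
                         t_transient = 2000, t_measure = 4000)
  expect_equal(mean(p_below$rate_hz), 0)
  expect_gt(mean(p_above$rate_hz), 10)
})
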