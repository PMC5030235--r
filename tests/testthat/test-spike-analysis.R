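periodic_record <- function(period_ms = 10, duration = 10000, n = 1) {
  times <- seq(period_ms, duration, by = period_ms)
  as_spike_record(
    tibble::tibble(neuron_id = rep(seq_len(n), each = length(times)),
                   time_ms = rep(times, n)),
    n_neurons = n, duration = duration)
}

test_that("rates are spike counts over the measurement window", {
  rec <- periodic_record(10, 12000)
  prof <- spike_rates(rec, t_transient = 2000, t_measure = 10000)
  expect_equal(prof$rate_hz, 100)

  empty <- as_spike_record(tibble::tibble(neuron_id = integer(),
                                          time_ms = numeric()),
                           n_neurons = 5, duration = 4000)
  expect_equal(spike_rates(empty, 1000, 3000)$rate_hz, rep(0, 5))

  expect_error(spike_rates(rec, t_transient = 12000), "window")
  expect_error(spike_rates(rec, t_transient = 6000, t_measure = 7000),
               "window")
})

test_that("periodic trains have zero CV and a single normalized-ISI bin", {
  rec <- periodic_record(8, 8000)
  st <- isi_stats(rec)
  expect_equal(st$cv, 0)
  expect_equal(st$mean_isi_ms, 8)

  h <- isi_histogram(rec, bins = 100, s_max = 3)
  bw <- h$s_over_t[2] - h$s_over_t[1]
  expect_equal(sum(h$density) * bw, 1)
  expect_equal(h$s_over_t[which(h$density > 0)], 1, tolerance = bw)
})

test_that("iid exponential intervals give CV near one", {
  times <- cumsum(withr::with_seed(31, stats::rexp(50000, rate = 0.1)))
  rec <- as_spike_record(tibble::tibble(neuron_id = 1L, time_ms = times))
  st <- isi_stats(rec)
  expect_equal(st$cv, 1, tolerance = 0.03)
})

test_that("neurons with fewer than two spikes are excluded and reported", {
  rec <- as_spike_record(
    tibble::tibble(neuron_id = c(1L, 1L, 1L, 2L),
                   time_ms = c(10, 20, 30, 15)),
    n_neurons = 3)
  st <- isi_stats(rec, neurons = 1:3)
  expect_equal(st$neuron_id, 1L)
  expect_setequal(attr(st, "excluded"), 2:3)
  expect_error(isi_pairs(rec, neuron = 2), "at least 2")
})

synthetic_profile <- function(rates) {
  tibble::tibble(neuron_id = seq_along(rates),
                 k_rank = seq_along(rates) / length(rates),
                 rate_hz = rates)
}

test_that("state labels follow the inactive/drifting/synchronized taxonomy", {
  expect_equal(classify_state(synthetic_profile(rep(0, 100)))$label, "I")

  # continuum only
  d <- classify_state(synthetic_profile(seq(60, 160, length.out = 100)))
  expect_equal(d$label, "D")

  # plateau + continuum
  ds <- classify_state(synthetic_profile(c(rep(99, 25),
                                           seq(110, 125, length.out = 75))))
  expect_equal(ds$label, "D+S")
  expect_equal(ds$fractions[["synchronized"]], 0.25)

  # silent subset + continuum
  id <- classify_state(synthetic_profile(c(rep(0, 10),
                                           seq(20, 120, length.out = 90))))
  expect_equal(id$label, "I+D")
  expect_equal(id$fractions[["inactive"]], 0.10)

  # single plateau spanning everyone
  s <- classify_state(synthetic_profile(rep(150, 100)))
  expect_equal(s$label, "S")
  expect_equal(sum(s$fractions), 1)
})

test_that("classification ignores neuron labels as long as rank order is kept", {
  prof <- synthetic_profile(c(rep(99, 25), seq(110, 125, length.out = 75)))
  relabeled <- prof
  relabeled$neuron_id <- prof$neuron_id + 1000L
  a <- classify_state(prof)
  b <- classify_state(relabeled)
  expect_equal(a$label, b$label)
  expect_equal(a$fractions, b$fractions)
})

test_that("numerically identical rates are never split across a plateau", {
  prof <- synthetic_profile(c(seq(50, 80, length.out = 40), rep(100, 60)))
  lab <- classify_state(prof)
  expect_equal(length(lab$cluster), 60)
  expect_setequal(lab$cluster, 41:100)
})

test_that("identical neurons synchronize: zero coupling spread gives state S", {
  cpl <- coupling_strengths(50, 5, 0)
  spk <- simulate_network(cpl, duration = 6000, seed = 77)
  prof <- spike_rates(spk, t_transient = 2000, t_measure = 4000)
  lab <- classify_state(prof)
  expect_equal(lab$label, "S")
  expect_equal(lab$fractions[["synchronized"]], 1)
})
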