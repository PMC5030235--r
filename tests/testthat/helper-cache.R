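# Heavy simulations are shared across test files through a lazy cache so each
# parameter point is integrated once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Standard 12 s run (2 s settling + 10 s measurement) at N = 100.
anchor_run <- function(k_mean, delta_ratio, seed = 42, duration = 12000) {
  key <- sprintf("anchor_%g_%g_%d_%g", k_mean, delta_ratio, seed, duration)
  cached(key, {
    cpl <- coupling_strengths(100, k_mean, k_mean * delta_ratio)
    simulate_network(cpl, duration = duration, seed = seed)
  })
}

# Long mixed-state run used by the chaos diagnostics: enough spikes for
# > 20000 interspike intervals of a mid-rank drifting neuron (~110 Hz).
mixed_long_run <- function() {
  cached("mixed_long", {
    cpl <- coupling_strengths(100, 2.0, 0.4)
    simulate_network(cpl, duration = 2000 + 185000, seed = 5)
  })
}

# The drifting neuron whose coupling rank is closest to 0.5 (the cluster, if
# any, is excluded first).
mid_drifting_neuron <- function(record, t_transient = 2000) {
  prof <- spike_rates(record, t_transient = t_transient)
  lab <- classify_state(prof)
  drifters <- setdiff(prof$neuron_id[prof$rate_hz >= 1], lab$cluster)
  drifters[which.min(abs(prof$k_rank[drifters] - 0.5))]
}

# Uniform random points used by the box-counting checks.
unit_square_points <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(s_n = stats::runif(n),
                                        s_np1 = stats::runif(n)))
}
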