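#' Simulate the excitatory spiking network
#'
#' Integrates the conductance-based integrate-and-fire network with a fixed
#' timestep. Membrane potentials follow a forward-Euler step of
#' `tau dV/dt = (v_rest - V) + g (e_ex - V) + i_ext` while conductances decay
#' by the exact exponential factor between spike-driven increments
#' `Delta g_i = K_i/(n-1) * sum_j w_ij y_j`. Threshold crossing, reset and
#' refractory onset happen within a step; the resulting conductance
#' increments are applied at the end of that step and first influence the
#' next step. During the refractory period the membrane equation is
#' suspended (`V` clamped at `v_rest`) but conductances keep decaying and
#' accumulating input.
#'
#' Initial membrane potentials are drawn uniformly from `[v_rest, v_theta)`
#' and initial conductances uniformly from `[0, 2]` under `seed`; no neuron
#' starts refractory. The conductance kick is what ignites the autonomous
#' network (without it no potential could ever reach threshold); whether
#' activity is then sustained is decided by the coupling, and the ignition
#' transient is discarded by the analysis functions.
#' Identical configurations and seed reproduce identical spike tables
#' bit-for-bit.
#'
#' @param coupling Coupling tibble from [coupling_strengths()] (columns
#'   `neuron_id`, `k`, `k_offset`).
#' @param duration Simulated time, ms.
#' @param params [neuron_params()].
#' @param dt Timestep, ms (default 0.01).
#' @param weights Optional `n x n` weight matrix from [weight_matrix()];
#'   `NULL` selects the exact uniform mean-field matrix (fast path).
#' @param i_ext Constant external drive, mV (enters the membrane equation
#'   additively). Ignored when `schedule` is given.
#' @param noise_sd Standard deviation of additive zero-mean Gaussian membrane
#'   noise, mV sqrt(ms); the per-step increment is scaled by `sqrt(dt)` so
#'   the noise intensity is timestep-invariant.
#' @param seed RNG seed for initial conditions and noise; `NULL` uses the
#'   current RNG state.
#' @param init Optional state snapshot (the `final_state` attribute of a
#'   previous run) to continue from; overrides the random initial conditions.
#' @param schedule Optional piecewise-linear parameter schedule: a data frame
#'   with columns `time_ms`, `k_mean`, `delta_k` and optionally `i_ext`.
#'   Couplings then follow `K_i(t) = k_mean(t) + delta_k(t) * k_offset_i`.
#' @param record_traces If `TRUE`, store `V` and `g` trajectories every
#'   `trace_stride` steps (memory-hungry; meant for short runs).
#' @param trace_stride Steps between stored trace samples.
#' @param max_events Safety cap on the number of recorded spikes.
#' @return A `spike_record`: a tibble with columns `neuron_id` and `time_ms`,
#'   one row per spike, ordered by time, with the run configuration, final
#'   state and optional traces stored as attributes.
#' @examples
#' cpl <- coupling_strengths(100, k_mean = 3, delta_k = 1.8)
#' spk <- simulate_network(cpl, duration = 500, seed = 1)
#' head(spk)
#' @export
simulate_network <- function(coupling, duration, params = neuron_params(),
                             dt = 0.01, weights = NULL, i_ext = 0,
                             noise_sd = 0, seed = NULL, init = NULL,
                             schedule = NULL, record_traces = FALSE,
                             trace_stride = 1L, max_events = 2e7) {
  stopifnot(
    "duration must be > 0" = duration > 0,
    "dt must be > 0" = dt > 0,
    "noise_sd must be >= 0" = noise_sd >= 0,
    "coupling must have columns neuron_id, k" =
      all(c("neuron_id", "k") %in% names(coupling))
  )
  params <- as_neuron_params(params)
  n <- nrow(coupling)
  if (any(coupling$k < 0)) stop("negative coupling strength in `coupling`")
  if (!is.null(weights)) {
    stopifnot(
      "weights must be an n x n matrix" =
        is.matrix(weights) && all(dim(weights) == n),
      "weights must have zero diagonal" = all(diag(weights) == 0),
      "weights must be nonnegative" = all(weights >= 0)
    )
  }

  if (is.null(schedule)) {
    sched <- matrix(c(0, 0, 1, i_ext), nrow = 1)
    k_base <- coupling$k
  } else {
    stopifnot(
      "schedule needs columns time_ms, k_mean, delta_k" =
        all(c("time_ms", "k_mean", "delta_k") %in% names(schedule)),
      "coupling needs a k_offset column for scheduled runs" =
        "k_offset" %in% names(coupling)
    )
    if (is.null(schedule$i_ext)) schedule$i_ext <- 0
    if (is.unsorted(schedule$time_ms)) stop("schedule times must be sorted")
    if (any(schedule$delta_k > schedule$k_mean) || any(schedule$delta_k < 0)) {
      stop("schedule requires 0 <= delta_k <= k_mean at every breakpoint")
    }
    sched <- cbind(schedule$time_ms, schedule$k_mean, schedule$delta_k,
                   schedule$i_ext)
    k_base <- coupling$k_offset
  }

  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    v0 <- stats::runif(n, params$v_rest, params$v_theta)
    # an initial conductance kick is required to ignite the autonomous
    # network: with g = 0 and no external drive every potential decays to
    # rest and no spike can ever occur. The kick is discarded with the
    # settling transient.
    g0 <- stats::runif(n, 0, 2)
    ref0 <- rep(0, n)
    yw0 <- rep(0L, n)
    t0 <- 0
  } else {
    stopifnot(all(c("v", "g", "ref", "yw", "t") %in% names(init)))
    v0 <- init$v; g0 <- init$g; ref0 <- init$ref
    yw0 <- as.integer(init$yw); t0 <- init$t
  }

  nsteps <- round(duration / dt)
  out <- sim_core(k_base, sched, weights,
                  params$tau, params$tau_ex, params$v_rest, params$v_theta,
                  params$e_ex, params$t_ref, params$spike_width_steps,
                  dt, nsteps, t0, noise_sd, v0, g0, ref0, yw0,
                  record_traces, as.integer(trace_stride), max_events)

  rec <- tibble::tibble(neuron_id = out$neuron + 1L, time_ms = out$time)
  attr(rec, "n_neurons") <- n
  attr(rec, "coupling") <- coupling
  attr(rec, "params") <- params
  attr(rec, "dt") <- dt
  attr(rec, "t0") <- t0
  attr(rec, "t_end") <- out$t_end
  attr(rec, "duration") <- out$t_end - t0
  attr(rec, "final_state") <- list(v = out$v, g = out$g, ref = out$ref,
                                   yw = out$yw, t = out$t_end)
  if (record_traces) {
    attr(rec, "trace_time") <- out$trace_time
    attr(rec, "trace_v") <- out$trace_v
    attr(rec, "trace_g") <- out$trace_g
  }
  class(rec) <- c("spike_record", class(rec))
  rec
}

#' Construct a spike record from a plain spike table
#'
#' Wraps an existing table of spike events (for instance one read from disk
#' or produced by other software) as a `spike_record` so the analysis
#' functions can consume it.
#'
#' @param x Data frame with columns `neuron_id` (1-based integers) and
#'   `time_ms`.
#' @param n_neurons Network size; defaults to `max(neuron_id)`.
#' @param duration Recording length, ms; defaults to `max(time_ms)`.
#' @param t0 Recording start time, ms.
#' @param coupling Optional coupling tibble ([coupling_strengths()]).
#' @param params Optional [neuron_params()].
#' @return A `spike_record` tibble.
#' @export
as_spike_record <- function(x, n_neurons = NULL, duration = NULL, t0 = 0,
                            coupling = NULL, params = NULL) {
  stopifnot(all(c("neuron_id", "time_ms") %in% names(x)))
  rec <- tibble::tibble(neuron_id = as.integer(x$neuron_id),
                        time_ms = as.numeric(x$time_ms))
  rec <- dplyr::arrange(rec, .data$time_ms, .data$neuron_id)
  if (is.null(n_neurons)) {
    n_neurons <- if (nrow(rec) > 0) max(rec$neuron_id) else 0L
  }
  if (is.null(duration)) {
    duration <- if (nrow(rec) > 0) max(rec$time_ms) - t0 else 0
  }
  attr(rec, "n_neurons") <- as.integer(n_neurons)
  attr(rec, "coupling") <- coupling
  attr(rec, "params") <- params
  attr(rec, "t0") <- t0
  attr(rec, "t_end") <- t0 + duration
  attr(rec, "duration") <- duration
  class(rec) <- c("spike_record", class(rec))
  rec
}

#' Continue a simulation from its final state
#'
#' Restarts the integrator bit-exactly from the state snapshot stored in a
#' previous [simulate_network()] result, optionally with different coupling
#' parameters, external drive or schedule. Used by the adiabatic protocols to
#' carry the network state continuously across parameter ramps and frozen
#' observation windows.
#'
#' @param record A `spike_record` produced by [simulate_network()].
#' @param duration Additional simulated time, ms.
#' @param ... Passed on to [simulate_network()] (e.g. `schedule`, `i_ext`).
#' @return A new `spike_record` starting at the previous end time.
#' @export
continue_simulation <- function(record, duration, ...) {
  st <- attr(record, "final_state")
  if (is.null(st)) stop("record carries no final_state snapshot to continue from")
  args <- list(...)
  if (is.null(args$coupling)) args$coupling <- attr(record, "coupling")
  if (is.null(args$params)) args$params <- attr(record, "params")
  if (is.null(args$dt)) args$dt <- attr(record, "dt")
  do.call(simulate_network,
          c(list(duration = duration, init = st), args))
}

#' @export
print.spike_record <- function(x, ...) {
  n <- attr(x, "n_neurons")
  cat(sprintf("<spike_record> %d spikes from %s neurons over %.6g ms (t0 = %g ms)\n",
              nrow(x), ifelse(is.null(n), "?", n),
              attr(x, "duration") %||% NA, attr(x, "t0") %||% 0))
  NextMethod()
}
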