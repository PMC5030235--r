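#' Scan the (k_mean, delta_k) phase diagram
#'
#' Simulates every cell of a coupling-parameter grid from random initial
#' conditions, classifies the settled state and records the mean network
#' rate. Low mean coupling gives the inactive state; small spreads at large
#' coupling synchronize the whole network; most of the plane in between is
#' dominated by drifting states. The mean rate varies smoothly and drops
#' only towards the inactive region, so it carries no signature of the
#' other phase boundaries.
#'
#' @param k_values Grid of mean couplings `k_mean`.
#' @param delta_ratio Grid of relative spreads `delta_k / k_mean` in `[0, 1]`.
#' @param n Network size.
#' @param params [neuron_params()].
#' @param dt Timestep, ms.
#' @param t_transient,t_measure Settling and measurement windows, ms.
#' @param seed Master seed; each cell uses `seed + cell index`.
#' @param ... Passed to [classify_state()].
#' @return A tibble with one row per cell: `k_mean`, `delta_k`, `label`,
#'   state fractions, `mean_rate_hz`, `seed`. Failed cells carry `NA` values
#'   and the error message in `error`.
#' @export
scan_phase_diagram <- function(k_values, delta_ratio, n = 100,
                               params = neuron_params(), dt = 0.01,
                               t_transient = 2000, t_measure = 10000,
                               seed = 1, ...) {
  grid <- tidyr::expand_grid(k_mean = k_values, delta_ratio = delta_ratio)
  purrr::pmap_dfr(
    list(grid$k_mean, grid$delta_ratio, seq_len(nrow(grid))),
    function(km, dr, idx) {
      cell_seed <- seed + idx
      res <- tryCatch({
        cpl <- coupling_strengths(n, km, km * dr)
        spk <- simulate_network(cpl, duration = t_transient + t_measure,
                                params = params, dt = dt, seed = cell_seed)
        prof <- spike_rates(spk, t_transient = t_transient,
                            t_measure = t_measure)
        lab <- classify_state(prof, ...)
        dplyr::bind_cols(
          tibble::tibble(k_mean = km, delta_k = km * dr),
          tidy(lab)[, c("label", "frac_inactive", "frac_drifting",
                        "frac_synchronized")],
          tibble::tibble(mean_rate_hz = mean(prof$rate_hz),
                         seed = cell_seed, error = NA_character_)
        )
      }, error = function(e) {
        tibble::tibble(k_mean = km, delta_k = km * dr, label = NA_character_,
                       frac_inactive = NA_real_, frac_drifting = NA_real_,
                       frac_synchronized = NA_real_, mean_rate_hz = NA_real_,
                       seed = cell_seed, error = conditionMessage(e))
      })
      res
    }
  )
}

#' Adiabatic path through coupling-parameter space
#'
#' Moves the coupling parameters `(k_mean, delta_k)` along a polyline of
#' vertices on a timescale much slower than the network dynamics, carrying
#' the network state continuously. At every vertex the parameters are frozen
#' and, after a settling period, a rate profile is measured — parameters
#' never change during an observation window. Ramps are linear in time; each
#' ramp lasts at least `ms_per_unit` times the larger of the two parameter
#' changes, and never less than `100 * tau`, so the drive is adiabatic.
#'
#' Traversing a path forwards and backwards probes reversibility: the
#' emergence of a synchronized cluster out of the fully drifting state is
#' reversible, while leaving the fully synchronized state is not — the
#' network then lingers in metastable attractors, a signature of coexisting
#' states near that transition.
#'
#' @param points Data frame of path vertices with columns `k_mean` and
#'   `delta_k` (visited in row order).
#' @param n Network size.
#' @param params [neuron_params()].
#' @param dt Timestep, ms.
#' @param ms_per_unit Ramp slowness: simulated ms per unit parameter change.
#' @param settle_ms Settling time after each ramp before measuring, ms.
#' @param window_ms Length of each frozen observation window, ms.
#' @param seed Seed for the initial conditions.
#' @param ... Passed to [classify_state()].
#' @return A tibble with one row per window: `window`, `k_mean`, `delta_k`,
#'   `label`, `mean_rate_hz`, `profile` (list column of rate profiles),
#'   `seed`.
#' @export
run_adiabatic <- function(points, n = 100, params = neuron_params(),
                          dt = 0.01, ms_per_unit = 20000, settle_ms = 1000,
                          window_ms = 5000, seed = 1, ...) {
  stopifnot(all(c("k_mean", "delta_k") %in% names(points)),
            nrow(points) >= 1)
  params <- as_neuron_params(params)
  cpl <- coupling_strengths(n, points$k_mean[1], points$delta_k[1])

  const_sched <- function(t0, km, dk) {
    data.frame(time_ms = t0, k_mean = km, delta_k = dk)
  }
  # initial settle + first window
  state <- simulate_network(
    cpl, duration = settle_ms + window_ms, params = params, dt = dt,
    seed = seed, schedule = const_sched(0, points$k_mean[1], points$delta_k[1])
  )
  measure <- function(spk) {
    spike_rates(spk, t_transient = settle_ms, t_measure = window_ms)
  }
  rows <- list()
  add_row <- function(idx, km, dk, prof) {
    lab <- classify_state(prof, ...)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      window = idx, k_mean = km, delta_k = dk, label = lab$label,
      mean_rate_hz = mean(prof$rate_hz), profile = list(prof), seed = seed
    )
  }
  add_row(1L, points$k_mean[1], points$delta_k[1], measure(state))

  for (i in seq_len(nrow(points) - 1)) {
    km_a <- points$k_mean[i];     dk_a <- points$delta_k[i]
    km_b <- points$k_mean[i + 1]; dk_b <- points$delta_k[i + 1]
    change <- max(abs(km_b - km_a), abs(dk_b - dk_a))
    ramp_ms <- max(100 * params$tau, ms_per_unit * change)
    t0 <- attr(state, "t_end")
    if (change > 0) {
      ramp_sched <- data.frame(time_ms = c(t0, t0 + ramp_ms),
                               k_mean = c(km_a, km_b),
                               delta_k = c(dk_a, dk_b))
      state <- continue_simulation(state, duration = ramp_ms,
                                   schedule = ramp_sched)
      t0 <- attr(state, "t_end")
    }
    state <- continue_simulation(state, duration = settle_ms + window_ms,
                                 schedule = const_sched(t0, km_b, dk_b))
    # the measured profile belongs to the target coupling values
    attr(state, "coupling") <- coupling_strengths(n, max(km_b, 1e-12), dk_b)
    add_row(i + 1L, km_b, dk_b, measure(state))
  }
  dplyr::bind_rows(rows)
}

#' Adiabatic external-input excursions
#'
#' Starting from the settled autonomous state (`i_ext = 0`), ramps a
#' homogeneous external drive adiabatically through a sequence of values,
#' measuring a settled rate profile at each. Two independent excursions are
#' run from the same settled state, one towards positive and one towards
#' negative inputs. In the drifting state the rates respond continuously:
#' positive drive pushes the network towards the refractory-limited
#' saturation rate, negative drive lowers activity until the network falls
#' silent at a strongly negative input.
#'
#' @param coupling Coupling tibble from [coupling_strengths()].
#' @param i_ext_positive,i_ext_negative Input values for the two excursions
#'   (visited in order, each starting from 0), mV.
#' @param params,dt,settle_ms,window_ms,seed As in [run_adiabatic()].
#' @param ramp_ms Duration of each ramp between consecutive input values.
#' @return A tibble with one row per measured value: `excursion`
#'   (`"positive"`/`"negative"`), `i_ext`, `mean_rate_hz`, `n_active`,
#'   `profile` (list column).
#' @export
input_ramp <- function(coupling, i_ext_positive = c(2, 5, 10),
                       i_ext_negative = c(-2, -5, -8),
                       params = neuron_params(), dt = 0.01, ramp_ms = 2000,
                       settle_ms = 1000, window_ms = 5000, seed = 1) {
  params <- as_neuron_params(params)
  km <- attr(coupling, "k_mean")
  dk <- attr(coupling, "delta_k")
  if (is.null(km) || is.null(dk)) {
    stop("coupling must come from coupling_strengths() (k_mean/delta_k attributes needed)")
  }
  base <- simulate_network(coupling, duration = settle_ms + window_ms,
                           params = params, dt = dt, seed = seed)
  prof0 <- spike_rates(base, t_transient = settle_ms, t_measure = window_ms)
  row0 <- tibble::tibble(excursion = "baseline", i_ext = 0,
                         mean_rate_hz = mean(prof0$rate_hz),
                         n_active = sum(prof0$rate_hz > 1),
                         profile = list(prof0))
  excursion <- function(values, name) {
    state <- base
    cur <- 0
    purrr::map_dfr(values, function(ie) {
      t0 <- attr(state, "t_end")
      state <<- continue_simulation(
        state, duration = ramp_ms,
        schedule = data.frame(
          time_ms = c(t0, t0 + ramp_ms),
          k_mean = km, delta_k = dk, i_ext = c(cur, ie))
      )
      state <<- continue_simulation(state, duration = settle_ms + window_ms,
                                    i_ext = ie)
      cur <<- ie
      prof <- spike_rates(state, t_transient = settle_ms,
                          t_measure = window_ms)
      tibble::tibble(excursion = name, i_ext = ie,
                     mean_rate_hz = mean(prof$rate_hz),
                     n_active = sum(prof$rate_hz > 1),
                     profile = list(prof))
    })
  }
  dplyr::bind_rows(row0,
                   excursion(i_ext_positive, "positive"),
                   excursion(i_ext_negative, "negative"))
}

#' Weight-jitter ensemble
#'
#' Repeats a simulation over independent realizations of a jittered weight
#' matrix (off-diagonal entries `1 + eta`, `eta` flat with half-width
#' `delta_w`) and summarizes the per-rank firing rates by their ensemble
#' mean and standard deviation. Fully drifting states are barely affected
#' by weight variability; partially synchronized states respond more
#' strongly, with realization-to-realization variability concentrated at
#' high coupling ranks where neurons switch between locked and drifting.
#'
#' @param coupling Coupling tibble.
#' @param delta_w Jitter half-width in `[0, 1)`.
#' @param n_realizations Number of independent weight draws.
#' @param params,dt,seed As elsewhere; realization `j` uses weight seed
#'   `seed + j` and shared initial conditions (`seed`) so only the weights
#'   vary.
#' @param t_transient,t_measure Settling/measurement windows, ms.
#' @return A tibble `neuron_id`, `k_rank`, `rate_mean_hz`, `rate_sd_hz`;
#'   the full per-realization rates are attached as attribute
#'   `realizations`.
#' @export
jitter_ensemble <- function(coupling, delta_w, n_realizations = 20,
                            params = neuron_params(), dt = 0.01,
                            t_transient = 2000, t_measure = 10000,
                            seed = 1) {
  n <- nrow(coupling)
  full <- purrr::map_dfr(seq_len(n_realizations), function(j) {
    w <- weight_matrix(n, jitter_width = delta_w, seed = seed + j)
    spk <- simulate_network(coupling, duration = t_transient + t_measure,
                            params = params, dt = dt, weights = w,
                            seed = seed)
    prof <- spike_rates(spk, t_transient = t_transient,
                        t_measure = t_measure)
    dplyr::mutate(prof, realization = j, weight_seed = seed + j)
  })
  out <- full |>
    dplyr::group_by(.data$neuron_id, .data$k_rank) |>
    dplyr::summarise(rate_mean_hz = mean(.data$rate_hz),
                     rate_sd_hz = stats::sd(.data$rate_hz),
                     .groups = "drop")
  if (n_realizations == 1) out$rate_sd_hz <- 0
  attr(out, "realizations") <- full
  out
}

#' Rate profiles across network sizes
#'
#' Simulates the same coupling parameters at several network sizes and
#' returns the rate-vs-rank curves on the common rank axis. Because the
#' afferent coupling scales as `1/(n-1)` and the drifting neurons fire
#' regularly, the curves collapse: finite-size fluctuations are already
#' small at a hundred neurons.
#'
#' @param n_values Network sizes.
#' @param k_mean,delta_k Coupling parameters.
#' @param params,dt,seed As elsewhere; size `n` uses seed `seed + n`.
#' @param t_transient,t_measure Settling/measurement windows, ms.
#' @return A tibble `n`, `neuron_id`, `k`, `k_rank`, `rate_hz`, `seed`.
#' @export
size_scaling <- function(n_values, k_mean, delta_k,
                         params = neuron_params(), dt = 0.01,
                         t_transient = 2000, t_measure = 10000, seed = 1) {
  purrr::map_dfr(n_values, function(n) {
    cpl <- coupling_strengths(n, k_mean, delta_k)
    spk <- simulate_network(cpl, duration = t_transient + t_measure,
                            params = params, dt = dt, seed = seed + n)
    prof <- spike_rates(spk, t_transient = t_transient,
                        t_measure = t_measure)
    dplyr::mutate(prof[, c("neuron_id", "k", "k_rank", "rate_hz")],
                  n = n, seed = seed + n, .before = 1)
  })
}
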