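#' Write and read spike tables
#'
#' Spikes travel between tools as headered TSV with columns `neuron_id`
#' (0-based integer, for interoperability with array-indexed tools) and
#' `spike_time_ms` (fixed 6 decimals, which resolves even a 0.001 ms
#' timestep exactly), sorted by time then neuron id. `read_spikes()` inverts
#' `write_spikes()` exactly at that precision and restores 1-based ids.
#'
#' @param record A `spike_record`.
#' @param path File path.
#' @return `write_spikes()` returns `path` invisibly; `read_spikes()`
#'   returns a `spike_record`.
#' @export
write_spikes <- function(record, path) {
  stopifnot(all(c("neuron_id", "time_ms") %in% names(record)))
  ord <- order(record$time_ms, record$neuron_id)
  lines <- c("neuron_id\tspike_time_ms",
             sprintf("%d\t%.6f", record$neuron_id[ord] - 1L,
                     record$time_ms[ord]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spikes
#' @param n_neurons,duration,t0 Metadata for the reconstructed record (see
#'   [as_spike_record()]).
#' @export
read_spikes <- function(path, n_neurons = NULL, duration = NULL, t0 = 0) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "neuron_id\tspike_time_ms") {
    stop("not a spike TSV (expected header 'neuron_id\\tspike_time_ms'): ", path)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(as_spike_record(
      tibble::tibble(neuron_id = integer(), time_ms = numeric()),
      n_neurons = n_neurons %||% 0L, duration = duration %||% 0, t0 = t0))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop("malformed spike row at line ", bad[1] + 1L, " of ", path)
  }
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  ids <- suppressWarnings(as.integer(m[, 1]))
  ts <- suppressWarnings(as.numeric(m[, 2]))
  bad <- which(is.na(ids) | is.na(ts))
  if (length(bad) > 0) {
    stop("non-numeric spike row at line ", bad[1] + 1L, " of ", path)
  }
  as_spike_record(tibble::tibble(neuron_id = ids + 1L, time_ms = ts),
                  n_neurons = n_neurons, duration = duration, t0 = t0)
}

config_defaults <- function() {
  list(
    neuron = list(tau = 20, tau_ex = 5, v_rest = -60, v_theta = -50,
                  e_ex = 0, t_ref = 5, spike_width_steps = 1L),
    # the key is n_neurons (not n) because a bare `n` is a YAML boolean
    coupling = list(n_neurons = 100L, k_mean = 3, delta_k = 1.8,
                    scheme = "equidistant", seed = NULL),
    weights = list(jitter_width = 0, seed = NULL, renormalize = FALSE),
    simulation = list(dt = 0.01, duration = 12000, i_ext = 0, noise_sd = 0,
                      seed = 1L),
    analysis = list(t_transient = 2000, t_measure = NULL, rate_floor = 1,
                    rel_tol = 0.005, min_cluster = NULL)
  )
}

#' Experiment configuration files
#'
#' Experiments are described by a YAML file with sections `neuron`,
#' `coupling`, `weights`, `simulation` and `analysis` whose keys mirror the
#' arguments of [neuron_params()], [coupling_strengths()],
#' [weight_matrix()], [simulate_network()] and [spike_rates()] /
#' [classify_state()]. Missing keys are filled with the package defaults;
#' unknown sections or keys are rejected by name so typos do not silently
#' fall back to defaults. `load_config(NULL)` (or an empty file) yields the
#' full default configuration. `save_config()` round-trips losslessly.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return `load_config()` returns a validated nested list of class
#'   `experiment_config`; `save_config()` returns `path` invisibly.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  # validate by constructing the domain objects
  do.call(neuron_params, cfg$neuron)
  cpl_args <- cfg$coupling
  names(cpl_args)[names(cpl_args) == "n_neurons"] <- "n"
  do.call(coupling_strengths, cpl_args)
  if (cfg$weights$jitter_width < 0 || cfg$weights$jitter_width >= 1) {
    stop("weights$jitter_width must lie in [0, 1)")
  }
  if (cfg$simulation$dt <= 0) stop("simulation$dt must be > 0")
  if (cfg$simulation$duration <= 0) stop("simulation$duration must be > 0")
  if (cfg$simulation$noise_sd < 0) stop("simulation$noise_sd must be >= 0")
  structure(cfg, class = "experiment_config")
}

#' @rdname load_config
#' @param config An `experiment_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the experiment described by a configuration
#'
#' Convenience front end used by the command-line interface: builds the
#' coupling and weights, runs the simulation and returns the spike record.
#'
#' @param config An `experiment_config` from [load_config()].
#' @param seed Optional override of `simulation$seed`.
#' @return A `spike_record`.
#' @export
run_config <- function(config, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  params <- do.call(neuron_params, config$neuron)
  cpl_args <- config$coupling
  names(cpl_args)[names(cpl_args) == "n_neurons"] <- "n"
  cpl <- do.call(coupling_strengths, cpl_args)
  w <- if (config$weights$jitter_width > 0) {
    weight_matrix(config$coupling$n_neurons, config$weights$jitter_width,
                  seed = config$weights$seed,
                  renormalize = isTRUE(config$weights$renormalize))
  } else NULL
  simulate_network(cpl, duration = config$simulation$duration,
                   params = params, dt = config$simulation$dt, weights = w,
                   i_ext = config$simulation$i_ext,
                   noise_sd = config$simulation$noise_sd,
                   seed = seed %||% config$simulation$seed)
}
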