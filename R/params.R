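#' Membrane and synapse constants
#'
#' Bundles the single-neuron constants of the conductance-based
#' integrate-and-fire model. The membrane potential `V` relaxes towards
#' `v_rest` with time constant `tau` and is driven towards the excitatory
#' reversal potential `e_ex` by a dimensionless conductance `g`, which decays
#' with time constant `tau_ex`. When `V` reaches the threshold `v_theta` the
#' neuron spikes for `spike_width_steps` timesteps, `V` resets to `v_rest`,
#' and the membrane equation is suspended for the refractory period `t_ref`.
#'
#' The refractory period is the activity-limiting mechanism of a purely
#' excitatory network: it caps every firing rate at `1000 / t_ref` Hz
#' (200 Hz at the default 5 ms).
#'
#' @param tau Membrane time constant, ms.
#' @param tau_ex Conductance (synaptic) time constant, ms.
#' @param v_rest Resting potential, mV.
#' @param v_theta Firing threshold, mV.
#' @param e_ex Excitatory reversal potential, mV.
#' @param t_ref Refractory period, ms.
#' @param spike_width_steps Number of timesteps a spike lasts (each step of an
#'   ongoing spike delivers one conductance increment to the targets).
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params()
#' neuron_params(t_ref = 0) # no refractory period: activity dies or explodes
#' @export
neuron_params <- function(tau = 20, tau_ex = 5, v_rest = -60, v_theta = -50,
                          e_ex = 0, t_ref = 5, spike_width_steps = 1L) {
  stopifnot(
    "tau must be > 0" = is.numeric(tau) && tau > 0,
    "tau_ex must be > 0" = is.numeric(tau_ex) && tau_ex > 0,
    "must have v_rest < v_theta < e_ex" = v_rest < v_theta && v_theta < e_ex,
    "t_ref must be >= 0" = is.numeric(t_ref) && t_ref >= 0,
    "spike_width_steps must be >= 1" = spike_width_steps >= 1
  )
  structure(
    list(tau = tau, tau_ex = tau_ex, v_rest = v_rest, v_theta = v_theta,
         e_ex = e_ex, t_ref = t_ref,
         spike_width_steps = as.integer(spike_width_steps)),
    class = "neuron_params"
  )
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  tau = %g ms, tau_ex = %g ms, t_ref = %g ms\n",
              x$tau, x$tau_ex, x$t_ref))
  cat(sprintf("  v_rest = %g mV, v_theta = %g mV, e_ex = %g mV, spike width = %d step(s)\n",
              x$v_rest, x$v_theta, x$e_ex, x$spike_width_steps))
  invisible(x)
}

as_neuron_params <- function(x) {
  if (inherits(x, "neuron_params")) return(x)
  stopifnot(is.list(x))
  do.call(neuron_params, x)
}
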