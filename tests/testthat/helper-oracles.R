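# Independent oracle for the time-to-threshold: integrate the
# frozen-conductance membrane equation with an adaptive high-accuracy ODE
# solver and locate the threshold crossing by root finding.
ode_time_to_threshold <- function(k, r_bar, params = neuron_params()) {
  gs <- params$tau_ex * k * r_bar
  sol <- deSolve::lsoda(
    y = c(v = params$v_rest),
    times = c(0, 1e5),
    func = function(t, y, p) {
      list(((params$v_rest - y) + gs * (params$e_ex - y)) / params$tau)
    },
    rootfunc = function(t, y, p) y - params$v_theta,
    rtol = 1e-12, atol = 1e-12
  )
  tcross <- attributes(sol)$troot
  if (length(tcross) == 0) Inf else tcross
}
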