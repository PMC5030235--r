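# Example experiment configuration: the mixed (drifting + synchronized)
# state at K_mean = 2.0, delta_k / k_mean = 0.2. Omitted keys fall back to
# the package defaults (tau = 20 ms, tau_ex = 5 ms, V_rest = -60 mV,
# V_theta = -50 mV, E_ex = 0 mV, t_ref = 5 ms, dt = 0.01 ms).
coupling:
  n_neurons: 100
  k_mean: 2.0
  delta_k: 0.4
simulation:
  duration: 12000
  seed: 1
analysis:
  t_transient: 2000
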