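# spikedrift

Self-organized dynamical states in autonomous networks of excitable,
purely excitatory spiking neurons — simulation, analytic mean-field theory,
state classification, and a return-map chaos diagnostic.

## The scientific problem

Can a network made exclusively of *excitatory* neurons sustain stable,
asynchronous, even irregular spiking on its own, with no external input and
no inhibition? The units studied here are excitable: leaky
conductance-based integrate-and-fire neurons that stay quiet unless driven
by the rest of the network, so any activity must bootstrap and limit
itself. Two ingredients turn out to suffice: a refractory period (which
caps every firing rate at 1/t_ref and keeps activity from exploding) and a
minimal amount of structural variability — a distribution of afferent
coupling strengths K_i across otherwise identical, globally coupled
neurons.

The package is aimed at computational neuroscientists and dynamical-systems
researchers who want to reproduce, extend or probe this class of models:
its phase diagram, its analytic stationary mean-field solution, and its
spike-train-level chaos diagnostic (which applies to any spike data, not
just this model).

## The model

Each neuron `i` has a membrane potential `V_i` and a dimensionless
conductance `g_i`:

    tau  dV_i/dt = (V_rest − V_i) + g_i (E_ex − V_i) + I_ext
    tau_ex dg_i/dt = −g_i

with `tau = 20 ms`, `tau_ex = 5 ms`, `V_rest = −60 mV`, threshold
`V_theta = −50 mV`, `E_ex = 0 mV`. When `V_i` reaches threshold the neuron
spikes, resets to `V_rest` and is refractory for `t_ref = 5 ms` (the
membrane equation is suspended; conductances keep integrating). Every spike
of neuron `j` increments all other conductances:

    Delta g_i = K_i/(N−1) * sum_{j≠i} w_ij y_j ,  w_ij = 1 (i≠j), w_ii = 0

so each neuron couples to the network mean field `r(t)` with its own gain
`K_i`. The gains are spread evenly over `[K̄ − ΔK, K̄ + ΔK]`. Depending on
`(K̄, ΔK)` the network self-organizes into inactive (I), partially inactive
(I+D), fully drifting (D), mixed (D+S) or fully synchronized (S) states.

For asynchronous drifting states the package also provides the closed-form
stationary mean-field (SMF) solution: with a constant mean field `r̄` the
steady conductance is `g*_i = tau_ex K_i r̄`, the time-to-threshold `t*_i`
follows in closed form, and `r̄ = ⟨1/(t*_i + t_ref)⟩` is solved
self-consistently by bisection.

The chaos diagnostic embeds one neuron's spike train as pairs of
consecutive interspike intervals `(s(n), s(n+1))` and estimates the
box-counting (Minkowski) dimension D_F of the resulting set: D_F = 1 for a
limit cycle, fractional (≈ 1.8 in the mixed state at full resolution) for a
strange attractor.

## Worked example

```r
library(spikedrift)

cpl <- coupling_strengths(n = 100, k_mean = 2.0, delta_k = 0.4)
spk <- simulate_network(cpl, duration = 12000, seed = 1)
print(spk, n = 3)
#> <spike_record> 132146 spikes from 100 neurons over 12000 ms (t0 = 0 ms)
#> # A tibble: 132,146 × 2
#>   neuron_id time_ms
#>       <int>   <dbl>
#> 1        80    0.1
#> 2        21    0.15
#> 3         4    0.21

prof <- spike_rates(spk, t_transient = 2000, t_measure = 10000)
classify_state(prof)
#> <phase_label> D+S  (inactive 0%, drifting 77%, synchronized 23%)

sol <- solve_smf(cpl)
print(sol)
#> <smf_solution>
#>   r_bar = 119.624 Hz (3 fixed points found; residual -3.17e-13)
#>   100 / 100 neurons predicted active
```

At `K̄ = 2, ΔK/K̄ = 0.2` the network settles into the mixed state: 23 of
the 100 neurons lock into a synchronized cluster firing at a common rate,
while the remaining 77 drift with a continuum of higher rates. The SMF
fixed point (119.6 Hz) describes the drifting branch; the measured rates
follow it closely away from the cluster. `autoplot(prof, smf = sol)`
overlays the two rate-vs-rank curves.

The drifting neurons in this state fire chaotically. With a longer run
(≳ 20 000 intervals per neuron) the return-map embedding yields a
fractional dimension:

```r
emb <- isi_pairs(spk, neuron = 50, t_transient = 2000)
fd  <- fractal_dimension(emb, fit_range = 2:4)
print(fd)
#> <boxcount_fit> D_F = 1.540 (fit r = 2..4 over 1108 points)
```

(1108 points from a 10 s window underestimate D_F; the acceptance script
below runs the full-length version, which gives ≈ 1.7.)

A thin command-line front end over the same functions lives at
`inst/cli/spikedrift.R` (`simulate`, `smf`, `smf-boundaries`, `analyze`,
`chaos`, `phase-scan`, `adiabatic`, `ramp`, `ensemble`), driven by a YAML
config and writing tidy TSVs plus a reproducibility manifest.

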