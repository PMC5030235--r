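---
title: "Drifting, synchronized and chaotic states in excitatory spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drifting, synchronized and chaotic states in excitatory spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikedrift)
```

## The model and its assumptions

`spikedrift` simulates and analyses autonomous networks of *excitable*
conductance-based integrate-and-fire neurons: units that fire only when
driven by the rest of the network, with no intrinsic limit cycle and hence
no preexisting natural frequency. Every neuron carries a membrane potential
$V_i$ and a dimensionless conductance $g_i$,

$$\tau \dot V_i = (V_\mathrm{rest} - V_i) + g_i (E_\mathrm{ex} - V_i) + I_\mathrm{ext},
\qquad \tau_\mathrm{ex}\, \dot g_i = -g_i ,$$

with a spike (reset to $V_\mathrm{rest}$, refractory clamp for
$t_\mathrm{ref}$) whenever $V_i$ reaches $V_\theta$. Spikes of neuron $j$
increment every other conductance by
$\Delta g_i = K_i/(N{-}1)\sum_{j\neq i} w_{ij} y_j$. The baseline
connectivity is uniform and all-to-all ($w_{ij}=1$, no self-coupling), so
each neuron integrates the network mean field $r(t)$ with an individual
gain $K_i$, spread evenly across $[\bar K - \Delta K, \bar K + \Delta K]$.
All coupling is excitatory; the refractory period is the only
activity-limiting mechanism, capping every rate at
$1/t_\mathrm{ref}$ (200 Hz at the defaults). Depending on
$(\bar K, \Delta K)$ the network self-organizes into inactive (I),
partially inactive (I+D), fully drifting (D), mixed (D+S) or fully
synchronized (S) states.

Key modelling assumptions: no inhibition, no synaptic delays, no spatial
structure beyond optional weight jitter, instantaneous (one-timestep)
spikes by default, and homogeneous intrinsic parameters — all variability
lives in $K_i$ (and optionally $w_{ij}$).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tau` | 20 | ms | membrane relaxation |
| `tau_ex` | 5 | ms | conductance decay; sets the drive scale $g^*=\tau_\mathrm{ex}K\bar r$ |
| `v_rest`, `v_theta`, `e_ex` | −60, −50, 0 | mV | resting, threshold, reversal |
| `t_ref` | 5 | ms | refractory period; rate ceiling $1/t_\mathrm{ref}$ |
| `k_mean`, `delta_k` | — | – | coupling mean and spread; the phase-diagram axes |
| `dt` | 0.01 | ms | integration step (0.001 for high-resolution chaos runs) |
| `spike_width_steps` | 1 | steps | spike duration; each step delivers one increment |

Neuron constants follow the standard conductance-based benchmark values.
`delta_k` may not exceed `k_mean` (couplings stay nonnegative); the
relative spread `delta_k/k_mean` $\in [0,1]$ is how phase diagrams are
parameterized.

## Numerical scheme

The membrane equation advances by forward Euler at `dt = 0.01` ms while
conductances decay by the *exact* factor $e^{-dt/\tau_\mathrm{ex}}$ between
increments, removing the stiffer linear mode from the error budget at no
cost. Threshold crossing, reset and refractory onset happen inside a step;
the conductance increments a spike generates are applied at the end of that
step and first influence the next step, giving a causal, order-independent
update (simultaneous spikes simply sum). During refractoriness only the
membrane equation is suspended: `V` is clamped at rest while `g` keeps
decaying *and* accumulating input — the conductance models synaptic drive,
not membrane state; this is an assumption the model text leaves open, made
explicit here. Optional membrane noise enters as zero-mean Gaussian
increments scaled by $\sqrt{dt}$, so the noise intensity is
timestep-invariant. The test suite verifies first-order convergence of the
Euler trajectory against the closed-form membrane solution and exactness of
the conductance decay to machine precision.

**Initial conditions.** $V_i \sim U[V_\mathrm{rest}, V_\theta)$ and
$g_i \sim U[0, 2]$. The conductance kick is not cosmetic: an autonomous
excitable network with $g=0$ and no input has every potential decaying
monotonically to rest, so *no* spike could ever occur and every state would
be inactive. The kick ignites activity; whether it survives is decided by
the coupling, and the ignition transient (2 s by default) is discarded
before any measurement. Analyses are insensitive to the kick's scale as
long as it reaches the self-sustaining basin; `[0, 2]` brackets the steady
conductances of all active states studied here.

## The stationary mean-field solution

In an asynchronous drifting state each neuron sees an effectively constant
mean field $\bar r$ (spikes/ms). Its conductance settles at
$g_i^* = \tau_\mathrm{ex} K_i \bar r$ and the membrane equation integrates
in closed form, giving the time-to-threshold

$$t_i^* = -\frac{1}{B_i}\,\log\frac{B_i V_\theta - A_i}{B_i V_\mathrm{rest} - A_i},
\qquad A_i = \frac{V_\mathrm{rest} + g^*_i E_\mathrm{ex}}{\tau},\quad
B_i = \frac{1 + g^*_i}{\tau},$$

finite only above the firing bound
$K_i \bar r > (V_\theta - V_\mathrm{rest}) / (\tau_\mathrm{ex}(E_\mathrm{ex} - V_\theta))$
(0.04 ms⁻¹ at defaults). Self-consistency closes the loop:
$\bar r = \langle 1/(t_i^* + t_\mathrm{ref})\rangle$, with the average taken
over **all** $N$ neurons, silent ones contributing zero — this is what
makes partially inactive states solvable. Because the map is nondecreasing
in $\bar r$ and bounded by $1/t_\mathrm{ref}$, its fixed points are found
by a grid scan plus bracketed bisection (tolerance $10^{-10}$ ms⁻¹);
$\bar r = 0$ always solves, and the package reports the *largest* fixed
point as "the" solution (the active branch) while keeping all bracketed
roots for diagnostics. No stability claim is attached to coexisting roots —
which branch a finite network selects is left open. A thermodynamic-limit
variant (`solve_smf_limit()`) replaces the $N$-point average with 256-node
Gauss–Legendre quadrature over the flat coupling density; finite-$N$
solutions converge to it.

The theory describes drifting components only; it fails by construction
once a synchronized cluster makes the mean field periodic. Two analytic
boundary curves follow from it: activity onset (where a positive fixed
point first exists) and full activation (where the weakest neuron's drive
crosses the firing bound). At finite $N$ exactly the neuron whose drive
falls within one coupling-grid spacing of the bound may land on either
side; comparisons of predicted and simulated silent sets treat that single
boundary neuron as undecided.

## Classifying the self-organized states

Classification works on the settled rate-vs-rank profile (2 s transient,
10 s measurement by default). Neurons below `rate_floor = 1` Hz count as
inactive. Synchrony is diagnosed operationally from *rate equality*, the
model's observable signature ("firing at identical rates"): the largest run
of consecutive-rank active neurons whose rates agree within
`rel_tol = 0.5%` total relative spread forms a synchronized cluster if it
has at least `max(3, 0.05 N)` members; remaining active neurons are
drifting, and the label (I, I+D, D, D+S, S) is assembled from the non-empty
groups. Phase-lag structure inside a cluster is not used for
classification. The tolerance and floor are conventions — the model text
quantifies neither — and are exposed as arguments; at the defaults they
resolve the plateaus of all reference parameter points at $N = 100$.

Two practical caveats. First, rates measured over a window of length $T$
are quantized in units of $1/T$: windows much shorter than ~5 s can merge a
steep continuum into spurious plateaus, so short observation windows should
be paired with a coarser `rel_tol` interpretation (the adiabatic driver
uses 5 s windows for this reason). Second, in mixed states the locked
cluster sits at *low* coupling rank with the drifting continuum above it:
the cluster's common frequency is below the drifting neurons'
self-organized rates, consistent with the driven-oscillator picture of the
mixed state (a slow periodic drive under a faster natural frequency).

Interval statistics complete the picture: per-neuron CV
($\sigma_i/T_i$, population normalization) is zero for periodic firing,
$\sim 10^{-2}$ for the finite-size wobble of pure drifting or synchronized
states, and several-fold larger for drifting neurons driven by a
synchronized cluster. The network-averaged histogram of normalized
intervals $s/T_i$ uses 100 bins on $[0, 3]$ with equal weight per neuron.

## The chaos diagnostic

For one neuron the spike train is embedded as pairs of consecutive
interspike intervals $(s(n), s(n{+}1))$ — a minimal, two-dimensional delay
embedding. The box-counting dimension of the resulting set is the slope of
$\log_2 N_\mathrm{box}$ against the grid exponent $r$, where a
$2^r \times 2^r$ grid of equal squares is laid over the *tight bounding
square* of the points (largest coordinate extent, centred; square cells by
construction). Anchoring the grid to the data rather than to fixed axis
limits is a convention; dimension estimates are insensitive to it well
below saturation. $\log_2 N_\mathrm{box}$ saturates at $\log_2$ of the
number of points, so fit ranges are chosen below saturation: $r = 2\ldots7$
for $\ge 10^5$ points, $2\ldots5$ for $\ge 2\times10^4$, capped
automatically where $N_\mathrm{box} > 0.5\,N_\mathrm{points}$ (and flagged
if capping occurred). The estimator recovers known dimensions (point 0,
segment 1, filled square 2, Koch-type set $\log 4/\log 3$) within $\pm0.1$
at $10^5$ points, and longer spike trains extend the usable linear range.

In the mixed state at $(\bar K, \Delta K/\bar K) = (2.0, 0.2)$ a mid-rank
drifting neuron yields $D_F \approx 1.7$ from $2\times10^4$ intervals at
`dt = 0.01` ms — fractional, hence chaotic firing; a limit cycle would give
1. Higher-resolution runs (`dt = 0.001` ms, $>10^5$ spikes) sharpen the
estimate at proportionally higher cost. No Lyapunov spectrum is computed:
the return-map dimension *is* the diagnostic, and the measured fractional
dimension of the two-dimensional projection indicates (but does not prove)
chaos of the full $2N$-dimensional attractor.

## Protocols

* **Phase scans** simulate each $(\bar K, \Delta K)$ cell independently
  from random initial conditions and classify it; each cell's seed is
  recorded in the output.
* **Adiabatic paths** move the coupling parameters linearly on a timescale
  of $\ge 20$ s simulated time per unit parameter change (never faster than
  $100\tau$), carrying the network state continuously and measuring only in
  frozen windows (1 s settling + 5 s observation). Crossing D $\to$ D+S and
  back reproduces matching profiles (reversible transition); leaving the
  fully synchronized state does not — the network lingers in metastable
  attractors, so downward and upward legs disagree. Irreversibility is
  declared when matched-parameter profiles differ by more than 5% per rank,
  a threshold chosen well above the finite-size noise of the reversible
  branch.
* **Input ramps** drive $I_\mathrm{ext}$ adiabatically through positive and
  negative excursions from the settled autonomous state. Rates respond
  continuously; sufficiently negative input silences the network. The
  coupling point is the documented drifting-state anchor
  $(\bar K, \Delta K/\bar K) = (3.0, 0.6)$; the input level at which
  activity collapses depends on the coupling parameters and is treated as
  an order-of-magnitude observation, not a calibration target.
* **Weight-jitter ensembles** redraw $w_{ij} = 1 + \eta$,
  $\eta \sim U(-\Delta W, \Delta W)$, holding dynamics seeds fixed so only
  structure varies. Jittered matrices are *not* renormalized (the jitter is
  zero-mean, so normalization holds in expectation); a `renormalize` flag
  exists for exact row sums. The drifting state is the least affected;
  partially synchronized states show ensemble variability concentrated at
  high rank, where realizations disagree on who locks.
* **Size scaling** overlays rate-vs-rank curves for $N$ = 50…400; they
  collapse because coupling scales as $1/(N{-}1)$, with deviations of a few
  percent at $N = 50$.
* **Noise robustness** uses `noise_sd` ∈ {0.1, 0.5, 1.0} mV·ms$^{1/2}$ —
  amplitudes chosen here, as the robustness claim being checked is
  qualitative (state labels survive).

## What the generator emulates — and what it does not

Simulated spike tables are the package's own synthetic data: every analysis
function consumes the same `(neuron, time)` records it would read from
disk, so the full pipeline is exercised end-to-end. The study conditions
are $N = 100$, `dt = 0.01` ms, default neuron constants, 2 s + 10 s
windows; tests that need long interval series use a 187 s mixed-state run
(~$2\times10^4$ intervals per drifting neuron), and size-invariance checks
use $N \in \{50, 100, 200\}$. These sizes keep the full suite and the
acceptance script within minutes on one CPU while leaving all measured
quantities well inside their tolerance bands.

Passing tests therefore show that the *model* behaves as described under
its own idealizations. They do not show that cortical networks do: firing
here is far more regular than in vivo spiking (near-periodic versus
Poisson-like), rates are high, there is no inhibition, no delays, no
topology, and all intrinsic parameters are homogeneous. The chaos
diagnostic, in contrast, is model-agnostic and applies to any sufficiently
long spike train.

## Degenerate inputs and edge cases

Empty spike records classify as inactive; neurons with fewer than two
spikes are excluded from interval statistics and reported. A point set with
zero extent occupies one box at every refinement ($D_F = 0$). `t_ref = 0`
is accepted by the simulator (activity then dies out or saturates at one
spike per step — the refractory period is what makes finite-rate states
possible) but rejected by the mean-field solver, whose map would be
unbounded. Two-neuron networks run through every protocol. Event-count and
non-finiteness guards stop runaway simulations with the offending neuron
and time.

## Known limitations

Forward Euler is first-order: spike times carry an $O(dt)$ bias, which is
why chaos-grade runs use `dt = 0.001` ms. The S/(D+S) coexistence region is
known to shift with the spike width and is not mapped quantitatively here;
`spike_width_steps > 1` is exploratory. The return-map dimension is a
projection diagnostic, not a full attractor reconstruction. Plateau
detection is rate-based and will conflate distinct clusters that happen to
share a firing rate across a rank gap only if they are adjacent in rank;
phase relations within clusters are reported descriptively, not used for
classification.
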