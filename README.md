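# pmcsim

Simulation and theory of synaptic reshaping by **periodic multichannel
stimulation (PMCS)** in plastic networks of excitatory spiking neurons.

Excessive neuronal synchrony sustained by strong synaptic connectivity is
a hallmark of several brain disorders, and patterned brain stimulation —
coordinated reset and its generalisations — aims to *re-wire* such
networks rather than merely mask their symptoms. pmcsim is for
computational neuroscientists who want to design and verify such
stimulation strategies at desk scale: it simulates a network of
excitatory leaky integrate-and-fire (LIF) neurons with spike-timing-
dependent plasticity (STDP) under multichannel stimulation, and predicts
the outcome analytically from the statistics of stimulus-triggered
spikes, so that decoupling protocols and target connectivity motifs can
be designed before (or instead of) running long simulations.

## The model and the forecast

The network: `N` conductance-based LIF neurons with adaptive thresholds,
tonically active (subthalamic-nucleus-like), randomly connected with
probability 7%, driven by Poisson background input. Synaptic weights
`w ∈ [0, 1]` evolve under additive nearest-neighbour STDP with hard
bounds,

    W(Δt) = η e^{−Δt/τ₊}            Δt > 0
    W(Δt) = −η (β/τ_R) e^{Δt/τ₋}    Δt < 0,

where Δt is the post- minus presynaptic arrival lag at the synapse
(axonal delay 3 ms). Unstimulated, the network relaxes to a bistable,
strongly connected synchronised state with a bimodal weight distribution
— the "pathological" pre-stimulation condition.

PMCS delivers charge-balanced single-pulse or burst stimuli periodically
(frequency `f`) to `M` subpopulations with phase lags `Δα_k`. The
package's analytical engine computes the expected rate of weight change
for a synapse whose populations are stimulated with phase shift `φ`,

    ⟨J∞(φ, f, ξ)⟩ = f · (W⁺ + W⁻),

by integrating the STDP kernel over the stimulus-locked spike-time
distributions `Λ_k`, conditional ISI densities `λ_l(ε|x)`, and the
spike-count law `P(k)` (with `ξ = t_a − t_d` the delay difference). Block
means of the weight matrix then follow the bounded linear growth law

    ⟨w_{x→y}(t)⟩ ≈ [ w₀ + S(⟨J∞(Δφ_xy)⟩, w₀) · (t − t₀) ]_clip[0,1],
    S(J, w) = wJ (J ≤ 0),  (1−w)J (J > 0),

with `Δφ_xy` the pairwise phase-shift matrix of the delivery pattern.
Choosing `f`, the stimulus shape (pulse width, pulses per burst,
intraburst frequency) and the `Δα_k` steers every block up or down:
global decoupling, global strengthening, feed-forward chains, trees, and
single-block surgery are all reachable.

## Worked example

Relax a desk-scale network into its synchronised state, then compare the
simulated and predicted rates of weight change between two stimulated
subpopulations as a function of the phase lag:

```r
library(pmcsim)

st <- prepare_relaxed_network(N = 300, M = 2, relax_s = 600, seed = 1)
#> relaxed 600 s: mean weight 0.4531, 68.8% of weights at bounds,
#> 3.60 collective events/s

shape <- stimulus_shape("single_pulse", A_stim = 0.4, d_e = 1)
res <- run_two_pop_rate(st, shape, f = 10, stim_s = 40, density_s = 100,
                        seed = 5)
res
#>    dalpha       J_est     J_theory
#> 1     0.0 -0.06766378 -0.064929959
#> 2     0.1  0.09570511  0.092476424
#> 3     0.2  0.02866960  0.027749285
#> 4     0.3  0.00270542  0.002156409
#> 5     0.4 -0.01090833 -0.009545652
#> ...
attr(res, "sign_agreement")
#> [1] 1
```

Reading the numbers: after relaxation the mean synaptic weight sits near
its stationary value with collective spiking events at ~3.5 per second —
the synchronised state. Under 10 Hz single-pulse PMCS, simultaneous
stimulation (`Δα = 0`) *weakens* the 1→2 synapses at ~0.07 weight units
per second (decoupling), a small positive lag (`Δα = 0.1`, i.e. 10 ms)
*strengthens* them — the postsynaptic population fires just after the
presynaptic one — and larger lags weaken them again. The analytical
prediction `J_theory` tracks the simulation estimate `J_est` across the
whole grid (sign agreement 1.0).

Induce a structure instead: five-pulse bursts at 120 Hz intraburst
frequency up-regulate *all* blocks, at 60 Hz they down-regulate all;
staggered single pulses (`Δα = 0.3, 0.3`) carve a feed-forward chain:

```r
st3 <- prepare_relaxed_network(N = 300, M = 3, relax_s = 600, seed = 1)
sp  <- stimulus_shape("single_pulse", A_stim = 0.4, d_e = 1)
run_motif(st3, sp, f = 10, delta_alpha = c(0.3, 0.3), stim_s = 300)$classes
#>      [,1]   [,2]   [,3]
#> [1,] "down" "up"   "down"
#> [2,] "down" "down" "up"
#> [3,] "down" "down" "down"
```

A thin command-line wrapper over the same drivers ships in
`exec/pmcsim` (`relax`, `isi-stats`, `two-pop`, `decoupling`, `motif`
subcommands; `--full-scale` switches to N = 1000 / 3000 s).

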