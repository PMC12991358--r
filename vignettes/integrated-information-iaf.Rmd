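---
title: "Integrated information of an integrate-and-fire network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated information of an integrate-and-fire network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iafphi)
library(dplyr)
```

Integrated Information Theory (IIT 3.0) quantifies how irreducible a
system's cause-effect structure is to that of its parts, through a scalar
Φ. IIT's machinery is defined for discrete Markovian systems, while
neuronal models live in continuous state spaces. `iafphi` implements one
complete bridge between the two: a discrete-time leaky integrate-and-fire
(LIF) network is simulated at full floating-point resolution, its activity
is coarse-grained to binary spike/no-spike states, an empirical transition
probability matrix (TPM) is estimated from restarted runs, and Φ of the
resulting binary system is computed with a complete IIT 3.0 engine. This
vignette documents the model, the estimation protocol, the engine's
numerical conventions, and the design decisions a user should know before
trusting the numbers.

## The neuron and network model

Each neuron `i` updates its membrane potential once per step `dt`:

$$V_i(t) = V_i(t-1) + \frac{\Delta t}{\tau_i}\bigl(V_{rest} - V_i(t-1)\bigr)
  + \sum_j w_{ij}\, s_j(t-1) + I_i(t),$$

with `tau` the membrane time constant (in multiples of `dt`, `>= 1`),
`w_ij` the synaptic weight in mV from neuron `j`, `s_j` the binary spike
output and `I_i` an optional external increment. The update order within a
step is: leak and synaptic integration first, then the firing-window test
`threshold_low <= V < threshold_high`, then reset to `V_rest` on firing
only. A spike is therefore visible to other neurons on the *following*
step, and a window neuron (XOR) driven at or above its upper bound keeps
its supra-window voltage, stays silent, and continues to obey the update
equation — there is no reset without a spike.

Initial conditions are binary: a '1' neuron is treated as having just
fired (voltage at rest, spike on the wire for step 1), a '0' neuron is at
rest. `dt` is fixed at 1 ms by default and `tau` is expressed in multiples
of `dt`; non-integer `tau` is accepted by the type but the study grid uses
integers 1–8.

`gate_network(w, tau)` builds the canonical three-neuron system in which,
for `tau = 1` and `w = 50` mV, the neurons emulate logic gates through
their thresholds alone: OR fires at 50 mV, AND at 100 mV (150 mV in the
3-input variant used when an external input is attached), XOR in the
window [50, 100) mV. At `tau = 1` the leak term cancels the entire
history, so the network is exactly the memoryless gate system
A = OR(B, C), B = AND(A, C), C = XOR(A, B) — the test suite verifies the
simulated dynamics against an independent truth-table implementation.

## Coarse-graining and TPM estimation

At every step each neuron is mapped to '1' exactly when it fired, and '0'
for *any* other membrane potential — resting or subthreshold. The
empirical TPM is estimated by restarting the simulation once from each of
the `2^n` binary states, recording every consecutive transition including
the initial-state → first-step one, pooling counts over all restarts, and
normalising each row at the end. Including the initial transition
guarantees every row of the TPM is defined and reproduces the reference
gate-system TPM exactly; a switch to exclude transient transitions was
considered and rejected because it leaves rows of never-revisited states
undefined.

Run lengths are part of the study conditions: 8 steps suffice for the
memoryless gate check (8 restarts × 8 steps cover all transitions), 200
steps for the deterministic sweeps (activity is stationary well before
that; a property test asserts eventual periodicity within 200 steps for
the whole grid), and 1000 steps for noisy estimates.

Two caveats the user should keep in mind. First, for `tau > 1` identical
binary states can hide different membrane potentials, so the binary
process need not be Markovian; the empirical TPM is a Markov summary of a
possibly non-Markov coarse-graining, which is precisely the object under
study, not an approximation bug. Second, the state-by-state TPM of such a
system need not be conditionally independent across nodes; the model
object therefore stores the full `2^n × 2^n` matrix and never factorises
it on disk.

## The Φ engine

The engine consumes `(TPM, CM, state)` and implements IIT 3.0 semantics:

- **Per-node views.** Internally the state-by-state TPM is reduced to
  per-node conditional spike probabilities (the state-by-node view), and
  each node's view is marginalised uniformly over its non-inputs according
  to the connectivity matrix. This matches the reference semantics, whose
  repertoire algebra operates on per-node conditionals.
- **Repertoires.** The effect repertoire of a mechanism over a purview is
  the product over purview nodes of the node's spike probability with the
  mechanism clamped to its current state and every other node noised
  (averaged uniformly). The cause repertoire multiplies, over mechanism
  nodes, the likelihood of that node's current state across past purview
  states (non-purview past nodes uniform) and normalises; an all-zero
  likelihood is flagged as an empty repertoire and contributes φ = 0.
- **Small φ.** For each mechanism and direction, φ is the maximum over
  purviews of the minimum over mechanism/purview bipartitions of the
  earth-mover's distance between the whole repertoire and the product of
  the parts. The ground metric is the Hamming distance between purview
  states. The cause-side EMD is solved exactly as a transportation problem
  (successive shortest augmenting paths, compiled code); the effect-side
  EMD uses the closed form for product distributions, the sum of per-node
  marginal differences — the tests verify that closed form against the
  exact solver.
- **Concepts and Φ.** A concept is retained when
  `min(φ_cause, φ_effect) > 0`. For every unidirectional bipartition of
  the system, connections from one part to the other are severed (their
  inputs noised), the constellation is rebuilt — over the mechanisms of
  the intact constellation plus all mechanisms straddling the cut — and Φ
  is the minimum over cuts of the extended EMD between the intact and cut
  constellations, in which each concept carries mass φ, may move to a
  concept of the other constellation at the cost of the summed
  cause/effect repertoire distance over the union purviews, or be created
  or destroyed against the null concept (the unconstrained repertoires of
  the empty mechanism).
- **Reachability.** Φ is computed only for states the dynamics can reach:
  a state is reachable when some previous state assigns every node's
  current value positive probability under the per-node factorisation.
  Unreachable states are reported as a distinct status, never as Φ = 0,
  and are excluded from all means. For empirically estimated stochastic
  TPMs reachability is relative to the estimate (an estimated zero counts
  as impossible); the flag is exposed rather than second-guessed.

### Numerical conventions

Repertoire distances and φ/Φ values are rounded at `1e-6` before
comparisons, matching the reference implementation's printed precision —
this is why the package reports, e.g., 1.916666 where six-decimal
reference output shows 1.916665; the difference sits at the rounding
boundary and the test tolerance (1e-4) covers it. Ties in purview
selection prefer the larger purview, then the earliest purview in
size-then-lexicographic order; the reference tooling is silent on ties and
this choice makes outputs deterministic. Two exact shortcuts are used: a
candidate partition whose product equals the whole repertoire contributes
φ = 0 without an EMD call, and a system cut that severs no
connectivity-matrix edges leaves the system bit-identical, so its
constellation distance is exactly 0 (this is what makes every feedforward
system, e.g. the 4-element noise configuration, reducible in
milliseconds). TPM rows are validated to sum to 1 within `1e-9`.

## The parameter sweep

`run_sweep()` covers the study grid — `tau` from 1 to 8 `dt`, weights from
0 to 100 mV in steps of 12.5 mV, 200 steps per restart, Φ for all 8 states
per cell — and returns a tibble with one row per `(tau, w, state)`. Cells
are independent and failures are recorded per cell without aborting.
`mean_across_states()` averages only over states with a defined Φ.
Reproducing the full grid takes a few minutes on one CPU; the test suite
asserts the structural findings on representative sub-grids (the `tau = 1`
constancy across weights 50–87.5 mV per state, zero Φ at weights 12.5 and
25 mV, mostly nonzero Φ in the 37.5–87.5 mV working range) so that the
default test run stays fast.

## Noise experiments

The stochastic input is a homogeneous Poisson process approximated as
independent per-step Bernoulli draws with `p = 1/mean_interval` — at most
one spike per step, which is the resolution at which network states exist,
so finer event timing would be unobservable after coarse-graining. Each
noise spike delivers 50 mV by default, a full gate-strength input
(sufficient on its own to drive the OR neuron past threshold); the weight
is a parameter for sensitivity checks.

Two analyses are provided. `phi_internal_noise()` treats the train as
intrinsic to the OR neuron: an additive term in its input sum, a 3-element
network, a `3×3` CM, and a now genuinely stochastic TPM (estimated over
1000-step restarts). `phi_external_noise()` treats the train as a fourth
network element with a feedforward connection onto OR and no incoming
edges; this system is reducible — the cut severing the (non-existent)
edges back into the source changes nothing — so Φ = 0 for every state,
independent of seed and parameters. `relative_change()` reports
`100·(Φ_noise − Φ_base)/Φ_base` with the sentinel `"x"` where the baseline
is zero, and `mean_phi_vs_interval()` summarises mean Φ (±SEM across
defined cells) as a function of the mean spike interval, with `Inf` as the
noise-free point. Extremal relative changes (on the order of hundreds of
percent) are seed-dependent and should be read qualitatively; the package
fixes seeds end-to-end so any particular table is bit-reproducible.

## What the synthetic conditions do and do not show

Every input in this package is generated: the gate presets, the sweep
grid, the Poisson trains. Passing tests therefore demonstrate internal
consistency with the published reference surface (the gate-system Φ table,
the structural zero-Φ regimes, the noise limits), not fidelity to
biological neurons: there are no conductances, refractory periods,
synaptic kinetics or plasticity, the XOR firing window is a deliberate
abstraction, and only the full-system Φ is computed — no search over
sub-complexes, spatial or temporal coarse-grainings. Cost grows as
`O(4^n)` states times super-exponential partition counts, so the engine is
practical for the 3–5 node systems it targets.

## Worked example

```{r example}
net <- gate_network(w = 50, tau = 1)
model <- empirical_tpm(net, steps_per_run = 8)
glance(big_phi(model, "100"))
tidy(big_phi(model, "100"))
```
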