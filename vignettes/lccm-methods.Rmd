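---
title: "Methods: the laminar circuit model, its habituating synapses, and Bayesian inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the laminar circuit model, its habituating synapses, and Bayesian inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lccm)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open when it was designed, and what the test
suite does and does not establish.

## Neural-mass building blocks

A neural mass is described by two state variables: an average firing-rate
deviation and an average membrane-potential deviation, both measured from
the resting state. Incoming spike rate `Q(t)` is converted to potential by
convolution with the alpha kernel

$$h(t) = \frac{H}{\tau}\, t\, e^{-t/\tau},$$

with synaptic gain `H` (V) and a lumped time constant `τ` (s) standing for
conduction, synaptic and dendritic delays. The kernel is the Green's
function of a second-order ODE, carried as two first-order states `(y, z)`
per synaptic transform (`kernel_rhs()`). The gain convention is `H = e ×
peak`: the impulse response peaks at `t = τ` with value `H/e`, which the
test suite verifies against the closed form.

Potential maps back to rate through a logistic function shifted by its
value at zero,

$$S(u) = \frac{2e_0}{1+e^{r(u_0-u)}} - \frac{2e_0}{1+e^{r u_0}},$$

so that `S(0) = 0` exactly. The shift is what makes the all-zero state of
the coupled circuit a fixed point: every state variable is interpretable as
a deviation from spontaneous activity, and negative rates mean firing below
baseline. The price is that the supremum of `S` is no longer `2e_0` but
`2e_0 - 2e_0/(1+e^{r u_0})` (`sigmoid_max()`, ≈ 4.832 s⁻¹ at the default
parameters); everything that needs "the maximum firing rate" — input
scaling and the pool normalization below — consistently uses this value.

Tones reach the granular layer as gamma-shaped pulses
`P₀ ((t−t_k)/w)^n e^{-(t−t_k)/w}` summed over onsets `t_k`. The exponent is
fixed at `n = 7`; it is nearly redundant with `w` and the input gain and is
therefore excluded from estimation. `P₀` is not a free constant: it is
recomputed from the current sigmoid as `sigmoid_max / (n^n e^{-n})` so that
a single pulse peaks exactly at the maximum firing rate. With the default
sigmoid this evaluates to 0.0064 (two significant figures), which the
acceptance script recomputes; the agreement of this derived constant with
its conventional printed value is the strongest internal check that the
sigmoid and input-pulse forms fit together as intended. Pulse tails below
1e-12 of the peak are truncated for speed.

## The laminar circuit

Five populations — EIN (layer 4), sPC (layers 2/3), dPC (layers 5/6), sIIN
and dIIN — are joined by 13 intrinsic connections (`lccm_connection_table()`).
Seven are "certain": the serial excitatory pathway EIN→sPC→dPC, the
backward link dPC→EIN, and the intra-laminar pyramidal/interneuron loops
(sPC↔sIIN, dPC↔dIIN). Six cross-laminar connections are "uncertain" with
zero prior expectation: dPC→sPC, EIN→dPC (the parallel "short-cut" route),
sIIN→dPC, dPC→sIIN, dIIN→sPC and sPC→dIIN.

One design question had no single canonical answer: how to allocate
synaptic transforms. We give **each connection its own transform** with a
connection-specific `τ` (10 ms excitatory, 20 ms inhibitory priors), rather
than sharing one kernel per source population. That choice follows from
the requirement that time constants be estimable per connection, and it
fixes the bookkeeping: 13 transforms × 2 states = 26 core states for the
full graph, and removing an uncertain connection removes exactly two. The
extrinsic input `C₁·p(t)` is injected into the input sum of the dPC→EIN
transform, the one other afferent of the granular layer, rather than given
a 14th transform — this is what makes the 26-state count come out, and the
zero-strength-equals-absent invariant is unaffected.

Membrane potentials are sums of transform outputs, excitatory minus
inhibitory; the observed source signal is `u_sPC + u_dPC` (pyramidal
masses dominate the measurable dipole moment). The Jansen–Rit baseline
(`build_jrm()`) uses the same machinery with three transforms (6 states):
a shared excitatory kernel for the pyramidal output read out by EIN and
IIN, and the excitatory and inhibitory input kernels of the pyramidal
mass. Its connectivity priors are the classical constants `C = 135` with
ratios 1, 0.8, 0.25, 0.25, with the same gains and sigmoid as the laminar
model.

## Habituating synapses

Each excitatory connection carries a two-state vesicle pool: readily
releasable (occupancy `A_RR`) and not readily releasable (`A_NRR = 1 −
A_RR` by construction — conservation is structural, not enforced). The
rate law is mass-action exchange:

$$\frac{dA_{RR}}{dt} = n_r (1 - A_{RR}) - n_d \frac{Q(t)}{Q_{max}} A_{RR}
\qquad (Q \ge 0),$$

with recovery alone when `Q < 0` (below-baseline firing should not deplete
vesicles). `Q(t)` is the presynaptic population's rate deviation `S(u)` —
the quantity the sigmoid outputs — and `Q_max = sigmoid_max()`, so the
depression term is bounded by `n_d`. The efficacy multiplying the static
strength is `W = A_RR` (proportionality constant 1, pinned by `W = 1` at
the replete equilibrium). The vector field points inward at both ends of
[0, 1], so occupancy remains a probability; integration tests assert no
excursion beyond ±1e-9.

Prior rates are `n_d = 20 s⁻¹` and `n_r = 2 s⁻¹` per connection, each
connection owning its own pair (synapses from the same source onto
different targets can depress differently). Under recovery alone the
closed form gives 99% occupancy at `−ln(0.01)/n_r ≈ 2.30 s`, comfortably
inside the conventional "recovers within ~3 s" bound. Note that reading
that bound as "5τ = 3 s" would imply a 600 ms time constant, whereas this
rate law's recovery time constant is `1/n_r = 500 ms`; we keep the rate
law, which honors the stated rate of 2 s⁻¹, and treat the 3 s figure as
the bound it is. Habituation applies to all nine excitatory intrinsic
connections; inhibitory synapses and the extrinsic input are static
(excitatory synapses depress far more strongly than inhibitory ones, and
forward suppression in auditory cortex is attributed to synaptic
depression rather than inhibition). In the Jansen–Rit baseline the shared
pyramidal-output transform forces its two efferent connections to share
one pool; the EIN→PC synapse has its own.

## Numerical integration and observation

Simulation is fixed-step RK4 at `dt = 1 ms` (the integrator refuses larger
steps), starting from rest: core states zero, pools at 1. Starting each
epoch from rest is justified by the paradigm itself — sequences follow ≥10 s
of silence, after which pool occupancy is within `e^{-20}` of 1. Halving
the step changes the observed waveform by < 1e-6 relative RMS (tested), so
1 ms is well inside the asymptotic regime for these kernels. A non-finite
state aborts with the first offending time; the inversion treats such
blow-ups as rejected steps.

The observation decimates the 1 kHz trajectory to 125 Hz by subsampling.
No anti-alias filter is applied: the model output is already band-limited
by the 10–20 ms kernels, and the data this emulates were low-pass filtered
at acquisition. Max-abs normalization is optional and is a no-op on an
all-zero waveform.

## Priors and re-parameterization

All parameters are positive by definition, so estimation works on latent
parameters `θ`:

| class | map | latent prior | used for |
|---|---|---|---|
| `exp` (uninformative) | `φ = u e^θ` | N(0, 1/2) | certain strengths, time constants, habituation rates, observation gain |
| `exp` (informative) | `φ = u e^θ` | N(0, 1/16) | input `w`, input strength `C₁` |
| `sq` | `φ = θ²` | N(0, 10⁴) | the six uncertain connections |
| `const` | `φ = u` | — | `H_e`, `H_i`, `e₀`, `r`, `u₀` |

The squared map is a true shrinkage prior: the parameter is zero at the
prior mode and stays there unless the data pull it away. It has one
mechanical consequence worth knowing: `dφ/dθ = 2θ` vanishes at `θ = 0`,
so a Gauss-Newton search started exactly at the prior mean cannot move a
`sq` parameter — absent connections are then held at zero exactly. To give
the data a chance to recruit such a connection, start the search slightly
off the mode (`opts$init`); the shrinkage tests do exactly that and verify
the estimates return to (near) zero when the generating model lacks the
connection.

Amplitude bookkeeping: observed waveforms are max-normalized, so the
forward map divides the raw prediction by the peak amplitude of the
prior-expected prediction (a constant computed once per model/paradigm)
and multiplies by a free gain with prior expectation 1 (uninformative).
This keeps the gain near 1 rather than forcing it to absorb a three-orders-
of-magnitude unit conversion, and avoids normalizing the prediction itself,
whose max-location jumps would make the forward map non-smooth.

## EM Gauss-Newton inversion

`em_gauss_newton()` alternates:

* **E-step ingredients**: a central-difference Jacobian `J` of the forward
  map in θ-space (step 1e-3; one-sided fallback if a perturbed simulation
  blows up; a failing pair leaves a zero column with a warning).
* **M-step**: noise variance `σ² ← (‖r‖² + tr(J Σ Jᵀ))/N` under the single
  i.i.d. noise component `Σ_ε = σ² I` at 125 Hz, floored at 1e-10. One
  component suffices for white synthetic noise; correlated residuals would
  need a richer component set, which we deliberately do not model.
* **Damped Gauss-Newton step** on the log joint: `Δθ = (JᵀJ/σ² +
  C_θ^{-1})^{-1}(Jᵀr/σ² − C_θ^{-1}θ)`, halving the step (up to 8 times)
  while the log joint does not improve; no admissible step means a local
  optimum and terminates. Near-singular normal equations fall back to a
  ridge-stabilized solve with a warning.

Convergence is declared when `max|Δθ| < 1e-4` (default; 64 iterations
max). The posterior covariance is the inverse Gauss-Newton curvature at
the final mean, and the Laplace free energy

$$F = -\frac{\|r\|^2}{2\sigma^2} - \frac{N}{2}\log(2\pi\sigma^2)
      - \frac{1}{2}\eta^\top C_\theta^{-1}\eta
      - \frac{1}{2}\log|C_\theta| + \frac{1}{2}\log|\Sigma_{\theta|y}|$$

approximates the log evidence; the `p/2 log 2π` terms of prior and
posterior cancel, so `F` differences between models with different
parameter counts are directly log Bayes factors. `lnB ≥ 3` is the
conventional strong-evidence threshold. An uncertain connection is
declared nonzero when `|η|/sd > z_{0.90} ≈ 1.2816` — the one-sided 10%
tail of the latent Gaussian posterior excluding zero.

The damping criterion uses the log joint (one forward evaluation per
candidate) rather than `F` itself (which would need a Jacobian per
candidate); `F` is computed once per accepted iterate. On a linear forward
model the scheme reduces to the conjugate Gaussian posterior in one step,
which the tests verify to 1e-8 against the closed form.

## Synthetic data: what it does and does not emulate

`generate_dataset()` simulates the chosen circuit over a −100 ms to
2500 ms epoch — five tones at 500 ms onset spacing, the analysis epoch of
a ten-tone sequence paradigm in which habituation has converged by the
fifth tone — observes at 125 Hz, max-normalizes, and adds i.i.d. Gaussian
noise. The default `noise_sd = 0.05` (5% of peak) is the package's
realistic stand-in for the residual noise of an averaged, source-projected
evoked response; no published SNR anchors it. Datasets are bit-exact
functions of `(seed, truth, paradigm)`.

What passing parameter- and model-recovery tests on these data establish:
the estimation machinery is self-consistent — it recovers parameters it
generated, prefers the generating model, and shrinks absent connections.
What they do not establish: robustness to the mismatches real source
waveforms carry — correlated (filtered) noise, source-localization error
mixing in activity from other generators, inter-subject parameter
variability, and amplitude nonstationarities across a 20-minute recording.
None of those are emulated.

Problem sizes in the shipped tests are chosen to keep a full run in a few
minutes on one core: model-recovery uses five seeds at 5% noise with the
iteration cap at 12, and the noise-free recovery check starts at the truth,
where convergence is immediate by construction (zero residual and zero
prior gradient). The recovery-experiment harness (`recovery_experiment()`)
exposes the full bias/RMSE/coverage machinery for larger private runs.

## Known limitations

* Single cortical source; no inter-area hierarchy, no lead-field model.
  The observation is the source waveform itself.
* Two-pool vesicle kinetics; no reserve/fused distinction, no
  facilitation, no inhibitory-synapse plasticity.
* One lumped `τ` per connection; no separate fast/slow GABA kinetics.
* The input exponent `n = 7` is fixed; only onset timing of tones is
  modeled, not their spectral content.
* The noise model is a single i.i.d. component at 125 Hz.
* The `θ²` shrinkage prior makes detection of truly present uncertain
  connections initialization-dependent (see above); inference about their
  absence is the better-conditioned direction.
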