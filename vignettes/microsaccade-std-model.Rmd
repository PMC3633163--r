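---
title: "A feedforward LGN-V1 model of microsaccade-evoked responses under short-term depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A feedforward LGN-V1 model of microsaccade-evoked responses under short-term depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccstd)
```

## The model

During steady fixation a stationary image fades from perception; involuntary
microsaccades counteract that fading. This package implements a minimal
synaptic account of the phenomenon: short-term depression (STD) in the
thalamocortical pathway silences the cortical response to an unchanging
stimulus, and a microsaccade restores it by displacing the stimulus onto
less-depressed synapses.

Two one-dimensional layers of $N$ neurons each represent LGN and V1.
Receptive-field centres $x_j$ are spaced uniformly on $[-L, L]$, treated as a
ring of circumference $2L$ (all distances use the periodic metric
$d(a,b) = \min(|a-b|,\, 2L - |a-b|)$, applied to both kernels so the network
is translation invariant). A fixated dot at position $x_f$ with brightness
$A$ drives each LGN neuron $j$ as an independent Poisson process with
time-independent rate

$$R_j = A \exp\!\big(-d(x_j, x_f)^2 / \sigma_1^2\big),$$

and LGN neuron $j$ projects to every V1 neuron $i$ with weight
$W_{ij} = \exp\!\big(-d(x_j, x_i)^2/\sigma_2^2\big)$. Each V1 membrane obeys
a conductance-pulse integrate-and-fire equation,

$$\tau_m \frac{dV_i}{dt} = V_0 - V_i +
  \sum_j g\, W_{ij}\, S_j(t)\, (V_E - V_i)\, \delta(t - t^j_{sp}),$$

with threshold $V_{th}$, reset $V_{reset}$, and the synaptic strength
$S_j \in (0, 1]$ governed by STD: each presynaptic spike depletes
$S_j \to f S_j$, and between spikes $S_j$ recovers as
$dS_j/dt = (1 - S_j)/\tau_S$. A microsaccade is a displacement of $x_f$ by
$\Delta_M$ — instantaneous by default, or a constant-velocity ramp over a
fixed 15 ms in the velocity analyses.

### Parameters

| symbol | argument | default | meaning |
|---|---|---|---|
| $N$ | `N` | 1000 | neurons per layer |
| $L$ | `L` | 10 | half-width of the position range (position units) |
| $g$ | `g` | 0.15 | maximal synaptic conductance (0.2 in the strong-response condition) |
| $A$ | `A` | 50 | peak LGN rate, spikes/s (100 in the strong-response condition) |
| $\sigma_1, \sigma_2$ | `sigma1`, `sigma2` | 1.5 | input / weight tuning widths |
| $f$ | `f` | 0.75 | fraction of synaptic resource left per spike |
| $\tau_S$ | `tau_S` | 200 ms | depression recovery time constant |
| $\tau_m$ | `tau_m` | 30 ms | membrane time constant |
| $V_0, V_E$ | `V0`, `VE` | −70, 0 mV | resting / excitatory reversal potential |
| $V_{th}, V_{reset}$ | `V_th`, `V_reset` | −55, −58 mV | threshold / reset |
| `dt` | `dt` | 0.1 ms | integration step |
| $T$ | `T_bin` | 50 ms | response bin width |

The membrane and STD constants follow the standard depressing-thalamocortical
parameterisation; the high reset (−58 mV, close to threshold) matters, since
responding neurons re-approach threshold quickly.

### Steady states of the depression variable

Under sustained drive at rate $R$ the pre-spike strength of a periodically
driven synapse converges to the exact fixed point
$S^\ast = (1 - e^{-\Delta/\tau_S}) / (1 - f e^{-\Delta/\tau_S})$ with
$\Delta = 1/R$ (`std_steady_state_periodic()`), whose high-rate limit is the
familiar approximation $S^{ss} = 1/(f + (1-f) R \tau_S)$
(`std_steady_state_highrate()`). At $R = 50$ spikes/s, $f = 0.75$,
$\tau_S = 200$ ms these give 0.2961 and 0.3077. Note that the *time average*
of $S$ under Poisson drive is a different quantity: because depletion is
linear in $S$ and Poisson arrivals sample the stationary distribution, the
exact stationary mean is $1/(1 + (1-f) R \tau_S)$ = 0.2857 at the same rate
— about 7% below the high-rate formula. The package treats the periodic
fixed point as the exact reference and the high-rate formula as the
approximation it is; tests assert each quantity against its own closed form.

## Simulation conventions

Several details are not pinned down by the model equations; the package
fixes them as follows.

* **Delta-pulse convention.** The spike term is integrated across the spike
  as a jump $\Delta V = (g W_{ij} S_j / \tau_m)(V_E - V)$, evaluated at the
  pre-jump $V$ — dimensionally consistent with the membrane equation as
  written, and contracting toward $V_E$ so the membrane can never cross the
  reversal potential. The alternative without $1/\tau_m$ makes the adapted
  state fire continuously and is rejected.
* **Pre-depletion delivery.** The conductance delivered by a spike uses the
  synaptic strength *before* that spike's depletion: the transmitter being
  released is what causes the current event, and the resource is diminished
  immediately after. This is the canonical convention for multiplicative
  depressing synapses.
* **Step ordering.** Per step of length `dt`: evaluate the protocol; draw
  LGN spikes as independent Bernoulli($R_j\,dt$) events; apply the exact
  leak decay; deliver all jumps; deplete fired synapses; apply the exact
  exponential recovery over `dt`; detect threshold crossings and reset. All
  inputs of a step are delivered before threshold detection. V1 spike times
  are stamped at the end of the step; LGN spike times at its start, which
  makes the event-driven closed-form STD evolution
  (`std_evolve_train()`) reproduce the stepped $S_j$ trajectory exactly —
  this is the oracle used by the test suite.
* **Initial conditions and warm-up.** Runs start at $V_i = V_0$, $S_j = 1$
  (start of fixation, fully recovered synapses), which produces the large
  fixation-onset response. Experiments that probe the adapted state first
  run 2 s of stationary stimulation (the core of the profile adapts with an
  effective time constant $1/(1/\tau_S + (1-f)R) \approx 57$ ms at 50
  spikes/s; the weakly driven flanks take a few hundred ms) and exclude it
  from analysis.
* **Randomness.** LGN spiking uses exact per-neuron Bernoulli thinning,
  implemented with geometric skipping under the bound $p^* = A\,dt$ so RNG
  cost scales with the expected spike count rather than $N$. One user seed
  determines both the saccade-train stream and the spiking stream through
  fixed sub-seed derivation, so enabling state recording never perturbs a
  run. `dt = 0.1` ms keeps $R\,dt \le 0.005$; halving `dt` changes response
  peaks by well under 10% (tested).

## The adapted state is marginal

With the reference parameters ($g = 0.15$, $A = 50$,
$\sigma_1 = \sigma_2 = 1.5$) the adapted membrane sits only about 1.5 mV
below threshold, so the Poisson input fluctuations produce *sparse residual
firing* (tens of spikes per second across the whole population, i.e. of
order $10^{-2}$ spikes per neuron per 50 ms bin — zero for almost every
neuron in any single bin, but not exactly zero for the population). This
marginality is what makes the model work: because the adapted drive ends up
just below rheobase, a microsaccade-evoked response decays back slowly and
visual fading takes a few hundred milliseconds rather than a few tens. A
strictly silent adapted state can be produced by delivering the
post-depletion strength $f S_j$ (equivalently $g \to f g$), but that variant
pushes the adapted state ~3 mV below threshold and collapses the fading
time to ~50 ms; the package therefore keeps the canonical pre-depletion
convention and documents the residual firing as a property of the regime.

## Measurements

The response measure is the moving-bin population count $N_{sp}$: V1 spikes
in a sliding 50 ms window, evaluated every 1 ms (the window *start* indexes
the bin; with 50 ms steps the bins tile the run and conserve the total
count). Derived quantities:

* `response_peak()` — maximum $N_{sp}$ within 200 ms after an event; 200 ms
  brackets the transient without reaching the next event of a 4 Hz train.
  Peaks are raw maxima, with no baseline subtraction.
* `fading_time()` — time from the event until the first completely empty
  50 ms window after the post-event peak; degenerate cases are flagged
  (`no_activity`, `never_fades`).
* `average_activity()` — mean $N_{sp}$ after discarding the first 500 ms
  (the fixation-onset transient), and `sensitivity_curve()` — its
  finite-difference slope along a parameter grid (central differences,
  one-sided at the edges).
* `flash_interval_analysis()` reports the network-averaged synaptic
  strength $\langle S_j \rangle$ as the unweighted mean over all $N$
  synapses at the saccade time, from the sampled state trace.

## Protocols

`stationary_protocol()` and `flashing_protocol()` define the brightness
time course (flashing starts with an on-phase at $t = 0$; `T_off = 0`
degenerates to stationary). Saccade trains are `single_saccade()`,
`periodic_saccades()`, and `poisson_saccades()` (homogeneous Poisson,
truncated, no minimum interval — overlap is avoided in the experiments by
using a modest 1.5 Hz rate rather than imposing refractoriness).
Direction policy defaults to a uniform random $\pm 1$ per event: the
protocols are silent on whether real microsaccade sequences return to a
home position, and on the ring the population response is
direction-invariant, so the fixation point random-walks (with wrap) by
default; fixed and alternating policies are available. In flashing
experiments the saccade train runs through off-phases too; events during an
off-phase displace $x_f$ but evoke nothing. Finite-velocity mode ramps
$x_f$ linearly over 15 ms (the canonical human microsaccade duration), so a
velocity $v$ corresponds to $\Delta_M = 15 v$.

Boundary cases: the two kernel branches coincide at exactly $d = L$, so the
choice of branch there is immaterial; $x_f$ is wrapped into $[-L, L)$ after
every displacement, so trains cannot walk off the grid. The grid includes
both endpoints $-L$ and $+L$; they are the same ring point, so ring sums
(e.g. total input rate) are taken over distinct points.

## What the experiments compute

* **Single-saccade fading** (`run_experiment("fading")`): 2 s adaptation,
  one $\Delta_M = 2$ saccade; onset peak, saccade peak, fading time.
* **Frequency sweep** (`frequency_sweep()`): average activity and its slope
  versus Poisson saccade rate, 0.5–8 Hz.
* **Flashing vs stationary** (`flashing_vs_stationary()`,
  `flash_interval_analysis()`, `flash_onset_peak()`, `phase_diagram()`):
  paired saccade trains under flashing and stationary stimuli; the
  dependence of the evoked peak and $\langle S_j \rangle$ on the interval
  since flash onset; onset peaks versus `T_off`; and the
  $T_{on} \times T_{off}$ plane.
* **Magnitude/velocity saturation** (`magnitude_sweep()`,
  `velocity_sweep()`, defaults $g = 0.2$, $A = 100$): post-saccade peak
  versus $\Delta_M$ and versus velocity at fixed 15 ms duration.

Problem sizes in the test suite are the package's choices for routine
verification: single-saccade statistics use 20 seeds of 3.5 s runs; the
frequency sweep 20 seeds × 30 s per frequency; the flashing comparison
20 seeds × 100 s per condition; reduced versions of each sweep (a few grid
points, 2–3 seeds) check the qualitative shapes.

## What the synthetic protocols do and do not emulate

The generator reproduces the study conditions: Gaussian-tuned Poisson input
from a single fixated dot, stationary or square-wave flashing brightness,
and instantaneous or fixed-duration microsaccades at periodic or Poisson
times. It does not emulate drift or tremor as distinct stochastic
processes, two-dimensional retinotopy, multiple stimuli, orientation
tuning, corticocortical or inhibitory connections, retinal adaptation, or
trial-to-trial rate nonstationarity in real LGN. Passing tests therefore
demonstrate the internal consistency of this model class, not fidelity to
recorded cortical data.

## Known limitations

* The adapted state is marginal rather than strictly silent (above); tests
  that demand literal zero population counts in the adapted state fail by a
  handful of fluctuation-driven spikes.
* The measured mean fading time at the reference parameters is ≈ 170 ms
  (20 seeds), within the expected 150–450 ms band but below its nominal
  ~300 ms centre; the fading tail is governed by the slowly equilibrating
  flank synapses and by lulls in the residual background, so it is
  sensitive to the exact near-threshold margin.
* The average-activity curve versus saccade frequency is close to linear
  with mildly decreasing slope: each saccade contributes a roughly fixed
  burst, and bursts overlap only above ~6 Hz at the measured fading time.
  Its finite-difference slope therefore has no interior maximum in the
  0.5–8 Hz range under the mean-count measure.
* The high-rate steady-state formula is a property of periodic drive; it
  overestimates the Poisson-drive time average by ~7% at 50 spikes/s (see
  above), which is inherent to the formula, not a simulation error.
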