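---
title: "Models and methods behind snncrit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snncrit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snncrit)
```

`snncrit` simulates a small recurrent spiking network whose activity is
driven purely by intrinsic noise, and analyzes that activity with three
bespoke statistics: an avalanche-based criticality index, an
excitation–inhibition (EI) balance measure, and a population-decoding
estimate of fading stimulus memory. This vignette is the package's own
account of the model, the numerical choices, and what the tests do and do
not establish.

## The neuron model

Each of the `n_exc + n_inh` neurons follows conductance-based
leaky-integrate-and-fire dynamics for the subthreshold membrane potential,

$$\tau_m \frac{dv}{dt} = (v_{rest}-v)\,g_{rest} + (E_{exc}-v)\,g_{exc}
 + (E_{inh}-v)\,g_{inh},$$

with conductances normalized so that $g_{rest}=1$, and $g_{exc}, g_{inh}$
decaying exponentially with $\tau_{AMPA}$ and $\tau_{GABA}$ between
presynaptic events. There is no hard threshold: spiking is stochastic under
an *escape-noise* rule, where the probability of firing in one timestep is

$$P(\text{spike}) = \min\!\left(\frac{\Delta t}{\tau}\,
  e^{(v - v_{th})/b},\, 1\right),\qquad
\frac{\Delta t}{\tau} = f_{rest}\,\Delta t\, e^{(v_{th}-v_{rest})/b}.$$

The prefactor is calibrated so that a neuron sitting at rest fires at
exactly `f_rest` (0.4 Hz by default); with the default parameters
$\Delta t/\tau \approx 0.00594$ per 0.1-ms step, in the range measured for
layer-5 pyramidal neurons. This resting noise is the only drive the network
ever receives outside explicit stimulation: all synaptic weights start at 0
and every structure the network develops is self-organized.

On a spike, $v$ resets to $v_{rest}$ and the neuron is refractory for 3 ms
(excitatory) or 2 ms (inhibitory). Each spike consumes a fraction $U$ of a
presynaptic resource $x$ (Tsodyks–Markram short-term depression,
$x \leftarrow x - Ux$, recovery to 1 with $\tau_{rec}$), and delivers, after
a conduction delay of 1.5 ms (excitatory-to-excitatory) or 0.8 ms (all other
synapse classes), a conductance increment $U\,x\,w\,g_{max}$ to every
postsynaptic target.

### Defaults

All defaults live in `neuron_params()` / `stdp_params()`: potentials in mV
($v_{rest}=-74$, $v_{th}=-54$, $E_{exc}=0$, $E_{inh}=-80$), times in ms
($\Delta t = 0.1$, $\tau_m=30$, $\tau_{AMPA}=2$, $\tau_{GABA}=4$,
$\tau_{rec}=150$, $\tau_E=20$, $\tau_{I1}=10$, $\tau_{I2}=20$),
dimensionless $U=0.4$, $g_{max}=4$, $A_E=A_I=0.02$, and $f_{rest}=0.4$ Hz.
An empty configuration passed to `load_config()` reproduces this set
exactly.

## Plasticity

Long-term plasticity is spike-timing dependent, with the window selected by
the *presynaptic* unit's class. For an excitatory presynaptic neuron the
window is temporally asymmetric,

$$F_E(t) = \begin{cases} A_E e^{-t/\tau_E}, & t \ge 0\\
 -A_E \beta_E e^{t/\tau_E}, & t < 0,\end{cases}$$

with $t = t_{post}-t_{pre}$; for an inhibitory presynaptic neuron it is
symmetric,

$$F_I(t) = \frac{A_I}{1 - \frac{\tau_{I1}}{\tau_{I2}}\beta_I}
 \left(e^{-|t|/\tau_{I1}} -
 \frac{\tau_{I1}}{\tau_{I2}}\beta_I\, e^{-|t|/\tau_{I2}}\right),$$

valid when $\tau_{I1}/\tau_{I2} < \min(1/\beta_I, 1)$ (enforced at
construction). $\beta_E$ and $\beta_I$ set the depression/potentiation
balance; the shipped presets `crt` ($\beta_E=1, \beta_I=1.15$), `sub`
($1.2, 1.2$) and `sup` ($1, 1$) drive the developed network to the
critical, subcritical and supercritical regimes respectively.

Weight updates are *all-to-all*: a spike on either side of a synapse adds
the summed window value over **all** earlier spikes on the opposite side,
then clips the weight to $[0,1]$. The sums are realized exactly through
exponentially decaying per-neuron trace accumulators (one per window time
constant), which is algebraically identical to the explicit double sum —
the acceptance suite checks trace-vs-brute-force agreement to $10^{-9}$ on
100 random spike trains.

Choices where the design was genuinely open:

* **Coincident spikes.** Pairing is strict ("earlier than"), so two spikes
  in the same timestep do not interact; when simultaneous pre- and
  postsynaptic events are processed, the presynaptic update is applied
  first (relevant only when clipping binds). `stdp_window_e(0)` itself
  takes the $t \ge 0$ branch.
* **Timing basis.** Windows are evaluated at spike *emission* times, not
  delayed-delivery times.
* **Self-pairs.** Autapses carry no weight and no updates.

## The stepping engine

The compiled inner loop advances the state in fixed phases per
$\Delta t$-step: (0) scheduled stimulus pulses add their amplitude to $v$;
(1) delayed synaptic events due this step are delivered; (2) one forward
Euler step of the membrane equation (conductance/resource/trace decays use
their exact per-step exponential factors; refractory neurons hold
$v = v_{rest}$ while their conductances and resources keep evolving);
(3) one uniform draw per neuron decides spikes; (4) STDP updates, release
queueing (with the weight at emission time and $x$ before depletion),
resets and refractory timers. A stimulated neuron is not forced to fire —
the +30 mV pulse only raises the escape probability, and refractory neurons
ignore the draw entirely.

The per-step order is a convention, fixed and tested rather than derived:
the pure-R single-step operations (`step_subthreshold()`,
`fire_and_deliver()`, `apply_external_stimulus()`) implement the identical
rules and the suite cross-checks the compiled engine against them on
noiseless and forced-spike trajectories at $10^{-10}$ tolerance, and
against the closed-form exponential solutions as $\Delta t \to 0$.

Randomness is a single xoshiro256++ stream embedded in the network state
(checkpointable as 8 integer words), so checkpoint → restore → continue is
bit-identical to an uninterrupted run; evoked-response trials reseed a
cloned state per trial, as the measurement protocol prescribes.

## Protocols

The reference experiment (`run_experiment()`) is: develop the network from
zero weights under pure noise (reference: 72 h simulated; the test suite
uses minutes-long presets — wall-clock scaling is roughly 40 s per
simulated hour for 100 neurons); measure evoked responses (40 trials per
pattern, each preceded by a 10-s reseeded free run, plasticity frozen so
the probe does not itself consolidate memory); apply 4 disjoint 6-neuron
stimulus patterns 900 times each at 1 Hz in seeded random order; then let
the network run spontaneously for 12 h with 10-min monitoring windows every
hour (spikes, plus 2 s of synaptic-current recording; monitoring never
overlaps stimulation), and measure evoked responses again. Patterns are
disjoint across the four sets, mirroring spatially separated stimulation
electrodes.

## Avalanche criticality

All spikes are merged into one series; $\Delta t_{gap}$ is its mean
inter-spike interval, and an avalanche is a maximal run of spikes whose
internal gaps are all strictly smaller than $\Delta t_{gap}$ (recomputed
per analyzed window). Its size $s$ is its spike count. The empirical size
distribution $p_{emp}(s)$ is fit by least squares on the $\log_{10}$–
$\log_{10}$ plot over observed sizes in $[s_{min}, s_{max}]$, with
$s_{max} = 100$ (the population size) and deviations summed over the same
range:

$$A_{upper} = \sum \max(p_{emp}-p_{fit}, 0),\quad
 A_{lower} = \sum \min(p_{emp}-p_{fit}, 0),$$

and the criticality index $\Delta Cr$ is whichever of the two has larger
magnitude (ties to $A_{upper}$). Unlike the plain sum $\Delta p$, the index
cannot read a large but symmetric deviation as criticality.
$\Delta Cr < 0$ flags subcritical (e.g. exponential-tailed), $\approx 0$
critical (power-law), $> 0$ supercritical (excess large avalanches)
statistics. Sizes above $s_{max}$ count toward normalization but not the
fit or sums; unobserved sizes contribute nothing (the log-regression is
undefined there).

**Selection of $s_{min}$.** $s_{min}$ exists to drop small sizes that
deviate from the power law. Globally minimizing the fit residual over all
candidate $s_{min}$ turned out to be degenerate: on steep
exponential-tailed distributions every curve is locally linear near its
tail, so the global optimum escapes into a 3–5-point tail sliver carrying
almost no probability mass, which silently erases the subcritical signal
the index exists to measure (we measured $\Delta Cr$ collapsing from
$\sim-1$ to $-6\times10^{-4}$ on branching-process data with branching
ratio 0.5). `fit_power_law()` therefore advances $s_{min}$ greedily from
the smallest observed size, one size at a time, only while doing so
improves the per-point mean squared residual by at least a factor
`step_ratio` (default 1.5, in the spirit of parsimony rules like glmnet's
one-standard-error rule), stopping early when the fit is already exact. A
genuinely deviant head point collapses the residual by orders of magnitude
when dropped and is discarded; smooth curvature never clears the factor.
Base-10 logs throughout (any base gives the same slope; fixed for
reproducibility).

## EI balance

During monitoring, per-neuron excitatory and inhibitory synaptic currents
$(E_{exc}-v)g_{exc}$ and $(E_{inh}-v)g_{inh}$ are sampled every timestep
for 2 s. `ei_metrics()` computes, per neuron, the zero-lag Pearson
correlation between the excitatory trace and the sign-flipped inhibitory
trace (so balance reads as $cc \to 1$), averages over neurons with nonzero
variance in both traces, and reports the mean input magnitudes and their
ratio $I/E$. The estimator choice (zero-lag correlation, per-neuron then
averaged rather than pooled) reflects that balance is a statement about the
temporal coupling of the two inputs *to the same cell*. Degenerate inputs
(all-constant traces, zero excitation) yield flagged results rather than
NaN surprises.

## Fading memory

Evoked responses are reduced to firing-rate vectors per 20-ms half-open
latency bin (spike count / bin width, in Hz). The decoder is sparse
(L1-penalized) multinomial logistic regression via glmnet at a fixed
default regularization $\lambda = 0.01$, with features z-scored per unit on
each training fold. Accuracy uses 10-segment stratified *shuffle*
cross-validation — ten independent splits each holding out 10% per class,
which is not 10-fold CV (held-out sets may overlap between splits). The
decay time of fading memory scans bins from latency 0: per bin, the
leave-one-out correct count over all trials (classes pooled, $n = 160$ for
4×40 trials) is tested against the chance rate $1/4$ with a one-sided exact
binomial test, and the decay time is the start latency of the first bin
with $p \ge 0.05$ — no smoothing, no multiple-testing correction, exactly
one test per bin. Condition comparisons use a per-bin Friedman rank test
across conditions and a Wilcoxon signed-rank test on paired decay times.

In-vitro-style preprocessing (`preprocess_in_vitro()`) removes spikes
within 1 ms of each stimulus (electrical artifact) and drops electrodes
saturated by stimulation before any decoding, matching how
microelectrode-array recordings are cleaned.

## Synthetic ground truth

Every analysis stage has a generator whose answer is known in advance:

* `branching_process_spikes()` — Galton–Watson cascades with Poisson
  offspring (mean $\sigma$), per-generation cap at the population size, and
  an optional hard truncation `max_size` (required when $\sigma \ge 1$).
  Mean avalanche size is $1/(1-\sigma)$ without truncation. Spike times sit
  on an exact dyadic grid (intra-avalanche spacing $2^{-10}$ s ≈ 1 ms,
  inter-avalanche gaps 50× larger), so floating-point rounding cannot blur
  the strict-inequality segmentation and `detect_avalanches()` recovers the
  generated sizes exactly. Poisson offspring was chosen because it gives the
  standard critical-branching limit and an analytic progeny mean.
* `labeled_response_set()` — class-specific spatial rate patterns active in
  the first `signal_bins` bins over a base rate, Poisson counts; separation
  0 is exactly chance, large separation drives the Bayes error to 0, and the
  ground-truth decay time is `signal_bins × bin_width`.
* `correlated_current_pair()` — Gaussian mixtures with population
  correlation exactly `rho`, the oracle for the EI estimator.
* `mea_like_recording()` — injects artifact spikes within 1 ms of stimulus
  onset and flags saturated units, returning the clean ground truth
  alongside for round-trip testing.

These generators emulate the *statistics* each analysis consumes — not
real biology: branching trains have no refractoriness or delays, labeled
responses have no temporal correlations within a bin, and current pairs are
white. A green test therefore establishes that an analysis recovers known
structure from data of the assumed form, not that the simulator produces
such data; the end-to-end protocol test and the full-scale (cluster-scale)
experiment are what connect the two.

## Known limitations and full-scale expectations

The desk-scale suite deliberately stops short of the full experiment
(72-h development × 30 seeds × a $\beta_E \times \beta_I$ grid). At full
scale the critical preset is expected to reach EI cross-correlation above
0.75 and the subcritical preset below 0.5, with repetitive stimulation
transiently lowering $\Delta Cr$ and spontaneous activity restoring it
within hours; these runs are launchable through `run_experiment()` /
`snncrit_cli("full-experiment", ...)` with the reference durations but are
documented here rather than asserted in CI. The model itself omits NMDA and
GABA_B kinetics, cell-type diversity beyond one excitatory and one
inhibitory class, neuromodulation, and spatial geometry — by design, as the
minimal configuration in which noise plus dual STDP windows suffices for
self-organized criticality and memory consolidation.

Other numerical conventions worth knowing: the refractory comparison uses a
1-ns tolerance so period boundaries are not lost to rounding; stimulus
pulses scheduled at time $t$ take effect in the step whose draw immediately
follows $t$; delays are rounded to whole steps; checkpoints are plain JSON
(diffable, environment-independent) rather than a binary container.
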