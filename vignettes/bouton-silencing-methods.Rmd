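---
title: "Methods: single-bouton quantification and the synthetic ground-truth world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-bouton quantification and the synthetic ground-truth world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonsilence)
```

# Scope

`boutonsilence` quantifies presynaptic function bouton by bouton from
fluorescence recordings of three sensor modalities and reduces the
per-terminal measurements to the population relationships that
characterize calcium-dependent synaptic silencing. This vignette is the
package's account of the science it implements: the measurement model and
its assumptions, the tunable parameters, what the synthetic generator
does and does not emulate, and the numerical choices made where the
design was genuinely open. Every empirical statement here is computed by
the test suite or the acceptance script; nothing is asserted that the
code does not itself measure.

# The measurement model

## Sensor equilibrium and inversion

A calcium sensor with dissociation constant $K_d$, dynamic range
$R_f = F_{max}/F_{min}$ and Hill coefficient $n$ has equilibrium
fractional fluorescence

$$\frac{F}{F_{max}} = \frac{1}{R_f} +
  \Bigl(1 - \frac{1}{R_f}\Bigr)\frac{C^n}{C^n + K_d^n}.$$

`sensor_forward()` implements this map and `convert_to_calcium()` its
exact algebraic inverse. GCaMP6f defaults are $K_d = 0.38$ µM,
$R_f = 51.8$, $n = 2.3$ (in vitro constants). The inversion assumes
equilibrium binding within a frame and a per-terminal $F_{max}$ measured
by saturating the sensor (ionomycin). Two guards keep it total:
fluorescence at or below the zero-calcium floor $1/R_f$ (possible under
noise) maps to 0 µM with a `subfloor` flag, and fractional fluorescence
above 0.995 is flagged `saturated` with no value, because the inverse
diverges as $F/F_{max} \to 1$. The round-trip identity is enforced to a
relative error below $10^{-9}$ across $[10^{-3}, 10]$ µM.

## Per-terminal quantification

For each terminal and condition the chain computes:

* **baseline**: mean and sample SD (denominator $N-1$) of the 49 frames
  preceding the first stimulus frame. The estimator choice is ours; the
  measurement convention only fixes the 49-frame window.
* **peak ΔF**: mean of the modality-specific peak window minus baseline —
  the 5 frames ending at AP-train offset for the calcium and pHluorin
  sensors, 3 frames starting at the AP for the glutamate sensor.
* **silent call**: silent iff $\Delta F < \sigma_{baseline}$, strictly.
  Equality counts as responding (the stated rule is "less than"). On pure
  Gaussian noise this classifier calls ~1.9 % of terminals responding
  ($P(t_{48} \ge 1/\sqrt{1/5 + 1/49})$, the estimated-$\sigma$ version of
  the normal-approximation 1.7 %); this floor is verified against a
  brute-force Monte-Carlo oracle and matters when interpreting silent
  fractions near 100 %.
* **F_max**: the maximal 5-consecutive-frame mean inside the calibration
  window — a plateau estimate robust to a slowly rising calibration
  epoch (for a monotone rise it is the last 5 frames).
* **normalization**: vGpH responses are divided by the NH₄Cl-revealed
  pool $F_{max} - F_{baseline}$; iGluSnFR responses (averaged over the 15
  single-AP trials first) by $F_{max}$ itself; GCaMP responses are
  converted to absolute influx in nM.

Frames are 0-based and frame $i$ spans $[i/f_r, (i+1)/f_r)$; traces are
sampled at frame centers. Trial alignment uses the protocol's stimulus
frame — the synthetic data are jitter-free by construction, so no
sub-frame registration is attempted.

## ROI handling

Movies are reduced to traces by difference-of-Gaussians detection
(default scales 1 and 3 px) on the mean baseline image, greedy local
maxima acceptance in descending intensity with a 4 px minimum separation,
fixed-radius (3 px) circular ROIs with center-in-circle pixel membership,
and one same-radius background ROI per terminal found by searching 8
angles at increasing radial offsets for the nearest position overlapping
nothing. The published workflow placed ROIs "semi-automatically"; the
deterministic detector replaces the manual step, and a user-supplied ROI
table (CSV) can override it. The automatic detection threshold is
`median(DoG) + 8 * mad(DoG)`, robust to the sparse bright spots.

## Population reduction

`summarize_condition()` computes per-neuron silent fractions and
responder means (non-silent, non-saturated, non-subfloor terminals only),
then across-neuron mean, SEM ($SD/\sqrt{n}$, sample SD) and CoV
(SD/mean of silent fractions; the denominator convention is ours).
`fit_linear_intercept()` is ordinary least squares on per-neuron points
with $x_0 = -b/m$; a non-positive slope still reports an intercept but
carries a warning flag. `fit_hill_silencing()` minimizes the sum of
squares of $S(\Delta) = 100\,K_d^c/(K_d^c + \Delta^c)$ — maximum pinned
at 100 % for zero influx — over $(\log K_d, \log c)$ from a deterministic
16-point start grid ($K_d \in \{5,15,45,135\}$ nM × $c \in
\{0.5,1,2,4\}$); the best final SSE wins and ties break toward the
smaller $K_d$. The decreasing branch is reported with the conventional
negative exponent $-c$. Optional weights (e.g. $1/SEM^2$) are supported;
the default is unweighted, matching fits on per-neuron means.

# The synthetic world

The generator renders the statistical structure the analysis assumes, as
a fixed "stated world":

| parameter | default | why |
|---|---|---|
| neurons × terminals | 9 × 200 | typical recording scale (~200 boutons per field) |
| [Ca²⁺]ₑ conditions | 2.0, 1.2, 0.8, 0.4 mM | the experimental ladder around the set point |
| influx intercept | 0.47 mM | the extrapolated cessation of Ca²⁺ entry |
| influx slope | 39.2 nM/mM | gives ~60 nM at 2.0 mM, mid-range of the silencing curve |
| sub-intercept residual | 5.9 nM | see below |
| silencing $K_d$, $c$ | 25 nM, 1.79 | the fitted population curve |
| resting [Ca²⁺]ᵢ | 0.05 µM | typical neuronal resting level (not stated by the source data; configurable) |
| F_max | lognormal, mean 2000 counts, CV 0.2 | expression variability |
| noise | read SD 2 counts + Gaussian shot term, variance 0.01/count | EMCCD-like counts |
| rendering | PSF σ 1.5 px, ≥4 px separation, offset 100, 16-bit | camera geometry |

**Silencing coupling.** One uniform draw $u$ per terminal is reused at
every condition; the terminal is silent where $u < p(\Delta)$ with
$p(\Delta) = K_d^c/(K_d^c + \Delta^c)$. Because $p$ rises as influx
falls, a terminal silent at one [Ca²⁺]ₑ is silent at every lower one —
the within-terminal monotonicity the all-or-none phenotype implies. A
hard-threshold mode (silent iff $\Delta < K_{d,sil}$) is provided because
the underlying mechanism — a threshold for Ca²⁺ entry — could be
deterministic; probabilistic is the default since per-terminal thresholds
are unobserved.

**The residual-influx default (5.9 nM).** Below the 0.47 mM intercept a
non-silenced terminal still admits a small residual influx. The headline
population estimate at 0.4 mM (~1.6 nM) averages over *all* terminals,
93 % of which are silent and contribute ~0; it is therefore not the
responder-level parameter the generator needs. We instead require
self-consistency with the stated silencing curve: 5.9 nM is the unique
influx at which $p(\Delta)$ equals the observed 93 % silencing at
0.4 mM, and the emergent population-mean influx (~0.4 nM) remains
"almost no measurable residual entry". Setting the residual to 1.6 nM
would instead imply 99.3 % silencing, contradicting the observed value
and colliding with the classifier's ~1.9 % noise floor.

**Kinetics.** The evoked transient follows a first-order (τ_rise)
saturating approach to the train plateau and a single-exponential decay
(τ_decay) after train offset; defaults are GCaMP-like (50 ms / 0.5 s),
pHluorin pool turnover (2.5 s / 15 s) and a fast glutamate transient
(2 ms / 50 ms). These are free parameters — the source measurements
constrain amplitudes, not kinetics. A strictly linear rise reaching the
plateau exactly at train offset was considered and rejected: it would
leave the end-of-train 5-frame peak mean ~5 % below the plateau,
incompatible with the required <1 % noiseless recovery of influx; the
saturating rise recovers the plateau to numerical precision while keeping
the same qualitative shape.

**Perturbations.** A fractional influx reduction (default emulation of
GABA_B agonism: 0.4) multiplies every terminal's influx by
$(1-\text{perturbation})$ *before* the silencing draw, so paired
pre/post comparisons under a shared seed isolate the effect of influx on
silencing.

**What the generator does not emulate** — and hence what a green test
does *not* establish: no inter-neuron heterogeneity of influx or
silencing propensity (all terminals of a neuron share one true influx per
condition, so across-neuron CoV of silent fractions is binomial-small,
~5–18 %, far below the 38–57 % seen in real populations); no axon-branch
structure in the silencing pattern; no bleaching, focus drift, motion, or
3-D optics; no vesicle-pool depletion beyond the step-plus-decay pHluorin
response; Gaussian approximations of Poisson photon statistics. Tests
passing on this world validate the measurement chain, not the biology.

# Numerical and I/O choices

* Saturation guard at $F/F_{max} = 0.995$; disable by passing a guard
  ≥ 1 (the round-trip property test does).
* The Hill fit optimizes log-parameters with `nlminb` at tight tolerance
  (`rel.tol = 1e-14`), recovering noiseless parameters to relative error
  below $10^{-6}$.
* Movies are plain uncompressed little-endian 16-bit multi-page TIFFs;
  the codec is implemented in-package (no TIFF library is assumed) and is
  validated against an externally produced reference file frozen into the
  test suite.
* Reports and manifests are canonical JSON: recursively sorted keys,
  numbers at 9 significant digits. Run manifests deliberately contain no
  wall-clock timestamps so that repeating any stage with the same config
  and seed is bit-identical end to end; provenance is carried by config
  hashes and input/output digests instead.
* One global seed spawns per-neuron child streams (prefix-stable), so
  enlarging `n_neurons` leaves earlier neurons' data unchanged.
* Hypothesis tests (t, ANOVA, post-hoc) are out of scope by design; the
  package emits the per-neuron summary tables such tests consume.

# Known limitations

* The background-ROI geometry ("adjacent, non-synaptic") is
  underdetermined in the published workflow; the ring-search rule here is
  one deterministic realization of it.
* Ensemble influx can be reduced terminal-then-average (default) or from
  the mean trace; both are available, and they differ in principle under
  sensor nonlinearity.
* σ_baseline is recomputed per condition; whether the original analysis
  shared it within a session is unstated.
* At silent fractions near 100 % the classifier's ~1.9 % noise floor
  biases measured fractions downward; the acceptance suite quantifies
  this regime explicitly.

```{r example}
cfg  <- generator_config(n_neurons = 3, n_terminals_per_neuron = 60,
                         ca_e_conditions = c(2.0, 1.2, 0.8), seed = 1)
summ <- summarize_condition(measure_dataset(generate_dataset(cfg)))
summ$per_condition[, .(condition_mM, silent_fraction_mean,
                       responder_mean_delta_ca)]
```
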