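# boutonsilence

Quantification of presynaptic function at single nerve terminals from
time-lapse fluorescence imaging, and population analysis of
calcium-dependent synaptic silencing.

## The problem

Hippocampal neurons in culture, sparsely expressing a presynaptically
targeted sensor, are stimulated with brief action-potential (AP) trains
while the external calcium concentration [Ca²⁺]ₑ is varied around the
physiologic set point of 1.2 mM. Each bouton appears as a punctate spot;
its fluorescence trace reports either Ca²⁺ influx (synaptophysin-targeted
GCaMP6f), vesicle exocytosis (vGLUT1-pHluorin, "vGpH") or glutamate
release (iGluSnFR). Two phenomena make single-terminal resolution
essential:

* Ca²⁺ influx is **sub-proportional** to [Ca²⁺]ₑ below ~2 mM: linear
  extrapolation of mean influx versus [Ca²⁺]ₑ crosses zero near 0.47 mM.
* Modest reductions of influx (low [Ca²⁺]ₑ, partial channel block, GABA_B
  agonism) **silence terminals in an all-or-none fashion** rather than
  scaling every terminal down.

This package implements the full measurement chain for those experiments,
plus a ground-truth synthetic-data generator so that every stage can be
validated without any experimental download.

## Models

**Fluorescence → calcium.** GCaMP fluorescence is normalized to the
ionomycin-saturated level F_max per terminal and inverted through the
equilibrium Hill curve

    [Ca²⁺]ᵢ = K_d · ((F/F_max − 1/R_f) / (1 − F/F_max))^(1/n)

with in vitro constants K_d = 0.38 µM, R_f = 51.8, n = 2.3. The evoked
influx Δ[Ca²⁺]ᵢ (nM) is the difference of the converted peak and baseline.

**Silent classification.** A terminal is *silent* when its peak ΔF
(mean of 5 frames at the end of the AP train; 3 frames from the AP for
iGluSnFR) is strictly less than the SD of its 49 baseline frames.

**Population dose-response.** Per-neuron silent fractions and responder
means feed (i) an OLS line of influx vs [Ca²⁺]ₑ with x-intercept
extrapolation, (ii) pairwise silencing slopes (% · mM⁻¹), and (iii) a
least-squares Hill fit of silent % versus influx with the maximum
constrained to 100 % at zero influx,

    S(Δ) = 100 · K_d^c / (K_d^c + Δ^c)

reported with the conventional negative exponent −c for the decreasing
branch.

## Worked example

Simulate the default synthetic world (9 neurons × 200 terminals ×
{2.0, 1.2, 0.8, 0.4} mM [Ca²⁺]ₑ), quantify every terminal, and summarize:

```r
library(boutonsilence)
cfg  <- generator_config(seed = 1)
ds   <- generate_dataset(cfg)
meas <- measure_dataset(ds)
summ <- summarize_condition(meas)
summ$per_condition[, .(condition_mM, silent_fraction_mean,
                       silent_fraction_sem, responder_mean_delta_ca)]
#>    condition_mM silent_fraction_mean silent_fraction_sem responder_mean_delta_ca
#> 1:          2.0                0.163             0.00961                    59.8
#> 2:          1.2                0.429             0.01094                    28.1
#> 3:          0.8                0.750             0.01027                    12.4
#> 4:          0.4                0.913             0.00645                     5.3
```

Silencing increases steeply as [Ca²⁺]ₑ falls below the set point (16 % →
91 % silent), while responder influx tracks the external concentration.
The population fits recover the generating relationships:

```r
pn <- summ$per_neuron
fit_hill_silencing(pn$responder_mean_delta_ca, 100 * pn$silent_fraction)
#> <hill_fit> Kd = 23.5 nM, n = 1.69 (reported -1.69), r2 = 0.9880

fit_linear_intercept(pn[condition_mM >= 0.8]$condition_mM,
                     pn[condition_mM >= 0.8]$responder_mean_delta_ca)
#> <linear_fit> slope = 39.58 nM/mM, x-intercept = 0.4888 mM, r2 = 0.9996
```

The Hill parameters (true K_d 25 nM, c 1.79) and the influx x-intercept
(true 0.47 mM) are recovered from noisy single-terminal measurements; the
small biases are classifier- and noise-limited and are themselves checked
by the test suite.

## Command-line pipeline

```sh
inst/cli/boutonsilence all --config my_config.json --out runs/demo --seed 1
# or stage by stage:
inst/cli/boutonsilence simulate --config C.json --out d1
inst/cli/boutonsilence quantify --in d1 --config C.json --out d2
inst/cli/boutonsilence analyze  --in d2 --config C.json --out d3
```

Configs are strict JSON (unknown keys rejected); every stage writes its
resolved config and a manifest of input/output digests, and repeated runs
with the same config and seed are bit-identical.

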