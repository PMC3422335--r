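---
title: "Methods: circadian period estimation for oxygen-evolution rhythms"
author: "oxyclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian period estimation for oxygen-evolution rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyclock)
```

## The scientific problem

Photosynthetic oxygen evolution in the dinoflagellate *Symbiodinium* —
free-living in culture or in hospite in a symbiotic coral — oscillates with
a roughly daily rhythm. Under a 12:12 light:dark (LD) cycle the oscillation
is entrained to ~24 h; under subsequent constant light (LL) it *free-runs*
at an endogenous period τ that depends on light intensity and spectrum. A
rhythm counts as circadian when τ falls in the 19–28 h criterion band.
The measurement chain is: optode (optical oxygen sensor) traces logged
every 5 min in replicate flasks or coral fragments (N = 4), a medium-only
blank channel to remove probe/medium drift, Fourier transformation of each
light-phase segment, and extraction of the dominant circadian frequency,
summarised as mean ± SD over replicates. A companion qPCR experiment
follows diel expression of putative photoreceptor genes (two cryptochromes
and a phytochrome) by the 2^−ΔΔCT^ method.

Raw traces for such experiments are rarely deposited, so the package pairs
every analysis stage with a synthetic-data generator whose ground truth is
known exactly. All tests and the acceptance analysis run on generated data;
the generator's defaults encode the published study conditions.

## The oscillator model behind the generator

Each replicate trace is

$$ y(t) = M + \beta t + A(t)\cos\varphi(t) + \varepsilon_t,
   \qquad \varepsilon_t \sim \mathcal N(0, \sigma^2)\ \text{i.i.d.}, $$

with mesor $M$, instrument drift slope $\beta$, and a phase $\varphi(t)$
that advances at $2\pi/\tau_{LD}$ during LD (anchored so the daily maximum
falls mid-light-window) and at $2\pi/\tau_{rep}$ during LL, continuously
across the switch — the free run starts from the entrained phase, with no
phase jump. The replicate's free-running period is drawn once per
replicate, $\tau_{rep} \sim \mathcal N(\tau, s_\tau)$: the published
replicate SDs exceed what estimator noise alone produces at this
signal-to-noise ratio, so between-replicate variability must live in the
period itself. Amplitude is damped geometrically,
$A(t) = A_0\, d^{\,n_{LL}(t)}$ with $n_{LL}(t)$ the number of completed
free-running cycles since the switch to constant light, emulating the
observed fading of the oxygen rhythm after the first LL day.

The carrier is a smooth cosine, not a square-wave gating of photosynthesis:
the analysis targets the fundamental period and the published traces show
continuous oscillation. A gating option (`gate_dark = TRUE`, oscillation
suppressed to the mesor during dark intervals) exists for sensitivity
checks and is off by default.

Defaults (instrument units are arbitrary): mesor 100, amplitude 30, noise
SD 3, drift 0.05 h⁻¹, damping 0.85 per cycle, blank mesor 90. The source
study reports no amplitude or noise magnitudes for its optode traces, so
these are declared choices — an SNR of 10 is typical of a healthy optode
channel — not values inferred from data. The eleven packaged scenarios
(`scenario_table()`) carry the published entrained and free-running
periods and replicate SDs as their ground truth.

What the generator does *not* emulate: mechanistic photosynthesis
(electron transport, P–I curves), spectral structure of the LED fields,
non-Gaussian sensor artifacts, or transient re-entrainment dynamics.
Passing tests therefore demonstrate that the analysis recovers known
parameters under the stated noise model, not that it is robust to every
pathology of real optode data.

### Regime durations

The default regime is 72 h of 12:12 LD followed by 96 h of LL. Four
free-running cycles match the published constant-light traces. For the
entrained segment, three forced cycles is the *minimum* well-posed record
for a windowed periodogram: with only two cycles the circadian peak of the
Hann-tapered spectrum overlaps the DC and negative-frequency window lobes
and the period estimate is biased by hours. Experiments that only need the
free run can shorten the LD phase via `get_scenario(id, ld_duration_h =)`.

## Preprocessing

* **Blank correction** subtracts the medium-only channel pointwise. Grids
  must align within half the median sampling interval; interpolation of
  the blank onto the sample grid is available but explicit
  (`interpolate = TRUE`), never silent.
* **Detrending** is linear by default: the blank removes shared drift, the
  line removes what remains, and the periodogram of a short record is
  otherwise dominated by low-frequency leakage. Period estimates are
  invariant (to < 1e-6 h) under adding any constant or line to the input.
* **Segmentation** maps each regime phase (LD block, LL block) to its time
  window; entrained and free-running periods are estimated segment-wise,
  matching how such results are reported. `skip_transition_h` can drop the
  transient after a mode switch; the default is 0 because the source
  analysis states no exclusion rule, and the headline estimates should use
  the full segments.
* **Gaps**: dropouts of ≤ 3 sampling intervals are linearly interpolated;
  longer gaps split the trace (`fill_gaps()`), since the FFT needs a
  uniform grid and inventing hours of signal would bias the spectrum.

## Period estimation

`estimate_period()` composes: linear detrend → Hann taper → zero-padding
to 16× the record length → FFT power spectrum → maximal-power bin with
period in the 19–28 h band → quadratic interpolation through the
log-power of the peak bin and its two neighbours.

The two non-obvious choices are the padding and the interpolation, and
they are load-bearing. A 96 h record has a raw frequency resolution of
1/96 cyc h⁻¹: inside the circadian band that grid offers only the 24.0 h
and 19.2 h periods, so free-running periods of 22.7, 23.5, 24.0 and
25.3 h are literally indistinguishable on the bare DFT grid. Zero-padding
interpolates the spectrum onto a 16×-finer grid (≈ 0.37 h at 24 h) and
the parabolic fit through log-power localises the peak to ≲ 0.01 h for
noiseless records — the test suite pins both the success of the refined
estimator (≤ 0.05 h) and the documented failure of the unrefined one.
The Hann taper controls leakage on 3–4-cycle records. The 19–28 h band is
the circadian criterion range; it also excludes the 12 h harmonic of LD
forcing by construction.

Numerical conventions: power is normalised so that, unpadded and
untapered, total power equals the sum of squared values (Parseval); ties
between equal-power bins resolve to the longer period; a peak on the band
edge is returned flagged (`edge_flag`), never silently; interpolation is
skipped at edges or when a neighbour's power is zero. An estimate whose
cosinor fit at the estimated period explains < 20% of the detrended
variance is flagged `low_power_flag` — white-noise records trip this
floor essentially always, while any rhythm near SNR 3 clears it by a wide
margin, including after amplitude damping.

Uncertainty is reported across replicates only (`replicate_summary()`,
sample SD with n − 1), matching the mean ± SD, N = 4 reporting
convention; no per-trace confidence intervals are constructed.

### The independent least-squares oracle

`lsq_period_scan()` is a brute-force cosinor grid search: at every trial
period (grid ≤ 0.05 h) fit mesor + cosine + sine by least squares and
take the period with minimal residual sum of squares. It shares no code
or numerical choices with the spectral path — no FFT, padding, taper or
interpolation — so the two estimators cross-validate each other.

One subtlety: on a *noisy* record every estimator carries sampling error,
and that error depends on how the estimator weights the record in time.
A Hann-tapered spectral estimate and a uniform-weight cosinor respond to
the same noise realisation differently (each with ~0.06 h RMSE at
SNR 3 on four cycles), so their difference conflates machinery with noise
response. When the scan serves as the oracle for the spectral machinery,
it is therefore run with the matching Hann weights
(`window = "hann"`, a weighted least squares); the two paths then agree
to ≤ 0.02 h on noisy traces, and any residual disagreement isolates
genuine implementation error. The uniform-weight scan remains the default
for stand-alone use.

## qPCR relative expression

`ddct()` implements relative quantification: ΔCt = Ct(target) − Ct(reference)
per sample, ΔΔCt against a calibrator sample, RQ = base^−ΔΔCt. The base
defaults to 2 (the canonical 2^−ΔΔCT^ form) with the measured assay
efficiency (E = 1.9, from the dilution-curve identity E = 10^−1/slope^)
available as an option; the source study names both without stating which
entered its final figures, so both are exposed and logged. Replicate
reactions are averaged on the Ct scale before ΔCt for the headline RQ
(the two orders of averaging differ under noise; the choice is
documented), and a per-replicate mode feeds the group statistics.

The calibrator defaults to the pre-dawn (06:30) LD sample of the same
spectrum — the earliest sample, taken 90 min before lights-on — because
the study names no calibrator; the choice is configurable and recorded in
the output. One consequence worth knowing: with per-spectrum calibrators,
both spectra have RQ = 1 at the calibrator time point by construction, so
blue-vs-red fold comparisons are statements about the light-phase time
points. The packaged design encodes equal pre-dawn baselines with a
2.5-fold light-induced blue/red difference for the CRY genes.

Reference-gene selection (`select_hkg()`) ranks candidates by the SD (or
CV) of their Ct across all samples — a stable housekeeping gene has
constant Ct — with exact ties broken lexicographically and flagged. In
the packaged design Cyclophilin carries the smallest Ct noise and wins in
≥ 95% of seeded simulations.

## Comparison statistics

`paired_t_test()`, `one_way_anova()` and `tukey_hsd()` are closed-form
implementations validated against independent references in the test
suite (hand-computed sums of squares, `t.test`, `aov`/`TukeyHSD`), and
calibrated under the null: the ANOVA type-I error at α = 0.05 is
0.05 ± 0.01 over 10,000 simulations (n = 4, k = 3) and the Tukey
familywise error stays ≤ 0.06. Tukey uses the studentized-range
distribution with the Tukey–Kramer standard error, so unequal group sizes
are handled even though the packaged designs are balanced. With two
groups it reduces exactly to the pooled t-test (q = √2·|t|).

Significance groups are summarised by the insert-and-absorb compact
letter display; by construction two groups share a letter if and only if
their pairwise comparison is non-significant, a property the test suite
asserts on randomly generated instances. Letters are assigned in
descending order of group means — presentation only.

Degenerate inputs are explicit errors, with one documented exception: a
paired t-test on identical vectors returns t = 0, p = 1 (no evidence of a
difference), while constant non-zero differences — zero variance with a
non-zero mean — are an error, since the statistic is undefined.

## Problem sizes and determinism

Every stochastic test and script draws from a single root seed through
`derive_seed()`, a deterministic hash onto per-stream child seeds, so any
individual trace can be regenerated without replaying the whole
experiment and identical calls are byte-identical. The packaged analyses
use the study's own sizes — N = 4 replicate traces per scenario at 5-min
sampling, triplicate qPCR reactions — and the property suites use 100
traces for estimator cross-validation, 200 draws for null letter
behaviour, and 10,000 simulations for type-I calibration.

## Known limitations

* The free-running period is modelled as constant within a replicate; no
  aftereffects or drift of τ across LL cycles.
* Period uncertainty is between-replicate only; a single trace yields a
  point estimate.
* No irregular-sampling spectral methods (Lomb–Scargle) or wavelet
  decomposition: traces are regularised or split instead.
* The qPCR chain starts at Ct values; no amplification-curve processing
  or standard-curve fitting from raw fluorescence.
* Published period values enter only as generator ground truth; original
  raw traces are not available, so exact numeric agreement with the
  original instrument records cannot be checked, only parameter recovery
  under the declared noise model.
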