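---
title: "Scoring evoked potentials and estimating rotational injury thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring evoked potentials and estimating rotational injury thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergthresh)
```

## The problem

Rapid coaxial rotation of the eye transmits mechanical stress to the
optic nerve and can produce traumatic optic neuropathy: a functional
deficit that is reversible (neuropraxia) at moderate doses and
irreversible above some injury threshold. Two questions drive the
analysis this package implements:

1. **Scoring** — given averaged flash electroretinogram (ERG) and flash
   visual evoked potential (fVEP) recordings, extract the standard
   clinical endpoints: a-wave, b-wave, oscillatory potentials (OPs) and
   their sum (SOP), photopic negative response (PhNR), steady-state
   flicker amplitude, and the fVEP N1–P1 amplitude/latency metrics.
2. **Threshold estimation** — given per-animal dose–response records
   (rotation amplitude $\Theta$ in degrees, peak angular velocity
   $\Phi$ in degrees/s, and a baseline-normalised change $\Delta y$ in
   an endpoint), estimate the injury thresholds
   $(\Theta_0, \Phi_0)$ with a piecewise linear threshold model.

## The threshold model

The dose–response mean is a two-dimensional hinge:

$$
\Delta y =
\begin{cases}
0 & \Theta < \Theta_0,\ \Phi < \Phi_0\\
c_1(\Theta-\Theta_0) & \Theta \ge \Theta_0,\ \Phi < \Phi_0\\
c_2(\Phi-\Phi_0) & \Theta < \Theta_0,\ \Phi \ge \Phi_0\\
c_1(\Theta-\Theta_0) + c_2(\Phi-\Phi_0) & \Theta \ge \Theta_0,\ \Phi \ge \Phi_0
\end{cases}
$$

equivalently $E[\Delta y] = c_1(\Theta-\Theta_0)_+ +
c_2(\Phi-\Phi_0)_+$. The boundary $\Theta = \Theta_0$ is assigned to
the supra-threshold branch; the excess there is zero, so the choice is
observationally null but fixed for determinism (`eq1_mean()`).

For a *postulated* threshold pair the model is linear in $(c_1, c_2)$,
so estimation proceeds by grid search: threshold pairs are postulated
on a grid ($0 \le \Theta_0 \le 45$ degrees, $0 \le \Phi_0 \le 3500$
degrees/s by default; steps 0.5 degrees and 25 degrees/s — the grid
resolution is a package choice, made fine enough that discretisation
is negligible against sampling noise), each cell is fitted by ordinary
least squares on the two hinge regressors **without intercept** (the
sub-threshold mean is pinned at zero by the model, which is also why
the null model for the F test is $\Delta y \equiv 0$, not a fitted
constant; an intercept-null variant would test a different, weaker
hypothesis), and significance is obtained by inverting the F
distribution:

$$
F = \frac{(RSS_0 - RSS_1)/q}{RSS_1/(n-q)},\qquad RSS_0 = \sum \Delta y_i^2 ,
$$

with $q$ the number of retained hinge columns. `grid_scan()`
vectorises all cells through the normal-equation cross-products and
agrees cell-for-cell with the reference `fit_cell()` (property-tested).

### Degenerate cells and collinearity

* A hinge column with no supra-threshold observations is dropped; if
  both are empty the cell reports $p = 1$.
* When the dose design couples velocity to amplitude almost
  proportionally, the two hinge columns are nearly collinear. Above a
  correlation of 0.99 (configurable) the fit collapses onto the
  amplitude hinge and the cell is flagged `identifiable = FALSE` —
  consistent with reporting single per-degree effects. A
  determinant guard catches numerically singular two-hinge systems the
  correlation screen misses.
* Cells without a residual degree of freedom report $p = 1$ and are
  flagged unsupported.

### Threshold selection

The decision rule returns the *lowest* pair (scaled order
$\Theta_0/45 + \Phi_0/3500$, ties to the smaller $\Theta_0$; the
scaling makes "lowest" well defined across incommensurate axes) among
cells that are

1. significant against the null of no change ($p \le \alpha$, with
   $\alpha \in \{0.05, 0.01, 0.001\}$ by default),
2. adequately supported (at least `support_min = 3` supra-threshold
   observations — the minimum leaving a residual degree of freedom
   plus replication), and
3. **adequate as a model**: not significantly worse-fitting than the
   best cell on the grid (an F comparison of the cell's RSS against
   the grid minimum with 2 numerator degrees of freedom for the two
   postulated thresholds, at the same $\alpha$).

Condition 3 deserves a comment because the design here was genuinely
open. A bare "lowest significant pair" rule degenerates whenever the
dose–response signal is strong: even a grossly misplaced threshold
pair then fits well enough to reject the null of *no* change, so the
rule would always walk to the grid origin. What "yielding a
statistically significant change *adequately supported by the data*"
has to mean, for the procedure to estimate anything, is that the cell
is also a *credible* location for the kink — which is exactly the
grid-search change-point confidence-region construction used in
segmented regression. With noise-free data condition 3 reduces the
eligible set to the exact-fit cells; with noisy data it is the
$1-\alpha$ confidence basin. `adequacy = FALSE` restores the bare
rule.

`estimate_thresholds()` is the companion *point estimator*: the
argmin-$p$ cell. Minimising $p$ rather than raw RSS keeps one- and
two-hinge cells comparable (a two-hinge corner cell can always shave
RSS by overfitting; it pays for the extra parameter in the F test).

### Multiplicity

Grid-wide selection without correction inflates the family-wise
type-I rate; this mirrors the original procedure and is reported
as-is. A Bonferroni-across-grid mode is available
(`bonferroni = TRUE`) and restores control (both behaviours are
measured in the acceptance suite). Reports record which mode produced
a selection.

### Supra-threshold variance

`variance_change_test()` compares response variability below and
above the selected thresholds: a one-sided variance-ratio F test by
default, or a median-centred (Brown–Forsythe-style) robust variant.
The one-sided alternative is `Var(supra) > Var(sub)` — increased
variability above threshold is itself an injury signature.

## Waveform scoring conventions

All measurements are referenced to a **baseline**: the mean voltage
over the 20 ms immediately preceding flash onset (the pre-stimulus
window length is a package convention; the source conventions never
define "baseline"). The pre-stimulus residual SD also sets the
**detection floor**: a peak or trough must clear
$3\times$ that SD to count as a feature, so noise wiggles cannot
define an endpoint on a flat trace (`floor_k` is configurable).

* **a-wave** — first local minimum after onset that falls below
  baseline by more than the floor; amplitude is baseline-to-trough.
  A qualifying trough must also dominate its $\pm 5$ ms
  neighbourhood: on a noisy descending limb every wiggle is a local
  minimum, and "first" is only meaningful among neighbourhood-dominant
  troughs.
* **b-wave** — global maximum after the a-trough; amplitude from the
  a-trough voltage. If no a-wave was found the b-wave is measured
  from baseline and flagged, keeping the pipeline total.
* **OPs** — the trace is band-pass filtered (zero-phase FFT filter,
  75–300 Hz with raised-cosine transitions; the band is the
  conventional OP band, and zero phase preserves peak times), then
  peak-picked. Each OP amplitude is a peak minus the deepest trough
  since the previous retained peak; peaks at or after the b-wave peak
  are discarded ("only OPs prior to the b-wave peak"), wavelets
  smaller than 5 % of the largest are treated as residual filter
  ripple, and at most four wavelets are labelled OP1-2, OP3, OP4, OP5
  in temporal order (the hyphenated first label reflects the fused
  first oscillation). If more than four qualify, the four largest are
  kept — genuine OPs always dominate residual ripple.
* **SOP** — arithmetic sum of the labelled OP amplitudes, with an
  annotation when labels are missing.
* **PhNR** — minimum after the b-wave peak, amplitude from baseline;
  if the trough stays above baseline the magnitude is reported with an
  `above_baseline` flag (the source conventions do not say which was
  used in that situation; the flag keeps both representable).
* **Flicker** — mean trough-to-following-peak excursion across
  complete 20 Hz cycles, with one dominant extremum per half-cycle.
* **fVEP** — N1 is the first prominent post-onset trough, P1 the
  first prominent peak after N1; the endpoints are the N1→P1 voltage
  difference and time difference, peak times referenced to flash
  onset.
* **Times** — reported at the parabolically refined extremum
  (3-point interpolation); amplitudes are read at the discrete
  extremum sample, so planted values round-trip at sample resolution.
* **Normalisation** — `normalize_change()` defaults to the raw
  difference (post − pre), which keeps voltage units and matches
  slopes quoted in mV/degree; a relative mode
  ((post − pre)/|pre|) is exposed because "normalized against
  baseline" admits either reading. Reports name the mode.

## The synthetic-data generator

The generator is first-class, tested code: it is the only source of
ground truth for the scoring and estimation machinery.

**Waveforms.** Each sweep is a deterministic component sum plus i.i.d.
Gaussian noise. Slow components (a, b, PhNR, N1, P1) are smooth
$\cos^4$ lobes with compact support; widths are derived from the
inter-component gaps so supports never collide at the planted peaks,
and the $\cos^4$ edge smoothness keeps the slow lobes' spectra from
leaking into the OP band. The OP train is a half-cosine interpolation
through alternating trough/peak control points spaced $1/(2f)$ at
`op_freq` (default 150 Hz), confined to the b-wave's ascending limb.
Because the scoring convention measures OPs on the *filtered* trace,
the train's control extrema are calibrated by a deterministic fixed
point so that the band-passed composite reproduces the planted
trough-to-peak amplitudes exactly — the templates exist precisely so
that the measurement rules have known answers. Defaults: 2000 Hz
sampling (resolving 100–150 Hz OPs comfortably), 300 ms ERG / 500 ms
fVEP sweeps, 20 ms pre-stimulus window, ERG amplitudes in µV and fVEP
in mV, times in ms from flash onset, 64 sweeps, noise SD 5 µV. Every
generator call takes a mandatory seed and is bit-reproducible;
control sweeps use an offset seed so signal and control noise are
uncorrelated.

What the generator does **not** emulate: 60-cycle interference,
electrode drift and artifact epochs, biophysical retina dynamics
(templates are phenomenological), or quality-control exclusions. A
green round-trip test therefore establishes that the scoring rules
measure what they claim on well-formed traces — not that the package
is robust to every pathology of real recordings. One geometric
limitation is inherent rather than a defect: an a-wave faster than
about 17 ms implicit time has genuine spectral content inside the
75–300 Hz OP band, and its filtered remnant contaminates the first
OPs; the same is true of real recordings.

**Dose–response tables.** `generate_dose_response()` draws
$\Delta y$ = hinge mean + Gaussian($0,\sigma$) over a design.
Gaussian residuals are an assumption (no distributional statement was
available); the generator is the single place to change it.
`pilot_design()` reconstructs the 27-animal pilot layout — negative
controls (n = 3, no rotation), saccade-level positive controls
(n = 3, 10 degrees at 500 degrees/s), and low/medium/high dose groups
(n = 4/8/10) spanning 12–47 degrees — with velocity coupled to
amplitude at a nominal 72 degrees/s per degree (the ratio implied by
the 20.5 degree / 1475 degrees-per-second pair) and a deterministic
±12 % per-animal spread. The spread matters: under *exact*
proportionality the kink is representable on either dose axis, the
p-surface develops a ridge, and $\Theta_0$ is unidentifiable; real
actuator runs scatter. `crossed_design()` varies the two doses
independently and is used wherever both thresholds must be
identifiable.

**Noise calibration.** `calibrate_sigma()` sets $\sigma$ so that the
truth cell's F statistic, evaluated with the true coefficients and
the true residual variance, sits at a chosen upper-tail probability:
$\sigma^2 = \sum_i \mu_i^2 / (q F^*)$ with
$P(F_{q,n-q} > F^*)$ equal to the target. This states a simulation's
signal strength in terms of the evidence the truth carries rather
than in raw units.

**SNR convention.** Where tests quote "SNR 10" for a component, the
ratio is *planted component amplitude / per-sweep noise SD*, with the
acquisition protocol's 64-sweep averaging applied before scoring —
the single-trial SNR is the quantity the averaging protocol is
designed to overcome.

## Known limitations

* **Localisation at moderate evidence.** With $\sigma$ calibrated so
  the truth cell carries $p \approx 10^{-4}$ of evidence, the mean
  response 2.5 degrees past the kink is only $|c_1| \cdot 2.5 \approx
  0.17\sigma$ per observation — far below what is needed to localise
  $\Theta_0$ to ±2.5 degrees with 27 animals, for any design. The
  acceptance suite asserts the stated 80 % recovery target anyway and
  that test fails honestly; the accompanying property test verifies
  what *is* true, namely that recovery improves monotonically as
  $\sigma$ shrinks and is essentially certain at $\sigma/16$.
* **Velocity threshold identifiability.** In proportional designs
  $\Phi_0$ is reported but is an artefact of the dose coupling, not an
  independent estimate; the `identifiable` flag marks this.
* **Family-wise error.** Uncorrected grid-wide selection inflates
  type-I error (measured, not hidden); use the Bonferroni mode when a
  controlled family-wise rate matters.
* **Latency units.** Latency changes are treated in ms throughout;
  a printed latency slope in mV/degree in the source material is
  recorded as an ambiguity, and the reader accepts either labelling.

## Reproducibility

Every stochastic element — sweep noise, dose noise, pipeline runs —
flows from explicit integer seeds. `run_pipeline()` logs the seed, a
config hash and the package version, and identical config + seed
yields byte-identical data files and reports, which the test suite
asserts.
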