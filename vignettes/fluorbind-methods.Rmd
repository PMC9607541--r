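---
title: "Models and methods behind fluorbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluorbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorbind)
```

fluorbind characterizes the interaction between a small molecule and serum
albumin from fluorescence titration data, and quantifies how that molecule
inhibits non-enzymatic protein glycation. This vignette documents the models,
the parameters that matter, the numerical choices, and what the synthetic
generators do and do not emulate. The running example throughout the package
is a flavonoid-class ligand binding bovine serum albumin (BSA), whose
intrinsic tryptophan/tyrosine fluorescence near 340 nm is quenched as ligand
is titrated in.

## The quenching and binding models

**Stern–Volmer analysis.** Quenching of the protein's intrinsic fluorescence
follows

$$\frac{F_0}{F} = 1 + K_q \tau_0 [Q] = 1 + K_{sv}[Q],$$

where $F_0$ and $F$ are peak intensities without and with quencher at
concentration $[Q]$ (mol/L), $K_{sv}$ (L/mol) is the Stern–Volmer constant
and $K_q = K_{sv}/\tau_0$ (L mol$^{-1}$ s$^{-1}$) the bimolecular quenching
rate constant, with $\tau_0 \approx 10^{-8}$ s the unquenched lifetime of
protein fluorophores. `fit_stern_volmer()` estimates $K_{sv}$ by unweighted
ordinary least squares of $F_0/F$ on $[Q]$ *with* a free intercept: a fitted
intercept outside $[0.9, 1.1]$ is a diagnostic for baseline or inner-filter
artifacts and triggers a warning rather than silently forcing the line
through 1. A non-positive slope is reported with a "no quenching" flag, not
an error, so screening workflows can proceed.

**Mechanism classification.** `classify_quenching_mechanism()` combines the
two textbook criteria. Static quenching (ground-state complex formation)
weakens with temperature, so $K_{sv}$ must strictly decrease across the
measured temperatures, *and* the apparent $K_q$ must exceed the
diffusion-collision ceiling of $2.0\times10^{10}$ L mol$^{-1}$ s$^{-1}$ —
a collisional process cannot be faster than diffusion. Dynamic quenching
requires the strict opposites. Any mixed signature is reported as
`indeterminate` with both criteria shown; we prefer an honest
"indeterminate" over a forced binary call because real systems with
combined static/dynamic character produce exactly such mixed signatures.
The ceiling is configurable (`kq_ceiling`); with a single temperature only
the $K_q$ criterion applies and the call is flagged.

**Double-logarithmic binding fit.** Under static quenching the bound/free
balance gives

$$\lg\frac{F_0 - F}{F} = \lg K_a + n \lg [Q],$$

with $K_a$ (L/mol) the association constant and $n$ the binding-site
number. "lg" is log base 10 — the standard in this literature, and the only
reading under which the intercept has the magnitude of published constants.
`fit_double_log()` excludes points with $F \ge F_0$ (no binding signal on
the log scale; they arise from noise at weak quenching), counts the
exclusions, and requires three usable points. The standard error of $K_a$
comes from the intercept SE by the delta method,
$\mathrm{se}(K_a) = \ln(10)\,K_a\,\mathrm{se}(\text{intercept})$.

A note on units: publications in this field often print both $K_{sv}$ and
$K_a$ with the unit "mol/L". Dimensional consistency of $K_{sv}[Q]$ requires
L/mol, and fluorbind labels both constants L/mol throughout.

## van't Hoff thermodynamics

With association constants at two or more temperatures,

$$\ln K_a = -\frac{\Delta H}{RT} + \frac{\Delta S}{R}, \qquad
  \Delta G = \Delta H - T\Delta S,$$

with $R = 8.314$ J mol$^{-1}$ K$^{-1}$. `fit_vant_hoff()` solves exactly
with two points (standard errors are then undefined and reported `NA`) and
switches to OLS of $\ln K_a$ on $1/T$ with three or more. The enthalpy is
assumed temperature-independent over the narrow experimental range
(typically 298–308 K).

$\Delta G$ is reported by two routes: $\Delta H - T\Delta S$ from the fitted
pair, and $-RT\ln K_a$ directly from each constant. For a two-point solve
these agree exactly at the input temperatures (an algebraic identity the
test suite asserts to $10^{-9}$ relative). `compute_gibbs()` exposes both
routes for arbitrary inputs and warns when they disagree by more than
0.5 kJ/mol — published per-temperature entropy values are sometimes
inconsistent with the same table's binding constants, and the package
surfaces that instead of reproducing one route silently. One fitted line has
exactly one $\Delta S$; per-temperature entropies can only come from
external information, so fluorbind reports the single fitted value plus the
route discrepancy.

**Force typing.** `classify_binding_forces()` applies the standard sign
rules: $\Delta H>0,\ \Delta S>0$ → hydrophobic; $\Delta H<0,\ \Delta S<0$ →
van der Waals + hydrogen bonding; $\Delta H<0,\ \Delta S>0$ → electrostatic.
The fourth quadrant ($\Delta H>0,\ \Delta S<0$) has no standard assignment
and returns an empty set, as do exact zeros (flagged as boundary cases).
All nine sign combinations are covered by a truth-table test.

## Site-marker displacement

Albumin's drug sites are probed competitively: warfarin marks site 1
(subdomain IIA), ibuprofen site 2 (subdomain IIIA), methyl orange site 3.
Two statistics are computed:

* the *probe ratio* $100\,F_2/F_1$ per concentration, where $F_2$ and $F_1$
  are the complex's intensities with and without the marker. Note this is a
  remaining-signal ratio (100% = no probe effect), not a "fraction
  displaced"; fluorbind implements and labels the ratio as such rather than
  converting to $1 - F_2/F_1$. Ratios above 100% (enhancement) are reported
  and flagged, never clipped.
* the *retention ratio* $100\,K'_a/K_a$, where $K'_a$ is refitted with the
  probe pre-bound (1:1 probe:protein).

`assign_primary_site()` assigns the site of the probe with the minimum
retention ratio, subject to two thresholds: the minimum must be below 60%
(otherwise no probe competes meaningfully) and the runner-up must be at
least 10 percentage points higher (otherwise the call is a tie). Published
analyses make this call qualitatively; the thresholds make it a reproducible
rule, chosen once so that clearly suppressed binding (ratios in the 20–50%
range against an unaffected ~90%) yields an unambiguous assignment while
near-ties are surfaced instead of silently broken. Both thresholds are
arguments.

## Synchronous fluorescence and UV trend

Synchronous scans at a fixed excitation–emission offset isolate residue
classes: $\Delta\lambda = 15$ nm reads tyrosine, 60 nm tryptophan.
`detect_peak_shift()` tracks the band maximum across concentrations using
quadratic-vertex interpolation (below) and reports the signed shift between
the highest and zero concentration, positive = red. The direction call uses
a 0.5 nm threshold by default — the scale of instrument wavelength
resolution — because "slight" shifts below that cannot be distinguished
from sampling error; it is configurable. The quenching degree
$1 - I_{\max\text{conc}}/I_0$ lets the Trp and Tyr channels be compared: a
larger degree on the 60 nm channel indicates binding closer to tryptophan
residues.

`uv_absorbance_trend()` is deliberately qualitative: complex formation
shows as a systematic decrease of 280 nm absorbance with titrant, and only
the trend direction and monotonicity are reported. No band model is fitted
because none is identifiable from a single-wavelength readout.

## Peak extraction

`extract_peak_intensity()` finds the local maximum nearest a nominal center
(340 nm for the intrinsic protein band), fits a quadratic to all samples
within ±15 nm (configurable), and returns the vertex — sub-sample accuracy
that is robust to a 1 nm wavelength step. A maximum on the spectral boundary
returns the boundary value flagged unreliable, with a warning; a window
whose quadratic curvature is non-negative falls back to the sampled maximum.
The default *downstream* readout, however, is intensity at a fixed
wavelength (`intensity_at()`, 340 nm), matching how titration intensities
are conventionally read; vertex extraction is the option for peak-position
analysis. The vertex intensity of a Gaussian band is biased slightly low
(the quadratic underestimates the crown; ~0.3% at SD 25 nm and window
15 nm), which is irrelevant for ratio statistics since the bias cancels.

## The synthetic generators

Every analysis stage is testable without laboratory data through seeded
generators with known truth (`sim_config()` plus `simulate_*()`):

* `simulate_titration()` draws from one of **two explicit quenching laws**:
  `stern_volmer` ($F = F_0/(1 + K_{sv}[Q])$) or `hill_binding`
  ($(F_0-F)/F = K_a[Q]^n$). Published analyses fit both equations to the
  same titration even though they imply different curve shapes; two modes
  make that internal tension testable instead of hiding it in one
  self-contradictory model.
* `simulate_temperature_series()` derives $K_a(T)$ from the configured
  $(\Delta H, \Delta S)$ through the van't Hoff relation and generates a
  hill-binding series per temperature.
* `simulate_synchronous()` produces Gaussian bands whose center drifts
  linearly with concentration (sign = shift direction) and whose amplitude
  is Stern–Volmer-quenched.
* `simulate_glycation_panel()` produces replicated control/treated readings
  with a known true inhibition fraction per condition and registry-derived
  excitation/emission labels.

Noise is multiplicative Gaussian on intensities, $F(1+\varepsilon)$,
$\varepsilon \sim N(0, \mathrm{cv})$ — the simplest model consistent with
percent-scale error bars from photon-counting instruments — seeded through
a single integer and restoring the caller's RNG state. Defaults are the
298 K parameters of the reference flavonoid–BSA system
($K_{sv} = 1.21\times10^5$, $K_a = 3.79\times10^4$ L/mol, $n = 1.5$,
$\Delta H = -51.53$ kJ/mol, $\Delta S = -85.25$ J mol$^{-1}$ K$^{-1}$,
1% noise) on the 0–10 µM, 6-point grid; the temperature default is 298 K
(source reports mix 293 K and 298 K for the same experiment; 298 K matches
the thermodynamic table and is used throughout).

What the generators do **not** emulate: inner-filter re-absorption,
scattering baselines, instrument drift, lifetime photophysics, and any
kinetics of the glycation cascade. Passing tests therefore demonstrate the
correctness of the *inference chain* — that each estimator recovers the
truth its generating law encodes — not robustness to every artifact of real
cuvette data. In particular, no inner-filter correction is applied anywhere
(reference workflows for this system do not state one); at the absorbances
implied by micromolar ligand this is a percent-level effect on intensities.

## A known, deliberate inconsistency

One documented limitation follows directly from the two-law tension above:
with the published $(K_a, n) = (3.79\times10^4, 1.5)$, the hill-binding
signal depth on the micromolar grid is at most
$K_a (10^{-5})^{1.5} \approx 1.2\times10^{-3}$ of $F_0$ — an order of
magnitude *below* a 1% noise floor. Noiseless recovery of $(K_a, n)$ is
exact at any signal depth (the log-linear relation is scale-free, and the
test suite asserts it to machine tolerance), but under 1% noise on this
grid the binding constant is unrecoverable: about half of seeded replicates
have fewer than three usable points and the median error is total. The
package reports this honestly (the corresponding recovery check fails, and
`scripts/acceptance.R` reports the measured median) rather than quietly
generating data from a more favorable concentration range. $K_{sv}$
recovery on the same grid, where the quenching signal reaches
$F_0/F = 2.21$, passes with ~1.5% median error over 200 seeds. These
problem sizes (6-point grids, 200 replicate seeds, 3-replicate panels) are
the package's standard test conditions.

## Degenerate inputs and tie-breaks

* Titration series require a zero-concentration row (defines $F_0$), strictly
  increasing concentrations (duplicates are an error naming the rows), and
  at least three nonzero points for any fit.
* `hill_binding` at $[Q] = 0$ returns $F_0$ exactly — no log of zero.
* Equal binding constants across temperatures give $\Delta H = 0$ exactly.
* Site assignment ties (within the separation threshold) and
  no-displacement panels return labelled ambiguity, never an arbitrary
  winner.
* Assay panels require every treated species present in the control;
  inhibition with a single replicate in either group reports `NA` SD rather
  than a fabricated uncertainty.
* Inhibition applies the same $1 - \text{treated}/\text{control}$ convention
  to absorbance as to fluorescence; the occasionally printed inverted form
  $(1 - A_0/A)$ would make every effective inhibitor negative and is treated
  as a typographical inversion.

## Orchestration

`run_full_workflow()` drives the chain from a YAML manifest (file paths,
temperatures, $\tau_0$, thresholds, seed, output directory) in the order
the experiments build on one another, writes per-stage CSV tables plus a
key-value summary when an output directory is set, and fails with the stage
name attached. Reports are plain text throughout so runs diff cleanly;
reruns on the same inputs are byte-identical. The package is library-first:
the workflow function, not a shell binary, is the entry point, and every
stage is equally callable on its own.
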