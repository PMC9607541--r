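# fluorbind

Tidy analysis of small-molecule–serum-albumin interactions from
fluorescence spectroscopy, plus inhibition statistics for non-enzymatic
glycation (AGE) assays.

When a ligand binds serum albumin it quenches the protein's intrinsic
tryptophan/tyrosine fluorescence near 340 nm. A titration of that quenching
carries a surprising amount of information, and fluorbind implements the
complete inference chain that extracts it:

* **Quenching mechanism** — Stern–Volmer regression
  `F0/F = 1 + Ksv[Q]`, the bimolecular rate constant `Kq = Ksv/τ0`
  (τ0 ≈ 10⁻⁸ s), and a static/dynamic/indeterminate call from the
  temperature trend of Ksv plus the 2×10¹⁰ L mol⁻¹ s⁻¹ diffusion ceiling.
* **Binding constant and stoichiometry** — the double-logarithmic fit
  `lg[(F0−F)/F] = lg Ka + n·lg[Q]`.
* **Thermodynamic driving forces** — van't Hoff analysis
  `ln Ka = −ΔH/RT + ΔS/R`, `ΔG = ΔH − TΔS`, and sign-rule classification
  (ΔH<0, ΔS<0 → van der Waals + hydrogen bonding, etc.).
* **Binding-site assignment** — competition against the classical albumin
  site markers (warfarin: site 1, ibuprofen: site 2, methyl orange:
  site 3) via retention ratios `100·K'a/Ka`.
* **Conformational readout** — synchronous-fluorescence peak-shift
  detection (Δλ = 15 nm → Tyr, 60 nm → Trp) and a qualitative 280 nm
  UV-absorbance trend check.
* **Glycation inhibition** — `100·(1 − treated/control)` statistics with
  error propagation for fructosamine, fluorescent AGEs (with the standard
  excitation/emission registry), glycoxidation products, and the
  thioflavin T amyloid index.
* **Seeded synthetic generators** with known ground truth for every stage,
  so the whole chain is testable without a fluorimeter.

Functions take data frames first and return tibbles; fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a titration at the reference system's published constants
(Ksv = 1.21×10⁵ L/mol, 0–10 µM grid, 1% noise) and run the chain:

```r
library(fluorbind)

cfg <- sim_config("stern_volmer", noise_cv = 0.01, seed = 42)
ts  <- simulate_titration(cfg)
fit_stern_volmer(ts)
#> Stern-Volmer fit (298 K, 6 points)
#>   Ksv = 1.231e+05 +/- 1.1e+03 L/mol
#>   Kq  = 1.231e+13 L/(mol s)   [tau0 = 1e-08 s]
#>   intercept = 1.0068, R^2 = 0.9997
```

The fitted Ksv recovers the 1.21×10⁵ truth within noise; Kq ≈ 10¹³ sits
three orders of magnitude above the diffusion-collision ceiling, the
signature of static (ground-state complex) quenching.

```r
fit_vant_hoff(c(`298` = 3.79e4, `308` = 1.93e4))
#> van't Hoff fit (2 temperatures, exact two-point solve)
#>   dH = -51.50 kJ/mol
#>   dS = -85.16 J/(mol K)
#> Binding forces: van der Waals + hydrogen bond
#> # A tibble: 2 × 5
#>   temperature_K    Ka dG_from_pair dG_from_ka spontaneous
#>           <dbl> <dbl>        <dbl>      <dbl> <lgl>
#> 1           298 37900        -26.1      -26.1 TRUE
#> 2           308 19300        -25.3      -25.3 TRUE
```

Both ΔH and ΔS negative: binding is enthalpy-driven through van der Waals
contacts and hydrogen bonds, and spontaneous (ΔG < 0) at both temperatures.

```r
assign_primary_site(
  tibble::tibble(probe_name = c("warfarin", "methyl orange", "ibuprofen"),
                 Ka_prime   = c(0.98e4, 1.79e4, 3.38e4)),
  Ka_reference = 3.79e4)
#> Site-marker competition (Ka_reference = 37900 L/mol)
#> # A tibble: 3 × 4
#>   probe_name    site_id Ka_prime ratio_percent
#>   <chr>           <int>    <dbl>         <dbl>
#> 1 warfarin            1     9800          25.9
#> 2 methyl orange       3    17900          47.2
#> 3 ibuprofen           2    33800          89.2
#> Primary binding site: site 1 (warfarin probe)
```

Warfarin collapses the apparent binding constant to 26% of its probe-free
value while ibuprofen leaves it essentially intact, so the ligand occupies
site 1 (subdomain IIA).

The full chain — titrations at several temperatures, probe files, a
glycation panel — runs from a YAML manifest with `run_full_workflow()`,
writing diff-able per-stage tables and a summary.

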