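# ProtDynamics

Multi-timescale backbone protein dynamics for ¹⁵N-labelled proteins in R.

Proteins that share a structure can still differ in how they move, and for
amyloidogenic immunoglobulin light chains those differences — not the fold —
track the propensity to form fibrils. Characterizing them takes several
experiments probing different timescales, each with its own model and
fitting protocol. ProtDynamics implements that full analysis chain for
people who have the measured tables (peak intensities, dispersion
profiles, exchange time courses, correlograms, MD-derived series) and want
reproducible parameter estimates with honest uncertainties:

* **Relaxation rates (ps–ns):** monoexponential fits of intensity-vs-delay
  series into R₁/R₂ with Monte-Carlo uncertainties (500 replicas, 68% CI),
  HetNOE ratios with error propagation, and the rotational correlation
  time from the mean ratio, tc = (1/4πν_N)·√(6R₂/R₁ − 7).
* **Lipari–Szabo model-free analysis:** J(ω) and the ¹⁵N dipolar+CSA rate
  equations (r_NH = 1.02 Å, Δσ = −172 ppm), per-residue fits of models 1–5
  with BIC selection (BIC = χ² + k·ln n), Monte-Carlo errors and a global
  isotropic tumbling-time optimization.
* **CPMG relaxation dispersion (µs–ms):** R₂,eff = −ln(I/I₀)/T, the
  Carver–Richards two-site exchange model in an exact finite-pulse-train
  closed form validated to ~1e-13 against numerical Bloch–McConnell
  propagation, the Rex > 3 s⁻¹ significance rule, and individual plus
  global fits sharing (kex, p_B) with ppm-anchored Δω across fields.
* **Hydrogen–deuterium exchange (s–h):** decay fits in 100% and 50/50 D₂O
  modes, censoring of residues that exchange before the first time point,
  intrinsic rates from the poly-DL-alanine reference scheme, protection
  factors P = k_e/k_int, ΔG_HD = −RT·ln P and variant ΔΔG.
* **Hydrodynamics:** Stokes–Einstein, DLS scattering vector and
  first/second-order cumulant analysis.
* **MD observables:** windowed N–H order parameters (ensemble
  second-moment S², 2.5 ns windows, convergence flag), hydrogen-bond
  occupancy (2.4 Å inclusive cutoff) and burial from exposed area.
* **Synthetic data:** seeded forward generators for every input above,
  with ground-truth sidecars and germline/mutant scenario presets, so each
  stage is verifiable by parameter recovery.

The central containers are S4 classes (`IntensitySeries`,
`RelaxationDataset`, `DispersionProfile`, `TwoSiteParams`, `HdxSeries`,
`DlsMeasurement`, `VectorTrajectory`, `SyntheticScenario`) with validity
checks and `show()` methods.

## Worked example

Estimate the tumbling time from cohort mean rates, then run a dispersion
recovery on synthetic data:

```r
library(ProtDynamics)

estimateTcFromR2R1(1.05, 17.3, 700e6) * 1e9
#> [1] 10.74533

scn <- germlineScenario(1, nResidues = 20, rexFraction = 1)
g <- makeCpmgInputs(scn)          # 40 profiles: 20 residues x 2 fields
gf <- fitGlobal(g$profiles)
round(c(kex = gf$kex, pb = gf$pb), 4)
#>       kex        pb 
#> 1166.0206    0.1504
```

The first number is the rotational correlation time in ns implied by the
mean R₂/R₁ ratio at 700 MHz — ~10.7 ns, a monomeric ~12 kDa domain. The
global dispersion fit recovers the generating exchange rate
(1175 s⁻¹) and minor-state population (15%) of the scenario from noisy
two-field profiles; per-residue |Δω| and R₂⁰ are in `gf$residues`.

Fitting a model-free cohort:

```r
r <- makeRelaxationRates(germlineScenario(2, nResidues = 60))
fits <- fitDataset(r$dataset, r$spin, tm = 10.7e-9, models = 1:5)
round(mean(fits$s2), 3)
#> [1] 0.831
table(fits$model)
#> 
#>  1  2  3  4  5 
#> 15  1 37  6  1
```

The cohort mean fitted S² sits at the generating value of 0.84 within the
fit noise, and model selection partitions residues between exchange-free
(models 1/2/5) and exchange-broadened (models 3/4) descriptions, as
expected for a β-sandwich domain with a shared excited state (with three
observables per residue the exact model identity within each group is not
sharply resolvable; see the methods vignette).

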