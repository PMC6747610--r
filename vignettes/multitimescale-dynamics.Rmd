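---
title: "Multi-timescale backbone dynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale backbone dynamics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtDynamics)
```

ProtDynamics analyses backbone ^15^N dynamics of a protein across four
timescales — picosecond-to-nanosecond bond librations (spin relaxation and
model-free analysis), microsecond-to-millisecond conformational exchange
(CPMG relaxation dispersion), second-to-hour stability (hydrogen-deuterium
exchange), and overall tumbling/hydrodynamics (R~2~/R~1~ and DLS) — together
with post-processing of molecular-dynamics time series into the same
observables. It was built around the comparison of an amyloidogenic
immunoglobulin light-chain variable domain and its germ line, but every
stage is generic. This vignette records the models, the estimators, the
tunable parameters, and the design decisions that were genuinely open.

## Relaxation rates (ps–ns input layer)

Peak intensities versus relaxation delay are fit to a single exponential
$I(t) = A e^{-Rt}$ with no baseline offset: the acquisition schemes reduce
both longitudinal and transverse experiments to decays toward zero, and a
floating baseline on nine-point series mostly absorbs noise. The fit
profiles out the amplitude (for fixed $R$ the optimal $A$ is closed form),
leaving a one-dimensional minimization that cannot diverge and is cheap
enough for Monte-Carlo error propagation: each series is refit
`nReplicas = 500` times with Gaussian noise of the spectral baseline
standard deviation added, and the half-width of the central 68% interval of
the refitted rates is reported as the uncertainty. All stochastic entry
points require a seed.

The heteronuclear NOE is the saturated/reference intensity ratio with
first-order error propagation; negative values pass through, as they should
for highly flexible amides.

The rotational correlation time uses the standard single-field estimator
$t_c = \frac{1}{4\pi\nu_N}\sqrt{6R_2/R_1 - 7}$, valid for slow isotropic
tumbling. Applied to the cohort mean rates of the two study proteins at
700 MHz it returns 10.7 and 11.0 ns:

```{r}
estimateTcFromR2R1(1.05, 17.3, 700e6) * 1e9
estimateTcFromR2R1(1.09, 18.9, 700e6) * 1e9
```

## Model-free analysis

The spectral density is the Lipari–Szabo form, isotropic tumbling only
(anisotropic diffusion gave no improvement for these proteins and is out of
scope). Five models are fit per residue: (1) $S^2$; (2) $S^2, t_e$;
(3) $S^2, R_{ex}$; (4) $S^2, t_e, R_{ex}$; (5) $S^2_f, S^2_s, t_e$.
Relaxation rates follow the standard ^15^N dipole–dipole + CSA expressions
with $r_{NH} = 1.02$ Å and $\Delta\sigma = -172$ ppm; the dipolar constant
is $d = (\mu_0/4\pi)\,\gamma_H\gamma_N\hbar/r_{NH}^3$, which reproduces the
observed rate scale ($R_1 \approx 1$ s^-1^, $R_2 \approx 15$ s^-1^ at
$S^2 = 0.84$, $t_m = 10.7$ ns, 700 MHz). The forward equations are verified
in the tests against an independently coded brute-force evaluation.

Fits minimize the $1/\sigma^2$-weighted squared residuals of
(R~1~, R~2~, NOE) under box constraints ($S^2$-type parameters in [0, 1],
$t_e \in [0, t_m]$, $R_{ex} \in [0, 50]$ s^-1^) from a small multi-start
grid. Model selection minimizes $BIC = \chi^2 + k\ln n$ with $n = 3$
observables per field and ties broken toward fewer parameters. With only
three observables per residue the selection has hard limits: the
three-parameter models (4 and 5) always fit exactly, pinning their BIC at
$3\ln 3$, and on exchange-free residues the exchange model wins whenever
noise mimics about one standard deviation of R~2~ excess. Both effects are
noise-level independent, so at a single field the *exact* model identity
is recoverable only ~70–85% of the time, while the scientifically
meaningful partition — residues requiring an exchange term (models 3/4)
versus not (1/2/5) — is recovered above 90%. Resolving model identity
sharply requires a second field (six observables), which the fitting layer
accepts but the single-field default does not assume. The global
tumbling time alternates per-residue fitting with a one-dimensional
refinement of $t_m$ until it moves by less than 0.01 ns.

## CPMG relaxation dispersion

Intensities convert to rates via
$R_{2,\mathrm{eff}} = -\ln(I/I_0)/T$ with a constant relaxation delay
$T = 30$ ms; non-positive intensities flag the point rather than abort the
profile. Repeated frequencies are averaged, their half-range (floored by a
baseline value) becoming the per-point uncertainty.

The two-site model deserves a note. The classical Carver–Richards
expression — the $\cosh^{-1}$ form with the $\psi/\zeta$ auxiliaries — is
exactly the decay rate of the dominant eigenmode of the two-echo
propagator; we verified this numerically to machine precision. What an
experiment measures, however, is an intensity after a *finite* echo train,
which also carries the projection of the initial magnetization onto that
eigenmode. For a 30 ms block at the lowest refocusing frequencies (two
echoes) and a sizable minor population this projection term is worth up to
~1 s^-1^. `carverRichardsR2eff()` therefore defaults to the exact
closed-form intensity-derived rate (the same eigenstructure plus the exact
projection factor, evaluated by elementwise complex algebra over the
frequency grid); `amplitude = FALSE` returns the classical dominant-mode
expression. A step-by-step Bloch–McConnell propagation
(`blochMcConnellR2eff`) — free precession with exchange, ideal refocusing
pulses as complex conjugation — is the independent numerical route used to
adjudicate; the two agree to ~1e-13 across slow-to-fast exchange, and the
classical form agrees with both to within its known low-frequency bias.

Profiles whose size $R_{2,\mathrm{eff}}(\nu_{min}) -
R_{2,\mathrm{eff}}(\nu_{max})$ exceeds 3 s^-1^ (strict) carry significant
exchange. Individual fits use weighted least squares with multi-start
Nelder–Mead and Monte-Carlo errors; the global fit shares
($k_{ex}, p_B$) across residues, anchors $|\Delta\omega|$ in ppm across
fields, leaves $R_2^0$ free per residue per field, and canonicalizes
$p_B < 0.5$, $\Delta\omega \ge 0$. Because the ($p_B, \Delta\omega$)
likelihood valley is shallow toward fast exchange, initialization scans a
coarse ($k_{ex}, p_B$) grid, setting each residue's $\Delta\omega$ by
matching its observed dispersion size, before joint quasi-Newton
refinement.

**Identifiability.** At the mutant-like regime ($k_{ex} \approx 2000$
s^-1^ with average $|\Delta\omega| \approx 0.5$ ppm) the exchange is fast
($k_{ex}/\Delta\omega \approx 9$): only the product
$p_A p_B \Delta\omega^2$ and $k_{ex}$ are well determined, and with
0.3 s^-1^ noise the profile $\chi^2$ in $p_B$ is flat within one unit from
0.1 to 0.5. Point estimates then drift toward the $p_B = 0.5$ boundary and
no estimator recovers the population to two percentage points. The
two-variant recovery experiments therefore construct the mutant scenario
the way the scenario contrast defines it — scaling $k_{ex}$ and $p_B$ from
the germline condition while inheriting the germline shift-difference draw
(mean 0.8 ppm) — which keeps enough residues in intermediate exchange for
the population to be identified. The Table-2-style mutant preset (mean
$\Delta\omega$ 0.5 ppm) remains available for qualitative comparison.

## Hydrogen-deuterium exchange

Decays in 100% D~2~O fit $A e^{-k t}$; the 50/50 solvent series fit
$A(0.5 + 0.5 e^{-kt})$ with the plateau pinned at half amplitude — 50%
pre-exchange fixes the equilibrium occupancy, and freeing the plateau on
2-minute grids destabilizes the fits. A series indistinguishable from its
plateau at the first sample is classified `before_first_point` and later
assigned the fastest rate measured in the dataset. Lifetimes
$\tau = 1/k_e$ are binned at exactly 100 s and 600 s. The fast set is
mapped onto the slow set's intensity scale by one least-squares factor over
residues quantified in both; the effective earliest observable time is
reported as half the fast-mode first sampling time (the halved decaying
amplitude brings the quantifiable onset forward), about 60 s for 2-minute
sampling.

Intrinsic rates use the poly-DL-alanine reference scheme (Bai, Milne,
Mayne & Englander, 1993): acid-, base- and water-catalyzed reference rates
with log-additive nearest-neighbour side-chain factors (shipped as a
plain-text table under `inst/extdata/`), $pD = pH_{read} + 0.4$ for D~2~O,
and Arrhenius temperature corrections (14/17/19 kcal/mol) from the 293 K
reference. Prolines and the chain start have no amide and raise an error.

The free-energy layer follows the quotient convention $P = k_e/k_{int}$
with $\Delta G_{HD} = -RT\ln P$ and
$\Delta\Delta G = -RT\ln(P_{var}/P_{ref})$. This is the *inverse* of the
common protection-factor convention; both are returned, labelled, and the
identity $\Delta\Delta G = \Delta G_{var} - \Delta G_{ref}$ holds to
numerical precision.

## Hydrodynamics

Stokes–Einstein ($D = k_BT/6\pi\eta R$) with the measurement constants
$\lambda = 633$ nm, $n = 1.333$, $\theta = 173°$, $\eta = 0.8872$ cP,
25 °C. Cumulant analysis takes $g_1 = \sqrt{g_2-1}$ (Siegert, unit
coherence) and fits $\ln g_1 = b_0 - \Gamma\tau + \mu_2\tau^2/2$ weighted
by $g_2-1$; the intercept absorbs the amplitude, second order is the
default, $D = \Gamma/q^2$, polydispersity $\mu_2/\Gamma^2$. A 2.1 nm
radius corresponds to $D \approx 1.17\times10^{-10}$ m²/s
($1.17\times10^{-6}$ cm²/s) at these conditions; published values around
$10^{-7}$ cm²/s for such domains are dimensionally inconsistent with a
~2 nm radius under the same equation and look like an exponent slip — the
package implements the physics and does not reproduce that exponent.

## MD observables

Windowed order parameters use the ensemble second-moment estimator
$S^2 = \frac{3}{2}\left[\langle x^2\rangle^2 + \langle y^2\rangle^2 +
\langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
2\langle yz\rangle^2\right] - \frac{1}{2}$ over 2.5 ns windows, rather
than correlation-function plateaus: it needs no tumbling deconvolution
because input vectors are assumed pre-aligned to the molecular frame
(alignment is the caller's responsibility). A window is flagged
non-converged when its half-window estimates differ by more than 0.05.
Hydrogen bonds count frames with H⋯acceptor distance ≤ 2.4 Å (inclusive,
no angle restriction); burial maps exposure linearly from 0 (100% buried)
to 10 (0% buried), clamped.

## The synthetic generators and what passing tests mean

Every pipeline input can be forward-simulated from a
`SyntheticScenario` holding the ground truth; generators are
deterministic given the seed and return their truth sidecar, and recovery
tests read truth only from that sidecar. The germline defaults encode the
study conditions: 90 residues, $t_m = 10.7$ ns, mean $S^2$ 0.84 (sd 0.06),
two thirds of fitted residues with exchange, a shared excited state at
$k_{ex} = 1175$ s^-1^, $p_B = 15\%$, per-residue $|\Delta\omega|$ around
0.8 ppm, log-normal HDX lifetimes with median 600 s; the variant contrast
is $k_{ex}\times1.709$, $p_B\times2/3$, lifetimes $\times1/6$, $S^2+0.04$.
Choices that neither the data tables nor the protocol fix, made once:

* **Rate-level noise** (r1 0.05, r2 0.4, noe 0.03 s^-1^) was set so that
  the synthetic *cohort spread* reproduces the printed per-cohort spreads
  (the $S^2$ distribution itself contributes ~0.064 s^-1^ to the R~1~
  spread; measurement noise makes up the remainder). Intensity-level noise
  is 1% of the amplitude.
* **$S^2$ and $\Delta\omega$ draws are recentred** so the sample mean
  equals the scenario mean: the printed cohort averages are the generating
  conditions, not merely expectations.
* **$|\Delta\omega|$ is log-normal** (sdlog 0.6): a narrow spread is
  incompatible with the observed coexistence of a ~0.5 ppm average and a
  sizable fraction of residues above the 3 s^-1^ significance cut.
* **Cone trajectories** use a Metropolis random walk on the spherical cap
  (geodesic Gaussian steps, reject-outside moves), whose stationary law is
  exactly uniform on the cap — the equilibrium of diffusion in a cone —
  so the closed form $S^2 = [\cos\theta_0(1+\cos\theta_0)/2]^2$ is the
  oracle.

The generators emulate monoexponential decays, two-site dispersion, HDX
decays on the real sampling grids, cone vector walks and single-species
correlograms with Gaussian noise. They do *not* emulate peak overlap,
baseline distortions, pulse imperfections, anisotropic tumbling,
three-site exchange, EX1 exchange or back-exchange — so passing recovery
tests demonstrates estimator correctness under the stated noise model, not
robustness to every experimental artifact.

Test and recovery problem sizes (20-residue dispersion sets, 60-residue
model-free cohorts repeated over three generations, 20-seed dispersion
repetitions, 200-draw closed-form-vs-oracle sweeps) are the package's
chosen balance between statistical resolution and a test suite that runs
in minutes.

## Numerical choices and degenerate inputs

One-dimensional profiled fits use `optimize` with tolerance 1e-12 and an
explicit zero-rate check (a constant series fits $R = 0$ exactly).
Monoexponential fits faster than 30 times the inverse earliest delay are
flagged rather than reported. The 2×2 complex matrix exponential uses the
Cayley–Hamilton closed form with a series fallback for the degenerate
eigenvalue case; matrix powers use the eigenvalue form with a
repeated-root branch. The exchange-free limits ($p_B \to 0$ or
$\Delta\omega = 0$) short-circuit to $R_2^0$. BIC ties break toward fewer
parameters; the global dispersion fit canonicalizes $p_B < 0.5$,
$\Delta\omega \ge 0$.

## Known limitations

Single-field model-free fitting with three observables cannot sharply
discriminate the five models (see the BIC note above); the mutant-regime
$p_B$ is unidentifiable at realistic noise when all shift differences are
small (documented above); HDX rates are not corrected for the 50% driving
force in the mixed solvent, matching the analysis being reproduced; and
the intrinsic-rate table carries the usual uncertainty of the reference
compilation.
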