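---
title: "Two-state conformational exchange from CPMG relaxation dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state conformational exchange from CPMG relaxation dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgdyn)
```

# The model

Many proteins interconvert on the µs–ms timescale between a highly
populated ground state A and a sparsely populated excited state B:

$$A \underset{k_{BA}}{\overset{k_{AB}}{\rightleftharpoons}} B,
\qquad k_{ex} = k_{AB} + k_{BA}, \qquad p_B = k_{AB}/k_{ex}.$$

Exchange between states with different ¹⁵N chemical shifts (difference
Δω) broadens amide resonances; a CPMG pulse train refocuses that
broadening progressively as its frequency ν~CPMG~ rises. The resulting
dispersion of the effective transverse rate,

$$R_{2,\mathrm{eff}}(\nu_{CPMG}) =
  -\frac{1}{T_{relax}} \ln \frac{I_{CPMG}}{I_0},$$

measured from peak intensities with (I~CPMG~) and without (I₀) a
constant relaxation delay (default `t_relax` = 30 ms), encodes
$k_{ex}$, $p_B$ and |Δω| per residue. Errors are propagated from the
spectral noise through the intensity of the point nearest 500 Hz and
floored at 3 % of each rate, and residues whose R₂,eff drop between the
lowest and the highest CPMG frequency (66.7 and 1000 Hz) exceeds 5 s⁻¹
in **any** field/temperature condition are classed exchange-active. The
"any condition" tie-break is deliberate: a residue with detectable
exchange in one condition carries information for the global model, and
the alternative ("all conditions") silently discards residues whose
dispersion flattens at high temperature.

## Forward model

`bm_r2eff()` propagates the two-state Bloch–McConnell equations
numerically: transverse magnetization $(M_A, M_B)$ evolves under a 2×2
complex Liouvillian (exchange rates off-diagonal, $i\Delta\omega$ on
the minor-state diagonal, a shared intrinsic rate $R_{2,0}$ on both
diagonals) between ideal, instantaneous 180° pulses applied as complex
conjugation. Echo blocks are paired palindromically, and the rate is
read out from the ground-state magnetization magnitude after the full
constant-time element, starting from equilibrium populations.

Numerical choices:

* The matrix exponential uses the closed Cayley–Hamilton form for 2×2
  complex matrices, and block propagation uses binary exponentiation —
  exact to machine precision, no step-size parameter.
* `t_relax * nu_cpmg` must correspond to an integer number of echo
  blocks; a non-integer count is rounded and the effective frequency
  recorded, and the synthetic generator rejects frequencies more than
  0.05 blocks away from an integer, reporting the closest valid value.
  All twelve default frequencies (66.7–1000 Hz) give even block counts
  in 30 ms.
* Δω is stored in ppm — the field-independent quantity — and converted
  per field with the ¹⁵N/¹H frequency ratio 0.1013.
* $R_1$ during the element is not modelled: it cancels in the
  intensity ratio of the constant-time experiment. Pulse imperfections
  are likewise outside the model, as the relaxation-compensated
  sequence is designed to suppress their systematic effects.

Two analytic oracles guard the propagator: the Carver–Richards closed
form (`carver_richards_r2eff()`) and the Luz–Meiboom fast-exchange
limit (`luz_meiboom_r2eff()`). The fast-exchange limit agrees with the
propagator to well under 5 % wherever its validity condition
$k_{ex} \ge 10\,\Delta\omega$ holds. The Carver–Richards expression is
the decay rate of the dominant eigenmode of the echo propagator, i.e.
the *asymptotic* rate; over a finite 30 ms element the observed
intensity also carries the projection amplitude of the starting
magnetization onto that mode. The two therefore differ where that
amplitude matters: at the lowest pulsing frequencies (few echo blocks)
in slow exchange with a large minor-state population, by up to ~8 % at
$p_B = 0.15$, $k_{ex} < \Delta\omega$, and still a few percent at
intermediate regimes. This is a documented property of the closed
form, not a defect of either implementation — the test suite verifies
the propagator against an eigenvalue-based evaluation and records the
disagreement map.

## Global fit

All selected residues, fields and temperatures are fitted together by
minimizing the error-weighted χ²

$$\chi^2(\zeta) = \sum \left(
  \frac{R_{2,\mathrm{eff}}^{calc}(\zeta) - R_{2,\mathrm{eff}}^{exp}}
       {\Delta R_{2,\mathrm{eff}}^{exp}}\right)^2$$

under the structural assumptions that (a) one exchange process is
shared by all residues, (b) $R_{2,0}$ is common to both states, and
(c) Δω (in ppm) is independent of temperature and field. The parameter
set is one $(p_B, k_{AB})$ pair per temperature, one Δω per residue and
one $R_{2,0}$ per residue and field — $2 n_T + n_R + n_R n_B$
parameters (76 at the reference design). A strict per-temperature mode
(`per_temperature = TRUE`) fits each temperature as an independent
dataset instead; the joint mode is the default because it reproduces
the stated parameter structure and pools the temperature series that
the thermodynamic analysis needs.

Implementation: rates are optimized on a log scale and $p_B$ through a
logit mapped onto (0, 0.5) — positivity and minor/major identifiability
by construction. For fixed kinetics and shifts, χ² is quadratic in each
$R_{2,0}$, so the intrinsic rates are profiled out analytically at
every evaluation (variable projection), leaving a 32-dimensional
nonlinear problem at the reference design. Levenberg–Marquardt is run
from the automatic initialization (Δω seeded from the fast-exchange
relation at $k_{ex}$ = 1000 s⁻¹, $p_B$ = 0.05) plus randomly perturbed
restarts (5 starts by default; exploratory starts run on a quarter of
the iteration budget and the best is polished), keeping the lowest χ².
Convergence uses a 10⁻¹⁰ relative tolerance and a 200-iteration cap per
start. Parameter uncertainties come from the Gauss–Newton covariance
at the optimum scaled by the reduced χ² (so that overstated data
errors, e.g. the 3 % floor applied to noiseless synthetic data, do not
inflate them), or from residual-resampling bootstrap.

## Thermodynamics

Per-temperature populations and rates feed two linear fits:
the Van't Hoff relation, $\ln K_e = \Delta S_{BA}/R - \Delta H_{BA}/(RT)$
with $K_e = p_B/p_A$, and the Eyring relation,
$\ln(k_{AB}/T) - \ln(\kappa k_B/h) = \Delta S^*/R - \Delta H^*/(RT)$,
with the transmission coefficient $\kappa = 1.6\times10^{-7}$ by
default (configurable; it shifts only the activation entropy, by
$R\ln\kappa$). Both regressions are unweighted by default since
equilibrium-constant uncertainties are usually unavailable; weights can
be supplied. Energies are joules per mole internally and kilojoules per
mole in reports, and `reaction_coordinate_diagram()` enforces
$\Delta G = \Delta H - T\Delta S$ at every level by construction.

# The synthetic-data generator

Every stage of the pipeline is verifiable by parameter recovery
without external data. `generate_two_state_system()` draws per-residue
shift differences and intrinsic rates uniformly (defaults 0.5–4 ppm and
8–20 s⁻¹, typical amide ¹⁵N ranges) and derives per-temperature
kinetics *exactly* from a thermodynamic truth, so $\ln K_e$ and
$\ln(k_{AB}/T)$ are linear in $1/T$ by construction. The default truth
is anchored at a minor-state population of 8.5 % and an exchange rate
of 812 s⁻¹ at 298 K with an excited-state enthalpy of −37 kJ/mol
(hence $T\Delta S \approx -43$ kJ/mol and $\Delta G \approx +6$ kJ/mol
at 298 K); the activation enthalpy, which no equilibrium measurement
pins down, is set to 50 kJ/mol — a realistic barrier for concerted
loop/cavity motions — and the activation entropy follows from the rate
anchor. The reference design is 22 residues × 2 fields (500/700 MHz)
× 5 temperatures (298.0–308.0 K) × 12 CPMG frequencies.

Noise models:

* Dispersion intensities receive Gaussian noise of standard deviation
  `noise_fraction × I0` (default 3 %) — constant per spectrum, the way
  thermal spectral noise enters peak intensities and the error formula.
* Relaxation decays receive *relative* noise (sd proportional to the
  model intensity at each delay), and `fit_exponential_decay()`
  accordingly uses proportional-error least squares, the
  maximum-likelihood estimator for that model and the nonlinear
  analogue of the classical log-linear exponential fit.
* Titration shifts receive Gaussian noise in ppm directly.

The generator works at the peak-intensity/peak-position level only. It
does not emulate lineshapes, overlapping peaks, exchange broadening to
invisibility, assignment errors, or field-dependent intensity changes —
so recovery tests demonstrate the estimators' correctness and
statistical efficiency under the stated model, not robustness to the
pathologies of real spectra. Residues whose peaks vanish during a
titration are carried with a `disappeared` flag and refused by the
binding fit rather than imputed.

The hollow-shell cavity fixture places atoms on concentric spherical
Fibonacci lattices (uniform angular coverage, leak-free at coarser
atom counts than a cubic packing) and records the enclosed sphere's
analytic volume as ground truth; a 400-direction ray test from the
cavity centre rejects shells a 1.3 Å probe could escape through.

# Fast-timescale dynamics

R₁ and R₂ come from exponential fits of delay series; the steady-state
heteronuclear NOE is the saturated/reference intensity ratio, flagging
residues below 0.65 as flexible. The overall rotational correlation
time is estimated by numerically inverting the isotropic-rotor
spectral-density expressions for the 10 %-trimmed-mean R₂/R₁ ratio of
rigid residues (NOE ≥ 0.65; exchange-active residues can be excluded,
since R~ex~ inflates R₂). Constants: N–H bond length 1.02 Å, ¹⁵N CSA
−160 ppm, all configurable. The R₂/R₁ ratio increases monotonically
with τ~c~, so the inversion is a bracketed one-dimensional root find
(0.5–50 ns). No Lipari–Szabo model-free analysis and no anisotropic
diffusion tensor are attempted.

# Chemical-shift analyses

* **Temperature coefficients.** The ¹H shift slope versus temperature
  (ppb/K); slopes *more positive than* −5 ppb/K indicate intramolecular
  hydrogen bonding. The inequality is strict — exactly −5 classifies as
  not hydrogen-bonded — and the classification is invariant to constant
  shift offsets.
* **Chemical-shift perturbation.** Combined displacement
  $\sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}$, the standard
  amide nitrogen weighting (configurable), with significance called at
  the mean plus one standard deviation.
* **Binding isotherm.** The exact single-site quadratic isotherm is
  fitted for $K_D$ and the saturation shift at known total protein
  concentration (reference design: 80 µM protein, 5–500 µM ligand).
  Fits where the data never approach half the fitted plateau, or where
  the fitted $K_D$ exceeds the sampled concentration range, are flagged
  poorly determined rather than rejected.
* **Titration vs dispersion.** `compare_dw()` compares the ¹⁵N shift
  differences obtained by the two independent routes residue by
  residue; agreement suggests the excited state resembles the bound
  state. The outlier cutoff defaults to 0.5 ppm — the two routes carry
  ~0.1–0.2 ppm uncertainties each, so half a ppm separates genuine
  structural disagreement from fit scatter without a claim to
  universality.

# Cavity volume

The internal cavity is measured on a regular grid (default 0.5 Å) by a
two-probe rolling-probe difference with radii 1.3 Å (solvent-sized) and
3.0 Å. The large-probe solvent-excluded region is computed with
*accessibility*: candidate probe centres are flood-filled from the box
boundary, so interior voids and channels too narrow for the large
probe remain excluded. The molecular solid is computed with the small
probe placed anywhere it fits, without connectivity — deliberately so:
with accessibility applied to both probes, a sealed cavity would be
excluded by both and cancel in the difference, leaving the method blind
to exactly the voids it exists to measure. The difference region is
decomposed into 6-connected components; components touching the box
boundary are bulk-solvent artefacts and are discarded. Discretized
probe spheres whose boundary voxels must lie strictly inside the radius
systematically undershoot it, so the dilation radius carries a
one-third-voxel correction that centres the quantization error; with
it, halving the grid changes the hollow-shell volume by about 1 %, and
rigid-body motion of the structure changes it well under 2 %.

Van der Waals radii follow the Bondi set (H 1.20, C 1.70, N 1.55,
O 1.52, S 1.80 Å), hydrogens included when present since NMR ensembles
carry them; unknown elements fall back to 1.70 Å with a warning.
Waters and hetero ligands are dropped by default, and one model of a
multi-model file is selected (the first by default — deposited
ensembles do not mark a privileged member, so absolute volumes on real
ensembles are approximate by nature). Tunnel/channel axis detection and
per-residue cavity lining analysis are out of scope.

# Pipeline and problem sizes

`run_config()` aggregates every default in one validated list (unknown
keys are rejected with the schema), and `run_pipeline()` chains the
stages in dependency order, isolating failures to their dependents and
writing per-stage CSVs plus a JSON report that echoes every effective
parameter, the seeds and all collected warnings. Identical
configuration and seeds reproduce every output exactly.

The test suite exercises the reference design (22 × 2 × 5 × 12, 3 %
noise, 20 replicates) for dispersion recovery, 50 replicates for the
relaxation fits and 20 for the titration, and a 2400-point parameter
grid for the oracle sweeps; these sizes keep the full suite within a
few minutes while leaving the recovery medians far from their
acceptance margins. `scripts/acceptance.R` re-runs one replicate of
each computation from scratch with a caller-supplied seed.

# Known limitations

* The two-state single-quantum model only: no multi-quantum or ¹H
  CPMG, no three-state topologies, no off-resonance R₁ρ.
* Carver–Richards and the finite-duration propagator disagree by more
  than 2 % in the slow-exchange, high-$p_B$ corner (see above); tests
  that compare them as oracles are restricted accordingly, and the
  full-grid comparison is reported, not hidden.
* Van't Hoff and Eyring fits assume temperature-independent ΔH and ΔS
  (no heat-capacity term) — adequate over the 10 K span of the design,
  unverifiable beyond it.
* The τ~c~ estimate assumes rigid isotropic tumbling; anisotropy and
  internal motion bias it in ways the estimator does not model.
* Grid cavity volumes carry O(grid spacing) surface uncertainty;
  quoted volumes are meaningful to a few percent at 0.5 Å.
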