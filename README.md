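# cpmgdyn

Protein micro-to-millisecond conformational dynamics from NMR
relaxation data, in R.

Proteins such as the PR-10 allergens (Bet v 1, Fag s 1) interconvert
between a dominant ground conformation and a sparsely populated excited
state whose opening motions gate access to an internal ligand-binding
cavity. This package provides the full quantitative chain to
characterize such an equilibrium from ¹H–¹⁵N peak-intensity data:

* **Relaxation dispersion.** Conversion of CPMG peak intensities into
  effective transverse rates, `R2,eff = -(1/T_relax) ln(I_cpmg/I0)`,
  with noise-propagated errors (3 % floor), and filtering of
  exchange-active residues (ΔR₂,eff > 5 s⁻¹ between 66.7 and 1000 Hz).
* **Global two-state fitting.** A numerical Bloch–McConnell propagator
  for the two-state exchange `A ⇌ B` (rates k_AB/k_BA, population
  p_B = k_AB/k_ex, shift difference Δω), fitted jointly to all
  residues, fields and temperatures by error-weighted least squares:
  per-temperature (p_B, k_AB), one Δω (ppm) per residue, one intrinsic
  rate R₂,₀ per residue and field. Carver–Richards and Luz–Meiboom
  closed forms serve as independent oracles.
* **Thermodynamics.** Van't Hoff (`ln Ke` vs 1/T) and Eyring
  (`ln(k_AB/T)` vs 1/T, transmission coefficient κ = 1.6×10⁻⁷) fits
  yield ΔH/ΔS of the excited and transition states and a
  reaction-coordinate diagram with ΔG = ΔH − TΔS enforced.
* **Backbone dynamics.** Single-exponential R₁/R₂ fits, heteronuclear
  NOE with a 0.65 flexibility cut, and rotational correlation time from
  isotropic-rotor R₂/R₁ inversion.
* **Chemical-shift analyses.** Amide temperature coefficients (H-bond
  indicator at −5 ppb/K), chemical-shift perturbation maps, quadratic
  single-site K_D titration fits, and titration-vs-dispersion Δω
  comparison.
* **Cavity volume.** Two-probe (1.3/3.0 Å) rolling-probe grid method
  on PDB coordinates for internal cavity volumes.
* **Synthetic data.** Generators with exactly known ground truth for
  every input above, so each stage is testable by parameter recovery.

## Worked example

Simulate the reference design — 22 residues, 2 fields (500/700 MHz),
5 temperatures (298–308 K), 12 CPMG frequencies, 3 % intensity noise —
then recover the exchange parameters and thermodynamics:

```r
library(cpmgdyn)

truth <- generate_two_state_system(noise_fraction = 0.03, seed = 7)
peaks <- generate_dispersion_intensities(truth, seed = 7)
disp  <- r2eff_from_intensities(peaks, noise_sd = 0.03 * 1e6)
disp
#> CPMG dispersion dataset: n_R = 22 residues, n_T = 5 temperatures,
#>   n_B = 2 fields, 2640 points

sel <- select_exchange_residues(disp)   # ΔR2,eff > 5 1/s filter
fit <- fit_global(subset_residues(disp, sel$retained), seed = 7)
fit
#> global two-state fit: 2400 points, 70 parameters, chi2 = 3970.8 (reduced 1.704)
#>   298 K: p_B = 0.083, k_ex = 809 /s
#>   300.5 K: p_B = 0.077, k_ex = 1025 /s
#>   303 K: p_B = 0.066, k_ex = 1319 /s
#>   305.5 K: p_B = 0.061, k_ex = 2013 /s
#>   308 K: p_B = 0.051, k_ex = 2465 /s
```

The generating truth at 298 K was p_B = 0.085 and k_ex = 812 s⁻¹; the
fit recovers 0.083 and 809 s⁻¹ from noisy data. The per-temperature
kinetics then give the excited-state (B) and transition-state (TS)
energetics relative to the ground state (kJ/mol at 298 K):

```r
th <- thermo_analysis(fit$params$per_temperature)
d <- reaction_coordinate_diagram(th, 298)
d[-1] <- round(d[-1] / 1e3, 1)
d
#>   level   dg    dh   tds
#> 1     A  0.0   0.0   0.0
#> 2    TS 23.8  49.3  25.4
#> 3     B  5.9 -39.4 -45.3
```

The excited state is enthalpically favorable and entropically costly
(generating values −37 and −42.9 kJ/mol), sitting ~6 kJ/mol above the
ground state. Independently, a cavity volume from coordinates:

```r
shell <- generate_hollow_structure(8)      # analytic volume 2144.7 A^3
rolling_probe_volume(shell)
#> cavity volume: 2179 A^3 (... probes 1.3/3.0 A, grid 0.50 A)
```

For real structures use `read_structure("file.pdb", model = 1)` in
place of the synthetic shell. `run_pipeline(run_config(...))` chains
all stages and writes per-stage CSVs plus a JSON report.

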