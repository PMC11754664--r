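# paibind

Quantitative analyses of DNA binding and folding for the Sleeping Beauty (SB)
transposase and its primary DNA-recognition subdomain, PAI.

SB transposition starts with the transposase binding short direct-repeat (DR)
sites in the transposon's terminal inverted repeats. How tightly it binds —
specifically to DR sites, nonspecifically to other DNA — and how the
structural stability of the PAI subdomain shifts that balance are measured
with a battery of biophysical experiments. paibind implements the
computational side of that battery as composable, tibble-first R functions:

* **Binding isotherms (MST/FA/FLT)** — mono- and biphasic Hill fits of
  dose-response curves, `F(c) = b + Σ ΔF·cⁿ/(K_Dⁿ + cⁿ)`, with SEM
  weighting, multistart, AICc mode selection, and affinity extraction from
  anisotropy or lifetime titrations.
* **pH-folding thermodynamics (CD)** — mean residue ellipticity, two-state
  folded fractions, and fits of the modified Henderson–Hasselbalch sigmoid
  to extract the folding pKa and Hill coefficient; isodichroic-point
  location.
* **Time-resolved fluorescence** — biexponential decays convolved with the
  measured IRF, global fits with lifetime linking across waveforms (variable
  projection), intensity-weighted lifetime `τ = (A₁τ₁² + A₂τ₂²)/(A₁τ₁ +
  A₂τ₂)`, integral intensity, and g-factor-corrected anisotropy.
* **NMR** — weighted chemical-shift perturbations
  `√(Δδ_H² + 0.15·Δδ_N²)`, active-residue selection for docking restraints
  (> 2 SD perturbation and > 50% relative solvent accessibility), and
  Stejskal–Tanner diffusion fits with monomer/dimer calling.
* **Rigid-body protein–DNA docking** — a knowledge-based
  distance/orientation potential `E = Σ E⁰ᵢⱼ(r, φ)` over residue–base
  pairs (derivable from training complexes by inverse Boltzmann), Metropolis
  Monte Carlo pose search, complete-linkage clustering at 3 Å Cα RMSD,
  energy ranking, 5 Å interface annotation with hydrogen-bond listing,
  Kabsch superposition, and Shrake–Rupley SASA.
* **Synthetic data** — seed-deterministic generators for every input type
  (titrations, pH series, decay sets, gradient ramps, peak lists, toy
  B-DNA/protein complexes) with known ground truth, so every chain is
  validated by parameter recovery.

Fitted objects are plain S3 lists with broom-style `tidy()`/`glance()`
methods and `autoplot()` ggplot2 methods.

## Worked example

Simulate an MST titration of Cy5-labelled DR-core DNA with SB10 transposase
at its measured affinity (K_D = 25.3 nM), then fit it back:

```r
library(paibind)

series <- sim_titration(kd_nM = 25.3, hill_n = 1, conc_range = c(1, 500),
                        n_points = 16, replicates = 3, sigma = 0.02, seed = 42)
fit <- fit_binding(series)
fit
#> <binding_fit> 1 mode(s), 16 points
#>   mode 1: KD = 26.07 +/- 1.1 nM, n = 0.964, dF = 1.03
#>   baseline = -0.01022, RSS = 30.03, AICc = 26.07
tidy(fit)
#> # A tibble: 4 × 4
#>   term       mode estimate std.error
#>   <chr>     <int>    <dbl>     <dbl>
#> 1 kd_nM         1  26.1       1.09
#> 2 hill_n        1   0.964     0.0544
#> 3 amplitude     1   1.03      0.0310
#> 4 baseline     NA  -0.0102    0.0203
```

The recovered K_D (26.1 ± 1.1 nM) agrees with the 25.3 nM ground truth within
its standard error; `autoplot(fit)` overlays the Hill curve on the data.
The same pattern runs through the other chains:

```r
fit_ph_transition(sim_ph_series(pKa = 5.98, sigma = 0.02, seed = 42))
#> <ph_fit> pKa = 6.066 +/- 0.156, n = 0.941, plateaus 0.11 -> 0.372

dfit <- fit_diffusion(sim_gradient_series(D = 1.86e-10, sigma = 0.01, seed = 42))
dfit
#> <diffusion_fit> D = 1.884e-10 +/- 1.9e-12 m^2/s (I0 = 1.008, nls fit)
classify_oligomer(dfit, D_monomer = 1.9e-10, D_dimer = 1.3e-10)$call
#> [1] "monomer"
```

A pKa near 6 is the signature of histidine-sidechain deprotonation driving
PAI folding, and the diffusion coefficient matching the monomer prediction
shows the stabilized subdomain does not dimerize. For docking, see
`?mc_dock` and `vignette("paibind-methods")`.

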