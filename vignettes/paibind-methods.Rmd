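---
title: "Models and methods behind paibind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paibind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paibind)
```

paibind quantifies how the Sleeping Beauty (SB) transposase and its PAI
DNA-recognition subdomain engage transposon DNA. It bundles the five analysis
chains such a study needs — dose-response binding fits, pH-folding
thermodynamics, time-resolved fluorescence reconvolution, NMR
chemical-shift-perturbation (CSP) and diffusion analysis, and rigid-body
protein–DNA docking — together with a synthetic-data module that generates
every input type with known ground truth, so each chain can be validated by
parameter recovery.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic generators do and do
not emulate.

## Dose-response binding (MST)

Microscale thermophoresis reports a normalized fluorescence ratio
$F_\mathrm{norm}(c)$ as labelled DNA is titrated with protein. The model is a
constant baseline plus one or two Hill terms,

$$F_\mathrm{norm}(c) = b + \sum_{m} \Delta F_m
  \frac{c^{n_m}}{K_{D,m}^{n_m} + c^{n_m}},$$

with the biphasic ($m = 2$) form describing a specific nanomolar mode plus a
nonspecific micromolar mode as an *additive* sum: the two transitions are
attributed to distinct binding modes, not sequential occupation of one site.
`fit_binding()` fits by weighted least squares with weights $1/\mathrm{SEM}^2$
and multistarts over log-spaced $K_D$ initial values; `select_binding_model()`
picks the mode count by small-sample-corrected AIC, resolving ties
($\Delta\mathrm{AICc} < 2$) to one mode, which is more robust than an F-test
at the 10–20 point counts typical of exported MST curves.

Choices that matter:

* **Hill exponent.** Free by default, bounded to $[0.5, 4]$; `fix_n = TRUE`
  fixes $n = 1$. The source fits are plain "Hill fits" with no exponent
  given, so the exponent is left to the data but kept in a physically
  sensible range.
* **SEM floor.** With three replicates the per-point SEM is itself noisy; raw
  $1/\mathrm{SEM}^2$ weights let a single lucky point dominate. SEMs are
  floored at 20% of the median positive SEM before weighting.
* **Concentrations** are handled on a log axis internally; a $c = 0$ point is
  retained as a baseline anchor (its saturation is exactly zero).
* **Flags.** A fitted $K_D$ outside the sampled concentration range is
  flagged `"unbounded"`; an amplitude within 2 SE of zero, or smaller than
  3 residual SDs, is flagged `"weak-amplitude"` (surfaced as
  `"no-signal-change"` by `titration_kd_from_observable()`).

`normalize_baseline()` subtracts each curve's minimum, the convention used to
overlay curves from different DNA sequences; $K_D$ is invariant to that shift
(and to any affine transform of the observable), which the test suite checks.

## pH-folding thermodynamics (CD)

Raw ellipticity is reduced to mean residue ellipticity by `compute_mre()`
using the standard path-length form
$\mathrm{MRE} = \theta_\mathrm{mdeg} / (10\, l_\mathrm{cm}\, C_\mathrm{M}\, N_\mathrm{res})$.
Some sources print a variant that divides by the wavelength; we treat that as
a typesetting artifact for the path length, but provide
`mode = "as-printed"` so the literal formula can be audited. `fraction_helix()`
converts $[\theta]_{222}$ to a two-state folded fraction by linear
interpolation between folded/unfolded reference values — a deliberate
replacement for full secondary-structure deconvolution, justified when an
isodichroic point (locatable with `find_isodichroic()`) indicates two-state
behaviour.

The pH dependence is fitted by `fit_ph_transition()` to the modified
Henderson–Hasselbalch sigmoid

$$f(\mathrm{pH}) = \frac{f_\mathrm{base} + f_\mathrm{acid}\,
  10^{\,n(\mathrm{p}K_a - \mathrm{pH})}}{1 + 10^{\,n(\mathrm{p}K_a - \mathrm{pH})}},$$

with both plateaus, $\mathrm{p}K_a$ and the Hill coefficient free, and a
multistart over a $\mathrm{p}K_a$ grid from 4 to 9. Note the parameters are
defined by their *plateau role*: $f_\mathrm{acid}$ is the low-pH plateau
(the $10^{n(\mathrm{p}K_a-\mathrm{pH})}$ term dominates at low pH). Printed
versions of this equation sometimes label the plateaus the other way around
than their own limits imply; defining by role removes the ambiguity. The fit
is canonicalized to $n > 0$ — the $(f_a \leftrightarrow f_b,\, n \to -n)$
reflection gives an identical curve.

With noise $\sigma_f = 0.02$ on a 9-point pH grid and all four parameters
free, the replicate-to-replicate spread of the recovered $\mathrm{p}K_a$ is
around $\pm 0.2$ even though each fit's covariance SE agrees with that
spread; the *mean* over replicates recovers the true midpoint to a few
hundredths of a pH unit. Recovery tests therefore assert the mean and the
SE calibration, not a tighter per-fit spread than the data support.

## Time-resolved fluorescence

A decay waveform is modelled as
$A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$ convolved with the measured
instrument response function (IRF) plus a constant background
(`convolve_model()`). `fit_decays_global()` fits one or many waveforms with
Poisson weights ($1/\max(\mathrm{counts}, 1)$ — photon-counting statistics
with a unit floor), sharing lifetimes (and optionally the IRF time shift)
across a linked set while amplitudes and baselines float per waveform.

The global fit uses **variable projection**: for trial lifetimes the
amplitudes and baseline of every waveform are solved exactly by weighted
linear least squares, and only the shared nonlinear parameters (two
log-lifetimes and the sub-bin IRF shift, bounded to $\pm$ one bin) are
optimized by Levenberg–Marquardt. This keeps a 12-waveform global fit to a
3-parameter outer problem — fast, and free of amplitude/lifetime start-value
interactions. The fit window defaults to 50 ns, within which the decay is
assumed complete. Derived quantities follow the standard definitions: the
intensity-weighted lifetime $\tau = (A_1\tau_1^2 + A_2\tau_2^2)/(A_1\tau_1 +
A_2\tau_2)$ and the integral intensity $A_1\tau_1 + A_2\tau_2$
(`summarize_lifetime()`); steady-state anisotropy is
$(I_{vv} - g I_{vh})/(I_{vv} + 2 g I_{vh})$ with the instrument g-factor
defaulting to 1.03 (`anisotropy()`).

`titration_kd_from_observable()` turns an anisotropy- or lifetime-vs-
concentration series into a $K_D$ through the same Hill machinery as
`fit_binding()`.

**A subtlety the lifetime generator must respect.** For a mixture of a free
species ($\tau_f$) and a bound species ($\tau_b$) with amplitudes
proportional to the populations, the intensity-weighted lifetime along a 1:1
binding curve is *exactly* a Hill curve — but with apparent midpoint
$K_D \tau_f / \tau_b$, not $K_D$: the fit would be perfect and the constant
systematically wrong. `sim_flt_titration()` therefore scales amplitudes as
population$/\tau$, i.e. it assumes the two species have equal molecular
brightness (equal time-integrated emission per molecule), which makes the
weighted lifetime exactly linear in the bound fraction and the recovered
$K_D$ unbiased. This is a stated assumption of the generator, not a property
of every real dye–DNA system; for a dye whose brightness tracks its lifetime,
lifetime titrations carry that $\tau_f/\tau_b$ bias intrinsically.

## NMR: CSP profiling and diffusion

`weighted_csp()` computes the standard combined amide shift change
$\sqrt{(\Delta\delta_H)^2 + 0.15\,(\Delta\delta_N)^2}$ between free and
bound peak lists. Residues missing from either list — typically broadened
beyond detection by exchange — are reported as missing and excluded from the
profile mean/SD, never coerced to zero. The SD is computed over all residues
with both peaks present, with no iterative trimming. `select_active_residues()`
implements the docking-restraint rule: perturbation above the profile mean
plus 2 SD *and* relative solvent accessibility above 50%, both
parameterizable; whether the threshold is relative to the mean or to zero is
not standardized, and mean + $k$·SD is adopted as the conventional choice.

`fit_diffusion()` fits Stejskal–Tanner attenuation
$I(g) = I_0 \exp[-D (\gamma g \delta)^2 (\Delta - \delta/3)]$, with a
linearized $\ln I$ vs $g^2$ regression as a cross-check (the two agree to
$10^{-9}$ relative on noiseless data). The generator defaults mirror the
reference acquisition: 32 gradient amplitudes spanning 2–98% of 0.53 T/m and
$\Delta = 60$ ms. The gradient pulse width is rarely printed; the generator
defaults to $\delta = 4$ ms and always records all acquisition constants in
the output attributes so the fit never has to assume them.
`classify_oligomer()` calls monomer/dimer against externally predicted
reference coefficients by relative proximity, returning `"ambiguous"` at an
exact tie or when the estimate is more than 3 SE from even the nearer
reference.

## Rigid-body protein–DNA docking

The docking engine scores a pose by a knowledge-based, orientation-dependent
potential: for every protein residue $i$ and DNA base $j$ within a distance
cutoff, a tabulated energy $E^0_{ij}(r, \varphi)$ is read at the pair's
distance bin and angle bin and summed (`interaction_energy()`). The geometry
descriptors are:

* $r$ — distance from the residue's sidechain centroid (C$\alpha$ for
  glycine) to the base's ring centroid;
* $\varphi \in [0°, 90°]$ — angle between the sidechain direction
  (C$\alpha$ → sidechain centroid) and the base plane, fitted by least
  squares to the ring atoms.

These reference points are a documented choice (the published method does not
pin them down) and are deliberately simple and swappable. Default bins are
$r \in [0, 15]$ Å in 1 Å steps and $\varphi$ in 15° steps; bins are explicit
configuration of `orientation_potential()`.

`derive_potential()` builds the table from training complexes by inverse
Boltzmann, $E = -\ln[(N_\mathrm{obs} + p)/(N_\mathrm{ref} + p)]$ with
pseudo-count $p$ and a **distance-marginal reference**: the observed counts
of each (residue type, base type, distance) stratum spread uniformly over the
angle bins, so the table scores orientational preference at each distance.
This is a simplified variant of the published potential (whose exact
binning and reference state live in its own references); numeric equality
with the original PD-DOCK tables is not claimed, and empty bins are left
neutral (zero) rather than repulsive.

`mc_dock()` runs independent Metropolis searches over 6-DOF rigid poses:
random initial orientation on a sphere around the DNA, Gaussian translation
(1 Å) and rotation (5°) moves, geometric cooling from $T = 5$ to $0.1$ in
arbitrary energy units, 2500 steps per run by default, best-seen pose
returned per run (the reference workflow collects 200 runs). All schedule
parameters are arguments. Because the pure table energy has no excluded
volume, a soft-core clash penalty — quadratic in the overlap below 2.5 Å
heavy-atom distance — is added *during search only* and reported separately
from the table energy. On a translation-only toy with a smooth engineered
well, the MC best matches exhaustive 0.5 Å grid enumeration within 1%.

`cluster_poses()` reproduces the published post-processing: pairwise pose
distance is the C$\alpha$ RMSD of the protein after superposing the DNA
frames (poses from `mc_dock()` share the DNA frame, so coordinates compare
directly), complete-linkage clustering is cut at 3 Å — which bounds every
cluster's diameter by the cutoff — and clusters are ranked by the energy of
their lowest-energy member, with a top-$k$-mean alternative for
HADDOCK-style ranking. Which C$\alpha$ set enters the RMSD is unstated in
the source; all residues common to the poses are used.

Supporting operations: `superpose()` (Kabsch via SVD with the determinant
correction, cross-checked against bio3d), `interface_contacts()` (5 Å
interface atoms; hydrogen bonds as donor–acceptor heavy-atom pairs within
3.5 Å and donor angle ≥ 120°, conventional criteria, with a bundled
heavy-atom donor/acceptor heuristic), and `sasa()` (Shrake–Rupley with 960
Fibonacci sphere points; relative accessibility against extended Gly-X-Gly
reference areas — agreement with any specific external accessibility program
is not claimed).

## The synthetic-data module

Every generator is a pure function of its parameters and a seed (the global
RNG stream is untouched), and every generator at zero noise round-trips
through its fitting counterpart to $10^{-6}$ relative error. Defaults encode
the study conditions: 16-point titrations with 3 replicates and 2%-amplitude
Gaussian noise; pH 4.5–8.5 in 0.5 steps with $\sigma_f = 0.02$; decays on a
0.1 ns grid over 50 ns with a Gaussian IRF (center 2 ns, width 0.15 ns) and
Poisson noise at $10^4$ peak counts; the gradient ramp above; peak lists with
localized perturbations, optional missing-at-random bound peaks standing in
for exchange broadening; and `sim_toy_complex()`, an idealized fiber-model
B-DNA duplex (3.38 Å rise, 36° twist, planar bases) plus a poly-alanine
helix for exercising the docking engine.

What the generators do **not** emulate: thermophoresis physics (only the
dose-response shape), NMR line shapes and chemical exchange (only peak
positions and dropout), sequence-dependent DNA geometry, and dye
photophysics beyond two exponential components. Passing recovery tests
therefore demonstrate that the *estimators* are unbiased and correctly
calibrated under the stated statistical model — not that any particular
instrument's systematics are handled.

## Problem sizes and numerical choices

Recovery studies use 100 replicates for the titration, pH and diffusion
chains and 50 for the end-to-end lifetime pipeline (each of whose replicates
is a 12-waveform global fit); these sizes give sub-percent Monte Carlo error
on the recovered means while keeping the whole validation suite quick on a
single CPU. Nonlinear fits use Levenberg–Marquardt with tight tolerances
(`ftol`/`ptol` $10^{-14}$) and multistarts as described; lifetime fits are
canonicalized to $\tau_1 < \tau_2$, pH fits to $n > 0$; degenerate inputs
(all-zero IRF, equal references, $n = 0$ transitions, collinear point sets)
are rejected with explicit errors rather than producing NaN.

## Known limitations

* The biphasic model is additive; competition and stoichiometric models are
  out of scope.
* The docking potential is a simplified inverse-Boltzmann variant; absolute
  energies are in arbitrary units and not comparable to published PD-DOCK
  values.
* Time-resolved *anisotropy decay* (rotational correlation) is not fitted;
  polarized intensities enter only through the steady-state formula.
* `fraction_helix()` is a two-state reduction, valid only when an
  isodichroic point supports two-state behaviour.
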