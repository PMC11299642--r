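---
title: "Methods: radical-scavenging kinetics, dose-response and geometry in radscav"
author: "radscav authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radical-scavenging kinetics, dose-response and geometry in radscav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscav)
```

`radscav` post-processes electronic-structure results for antioxidant
candidates: given per-site reaction and activation free energies for the
three canonical scavenging mechanisms — formal hydrogen transfer (FHT),
radical adduct formation (RAF) and single electron transfer (SET) — it
screens, rates, diffusion-corrects and aggregates the channels, and handles
the experimental side (DPPH dose–response) and structural validation
(crystal vs. optimized geometry) of the same workflow. This vignette
explains the models, the defaults, and the choices made where the method
left room.

## Thermodynamic screening

A channel enters kinetic evaluation only when its reaction free energy is
strictly negative (`screen_channels`, threshold configurable, default 0).
The boundary case ΔG° = 0 is classified nonviable — a literal reading of
the spontaneity requirement; users probing sensitivity can move the
threshold. SET channels are screened on ΔG° only and are never evaluated
kinetically here: a meaningful SET rate constant needs a reorganization
energy (Marcus theory), which is outside this package's scope. Screening is
a pure filter: it never edits channel parameters, and the viable and
nonviable subsets partition the input in order.

## TST rate constants

Conventional transition-state theory for a bimolecular channel:

$$k_{\mathrm{act}} = \sigma\,\kappa\,\frac{k_B T}{h}
  \exp\!\left(-\Delta G^\ddagger / RT\right)$$

with ΔG‡ in kcal mol⁻¹ referenced to the 1 M standard state, so the rate is
in M⁻¹ s⁻¹ directly. Channel tables are assumed to carry 1 M-referenced
barriers already (the convention of tabulated solution-kinetics outputs);
`standard_state_1m()` applies the 1 atm → 1 M shift for users starting from
raw gas-phase thermochemistry. All constants live in `phys_constants()`
(2019 exact SI values); the prefactor at 298.15 K is 6.2124×10¹² s⁻¹.

The reaction-path degeneracy σ is **data, not logic**: the bundled
gas-phase table carries σ = 3 on the two alkyl H-transfer sites because
that is the only reading under which the published FHT rate constants are
reconstructed from their printed (ΔG‡, κ) pairs, while the lipid-phase FHT
row is only consistent with σ = 1. Since the convention used upstream is
not recoverable, σ is an explicit per-channel column with default 1, and
the fixtures record the implied values.

### Tunneling corrections

Three resolvable modes (`tunneling_spec`):

* **supplied** — the κ column is consumed as-is. This is the default and the
  only mode used for reproducing the bundled reference tables, whose κ
  derivation inputs are not published.
* **wigner** — κ = 1 + u²/24, u = hcν‡/k_BT. Cheap, valid for small u.
* **eckart** — the thermal average of the transmission probability through
  an asymmetric Eckart barrier parameterized by (V_f, V_r, ν‡):
  κ = e^{V_f/RT}/RT ∫ P(E) e^{−E/RT} dE. P(E) uses the standard
  two-parameter form with 2πV/hν‡ barrier parameters; it is zero below the
  product asymptote max(0, V_f − V_r).

Numerical notes for the Eckart integral: the integrand decays like
e^{−E/RT}, so integration is truncated at V_f + 40 RT; the transmission
switches from ≈0 to ≈1 over an energy window of order hν‡ around E = V_f,
so the adaptive quadrature (`stats::integrate`, relative tolerance 1e-10)
is run piecewise with breakpoints bracketing that window — without this the
near-classical limit (ν‡ → 0, a step function) defeats adaptive
subdivision. Hyperbolic functions are evaluated in log space to survive
barrier parameters of order 10⁵. Pieces whose value and error estimate are
below 1e-12 in κ units are accepted regardless of the integrator's
convergence message (they are tunneling tails that underflow). The
implementation is validated in the test suite against a 10⁵-point
fixed-grid trapezoid oracle (agreement ≤ 1e-6 relative) and against the
Wigner expansion in the small-curvature regime (≤ 5% at 300 cm⁻¹).

## Solution-phase (diffusion-corrected) kinetics

In a viscous medium the apparent rate constant is the Collins–Kimball
interpolation between activation and diffusion control,

$$k_{\mathrm{app}} = \frac{k_D\,k_{\mathrm{act}}}{k_D + k_{\mathrm{act}}},$$

with the encounter rate from Smoluchowski theory,
k_D = 4π R_AB (D_A + D_B) N_A (converted to M⁻¹ s⁻¹), and Stokes–Einstein
diffusion coefficients D = k_BT/6πηr. The gas phase is represented as
k_D = ∞, making `k_app = k_act` an exact identity rather than an
approximation with a large finite number.

Defaults for the pentyl ethanoate (lipid-mimetic) configuration: viscosity
η = 8.62×10⁻⁴ Pa s at 298.15 K from standard solvent tables; Stokes radii
4.0 Å for the ~390 g mol⁻¹ fused-ring ester solute and 2.0 Å for the
hydroxyl radical; reaction distance = sum of radii. These give
k_D ≈ 8.6×10⁹ M⁻¹ s⁻¹. A known reconstruction gap: back-solving the
bundled lipid-phase reference rates for the encounter rate implies
k_D ≈ 1.8–3.6×10⁹, which **no** radii can produce under plain
Stokes–Einstein at this viscosity (k_D ∝ 2 + r_a/r_b + r_b/r_a is bounded
below by ≈7.7×10⁹). The upstream diffusion inputs are evidently different
and unrecorded; the package therefore treats all diffusion parameters as
configuration, reproduces the published lipid *aggregation* (branching and
overall rate) from the published per-channel rates, and reproduces only the
slow C13 channel — where the correction is negligible by magnitude — from
first principles.

Branching ratios Γ_i = 100 k_app,i/Σk_app are kept at full precision
internally and rounded to one decimal only in reports; k_overall is the
plain sum. Γ is scale-invariant and sums to 100 within 1e-9 by
construction.

## DPPH dose–response

Scavenging percentage is SP(%) = 100 (OD₀ − OD₁)/OD₀, computed per well and
aggregated to mean ± sd per concentration (replicates weighted uniformly —
the assay reports a single dispersion on EC50, so no per-well weighting
scheme is recoverable). The EC50 logic:

* if the largest mean SP is below 50%, the plate is **censored**: no
  numeric estimate is defensible and the fit reports "> cap". The cap
  defaults to the largest tested concentration; it is a plate attribute
  (`censor_at`) because screens sometimes validate a narrower reporting
  range than they test — the bundled screen reports against 128 µg mL⁻¹
  although 265 µg mL⁻¹ was on the plate.
* otherwise a four-parameter logistic with bottom fixed at 0,
  SP(c) = top/(1 + (EC50/c)^hill), is fit by Levenberg–Marquardt least
  squares (`minpack.lm::nlsLM`) on the concentration means, with top
  bounded by 100. Starting values: top = min(100, max mean SP), EC50 = the
  smallest concentration reaching half of that, hill = 1. Non-monotone data
  are fit without error and flagged in the `monotone` diagnostic.

The 4PL-with-zero-bottom choice is the standard DPPH convention; censoring
is the only behaviour the bundled screen exhibits for the synthesized
series, so the numeric branch is validated by generate-and-refit instead
(noiseless plates recover EC50 to 1e-6 relative; at 2 SP points of noise
over 100 seeded plates the median relative error stays under 5% — both
asserted in the suite). Mass→molar conversion is the exact identity
µg mL⁻¹ / (g mol⁻¹) = mM.

## Geometry metrics

All metrics are internal-coordinate based and therefore rigid-motion
invariant (asserted to 1e-9 under random rotations + translations): bond
lengths, three-point angles, signed dihedrals (atan2 form), hydrogen-bond
D–H⋯A triples, and acute plane–plane angles. The mean plane is the
least-squares plane through the centroid, obtained from the SVD of the
centered coordinates (normal = smallest right singular vector); its r.m.s.
deviation equals √(λ_min/n) of the coordinate scatter matrix, which the
suite checks against both an eigendecomposition oracle and a brute-force
orientation grid search. Crystal-vs-optimized comparison
(`compare_geometries`) evaluates named bonds and angles in each structure
separately — no superposition — with percent deviations taken against the
reference (crystal) values. Comparison against a deposited crystal
structure requires user-exported XYZ coordinates (CIF parsing is out of
scope); the suite uses constructed synthetic geometries with known answers
instead, e.g. ring pairs built at a 57.83° inclination. One caveat
discovered while building the constructive oracles: a published
hydrogen-bond triple of the form (d_DH 0.93, d_HA 2.35, d_DA 3.383 Å)
cannot be realized by any coordinates — the first two sum to less than the
third — so the oracle fixes the two short distances and the 150° angle and
derives the donor–acceptor distance by the law of cosines.

## Synthetic data

The simulators generate the statistical structure the pipeline assumes, not
the physics that produces it:

* `simulate_channels` — ΔG° uniform on [−25, 15] kcal mol⁻¹ (spanning the
  strongly exothermic RAF sites through the endothermic SET-adjacent ones of
  the reference compound), ΔG‡ = 10 + 0.4 ΔG° + ε with ε ~ N(0, 1 kcal
  mol⁻¹) floored at 0 (a Bell–Evans–Polanyi-style linear free-energy
  relation — a modeling convenience, not a claim), κ log-uniform on
  [1.0, 5.2] (the range of the tabulated corrections), σ = 1.
* `simulate_plate` — 4PL scavenging with additive Gaussian noise in SP
  points (default 2), back-computed to absorbances around OD₀ = 0.8 and
  floored at 0 (the floor can truncate noise only where SP ≈ 100);
  ladder default 8/32/128/265 µg mL⁻¹, 3 replicates.
* `simulate_perturbed_geometry` — i.i.d. Cartesian Gaussian displacements.

All generators take an explicit seed and restore the caller's RNG state, so
fixtures are bit-reproducible and never leak randomness. What passing on
synthetic data does *not* show: real plates have heteroscedastic,
occasionally non-monotone responses (solubility, vehicle effects); real
channel sets correlate κ with barrier shape rather than drawing it
independently; real geometric error is bonded-structure-correlated, not
isotropic. The fixture tests on the bundled reference tables cover the
realistic-input side.

## Problem sizes and runtime choices

Reference-table reproductions run in milliseconds. The stochastic property
checks use 100 seeded plates (EC50 recovery), 50 plates (censoring
conservatism), 100 seeds (geometry perturbation bounds) and one 10⁴-channel
draw (screening fraction vs. the uniform law) — sizes at which the binomial
and median statistics under test are stable while the whole suite stays in
the seconds range.

## Known limitations

* SET is screened, never rated (no reorganization-energy model).
* The diffusion layer is plain Stokes–Einstein/Smoluchowski/Collins–Kimball:
  no ionic strength, cage escape, or pH-dependent speciation.
* Tunneling is one-dimensional (Wigner/Eckart); no variational TST or
  small-curvature corrections.
* Printed reference tables round ΔG‡ to 0.1 kcal mol⁻¹ and κ to 0.1, which
  alone permits ±9% discrepancies in rate reconstruction; one bundled row
  pair (C4/C19) even shares identical printed inputs with 10%-different
  printed rates, so exact row-wise recovery has a floor set by the source
  data, not by the implementation.
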