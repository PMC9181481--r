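---
title: "Methods: umbrella sampling, WHAM and interfacial free energy landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: umbrella sampling, WHAM and interfacial free energy landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`interfep` estimates one-dimensional free energy profiles G(z) of small
reactive solutes across a vacuum–water slab interface and condenses
them into the landmark quantities used to discuss where such species
accumulate: the gas→surface free energy ΔG_gs, the surface→liquid
barrier ΔG_sl, the hydration free energy ΔG_hydr, and the Boltzmann
concentration enhancements exp(−ΔG/RT). This vignette records the
model, the numerical choices and their rationale, and what the test
suite does and does not demonstrate.

## The synthetic interface model

A real study of this kind runs explicit-solvent MD in a tetragonal
slab (water centred at z = 0, vacuum on both sides) and restrains the
solute at staggered positions along z. `interfep` replaces the MD
engine with a parametric potential so that every downstream claim can
be checked against a known ground truth:

* two plateaus — `g_vacuum` (the gas-phase reference, 0 by convention)
  and `g_bulk` (which *is* the hydration free energy of the generated
  species);
* a switching region of half-width `w_switch` (default 0.2 nm) centred
  at `z_interface` (default 1.6 nm, i.e. a ~3.2 nm water slab in an
  8 nm box — the slab geometry is an assumption, chosen so vacuum,
  interface and bulk regions are each at least 1 nm wide inside
  |z| ≤ 3.5 nm);
* mirrored Gaussian interface wells at ±`z_interface` of width
  `w_interface` (default 0.25 nm), whose amplitude is calibrated by a
  monotone root find so that min G = `g_surface_min` exactly.

The switch is a C² compact-support quintic smoothstep rather than a
logistic sigmoid: with the default geometry a logistic product leaves
~10⁻³-relative leakage at z = 0 and at the box edge, while the
compact-support form attains `G(0) = g_bulk` and the vacuum asymptote
exactly, which the invariants of the type demand at 10⁻⁶ kJ/mol.

The model is even in z by construction; the surrogate treats each
restrained solute independently (the multi-solute trick of slab
studies is a sampling-efficiency device; at ≥1 nm separation the
solutes are taken as uncoupled).

## Window placement and sampling

`window_scheme(7, 1.0, 12, -3.5, 3.5)` reproduces the canonical
staggered design: 7 simultaneous positions 1 nm apart, replicated 12
times with per-replicate offsets of 1/12 nm, giving 84 unique centres
that tile the range uniformly. With 20 replicates the offset is
exactly 0.05 nm; choosing the replicate count recovers either printed
description of the window shift. The harmonic bias sd at
k = 2000 kJ mol⁻¹ nm⁻² and 300 K is √(RT/k) ≈ 0.035 nm, ≥40% of the
1/12 nm spacing, which guarantees histogram overlap of the *pooled*
set (but not of any subset — see "Combining replicates").

Windows are sampled by Euler–Maruyama overdamped Langevin dynamics on
G(z) + ½k(z − z₀)²:

z ← z − (D/RT)·G'_tot(z)·dt + √(2·D·dt)·ξ.

Time is in reduced units; only the stationary distribution matters for
WHAM, so no mapping to nanoseconds is claimed. Defaults and why:

* `dt = 2.5e-5`, `diffusion = 1` — the per-step contraction of the
  biased harmonic mode is a = D·k·dt/RT ≈ 0.02, so the Euler
  stationary variance is inflated by only ~1% (the discretization bias
  of the scheme is O(a)); the stability guard √(2·D·dt) < w_interface/5
  rejects settings that could hop across the interface well in one
  step.
* `stride = 100` — about one relaxation time (1/a = 50 steps) between
  recorded samples, so retained samples are effectively independent.
* `n_steps = 1.2e7` per window, with the leading third discarded as
  equilibration (the last-two-thirds convention of 6 ns windows
  analysed over their final 4 ns), leaving 8×10⁴ near-independent
  samples per window. This depth was chosen because the
  vacuum-to-bulk free energy difference accumulates statistical error
  across the ~40-window overlap chain like a random walk; at this
  depth the landmark errors of the 84-window recovery runs are
  ~0.1 kJ/mol, comfortably inside the 0.3 kJ/mol recovery band the
  test suite asserts.
* Seeding is counter-based (`seed + window index`), so windows are
  reproducible independently of execution order; the Gaussian
  increments are drawn from R's RNG.
* A trajectory leaving |z| > z_max + 1 nm aborts with an error naming
  the window (with the defaults this indicates divergence, not
  physics).

## WHAM

`wham_solve()` iterates the standard self-consistent equations on
uniform bins (default 0.05 nm, matching the finest window-shift
granularity of the design) and reports −RT ln P with empty bins left
`NA` — never interpolated; downstream landmark extraction tolerates
holes. Numerical choices:

* convergence at max_i |Δf_i| < 10⁻⁷ kJ/mol, at most 10⁵ sweeps;
* Anderson (direct-inversion) acceleration with history depth 5: the
  plain iteration converges linearly and can need >10⁵ sweeps on
  84-window problems, the accelerated solve typically ~2×10³; the
  accelerated fixed point is verified in the tests against a naive
  double-loop iteration to 10⁻⁸ kJ/mol;
* the solver is deterministic (f initialised to 0, or warm-started);
* adjacent windows without a shared occupied bin trigger a warning; a
  disconnected overlap graph is an error that names the gap, because
  WHAM can only determine free energies up to a constant per connected
  component;
* the histogram range defaults to the scheme coverage [−3.5, 3.5] nm:
  bins beyond the outermost centres would be populated only by
  single-count tails; out-of-range samples are counted and reported.

The profile is referenced by subtracting the mean over occupied bins
with |z| in the vacuum region (default [3.0, 3.5] nm), fixing the
gas-phase zero, then symmetrized, g(z) ← ½(g(z) + g(−z)), since the
two slab interfaces are physically equivalent; symmetrization is
idempotent and roughly halves the variance.

## Bootstrap errors

Uncertainty is quantified at the window level, mirroring the spread
among a study's independent replicate profiles. Discrete resampling
with replacement, however, interacts badly with stiff restraints: a
resample of the 84 windows routinely omits three or more consecutive
centres, opening ~0.33 nm gaps that are ~5 bias standard deviations
wide — the overlap graph disconnects and the resample cannot be
solved. `bootstrap_profile()` therefore uses the Bayesian bootstrap:
each resample draws flat-Dirichlet weights over windows (the smooth
asymptotic equivalent of multinomial resampling) and rescales each
window's histogram and sample count. Every window keeps positive
weight, so each resample has exactly the full data's overlap graph.
Resamples are warm-started from the full-data window free energies,
referenced and symmetrized exactly like the point estimate, and the
per-bin sd across ≥20 resamples (default 50) is the reported standard
error.

## Landmarks, enhancements, Henry constants

On the symmetrized, vacuum-referenced profile (z ≥ 0 half):

* ΔG_gs = min g over the interface search region (default
  |z| ∈ [0.8, 2.6] nm); ties resolve to the smaller |z|;
* ΔG_hydr = unweighted mean g over the bulk plateau region (default
  |z| ∈ [0, 0.7] nm);
* ΔG_sl = ΔG_hydr − ΔG_gs, a *definition*, so the additive identity
  ΔG_gs + ΔG_sl = ΔG_hydr holds to machine precision — this matches
  the published landmark table, where the identity holds exactly for
  all twelve species, and distinguishes ΔG_sl from a transition-state
  barrier height. The regions are configuration-exposed because no
  standard convention fixes where plateaus are read.

Concentration enhancements are exp(−ΔG/RT) at the profile temperature
(300 K, the thermostat temperature — not 298.15 K). Experimental
hydration free energies come from solubility Henry constants via
H_cc = H_cp·R·T (R in J mol⁻¹ K⁻¹) and ΔG = −RT ln H_cc at 298.15 K,
the reference temperature of the Henry compilations; the two
temperatures are deliberately distinct and always explicit. Species
are classified hydrophilic iff ΔG_hydr < 0; an exact zero is
classified hydrophobic with a warning.

Comparisons against printed reference values use, for each enhancement
cell, 1% relative tolerance *plus* half a unit in the last printed
decimal: the sensitivity of exp(−ΔG/RT) to the ±0.005 kJ/mol rounding
of a two-decimal free energy is ~0.2%, but for coarsely printed values
(e.g. 4.8, 0.20) the print rounding itself exceeds 1%, and no
implementation can do better from the printed inputs.

## Combining replicates

The pipeline's default (`combine = "pooled"`) solves one WHAM over all
windows of all replicates — statistically efficient and
well-conditioned. The alternative reading of "averaging N individual
profiles", `combine = "mean"`, solves WHAM per replicate, references
each profile, and averages. With the study restraint this mode is
structurally unavailable: one replicate's 7 windows are 1 nm apart
(~28 bias sd), their histograms share no occupied bins, and the
per-replicate solve is disconnected — the pipeline isolates this as a
per-species failure. Both modes are exposed; their agreement is
demonstrated in the tests with a soft restraint (k = 20) where both
are defined.

## What the tests show — and what they cannot

The suite demonstrates, end to end: exact window bookkeeping; sampler
correctness (restrained variance RT/k, Boltzmann fidelity of long
chains against the generating surface, mirror symmetry in
distribution); WHAM correctness against independent oracles
(analytic single-window collapse, naive double-loop fixed point);
recovery of generator landmarks from 84 windows to 0.3 kJ/mol with a
null (flat-surface) control bounded by 3 bootstrap SE; and exact
reproduction of the published landmark arithmetic, enhancements,
and Henry conversions from the printed inputs.

It does *not* validate force fields, water models, finite-size or
cutoff effects, solute flexibility or orientation, interfacial
capillary waves, or aqueous reaction chemistry (speciation of
NO₂⁻/NO₃⁻/ONOO⁻ and acid dissociation are outside the model): the
synthetic generator emulates the *shape* of interfacial profiles with
known landmarks, not the molecular physics that produces them.
Explicit-solvent profiles are not reproducible at desk scale; the
recovery suite plus the printed-table arithmetic are the quantitative
surface of this package.

Problem sizes used by the default test run: 84 windows × 1.2×10⁷
steps for the recovery check (~2 min), 84 × 3×10⁶ for the flat null
with 50 bootstrap resolves (~1 min), and seconds-scale fixtures
elsewhere.

## Known limitations

* ΔG_gs is a minimum over noisy bins and thus biased slightly low at
  shallow sampling; the plateau mean ΔG_hydr is unbiased.
* The Euler–Maruyama stationary distribution carries O(D·k·dt/RT)
  discretization bias; halve `dt` to check convergence in `dt` if in
  doubt.
* Window-level bootstrap SE assumes windows are independent — true in
  the surrogate, approximate for real MD pulls from a shared box.
* The total-sampling bookkeeping of the original multi-replicate
  design (windows × replicates × nanoseconds) is not reproduced; the
  surrogate has no physical clock.
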