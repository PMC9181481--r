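# interfep

Free energy profiles of plasma-generated reactive oxygen and nitrogen
species (RONS) across the vacuum–water interface, from umbrella
sampling to a Table-of-landmarks summary.

## The problem

Cold atmospheric plasmas enrich water with reactive species (OH, HO₂,
H₂O₂, O₃, NO, NO₂, the HNO₂/HNO₃/ONOOH acids, N₂O₄ — collectively
RONS), producing *plasma-activated water*. Where each species
accumulates — gas phase, the vacuum–water interface, or bulk water — is
governed by its free energy profile G(z) along the slab normal z.
`interfep` provides a desk-scale, fully testable version of the
standard computational route to these profiles:

1. **Umbrella sampling** — harmonic restraints U_i(z) = ½k(z − z_i)²
   (k = 2000 kJ mol⁻¹ nm⁻²) at staggered centres: 7 positions spaced
   1 nm, replicated 12 times with 1/12 nm offsets over z ∈ [−3.5, 3.5]
   nm, i.e. 7 × 12 = 84 windows. Because running an explicit-solvent MD
   engine is out of scope, windows are sampled by overdamped Langevin
   dynamics on a parametric interface potential with known ground truth
   (vacuum plateau, Gaussian interface wells, bulk plateau).
2. **WHAM** — the weighted histogram analysis method combines the
   biased window histograms h_i(b) into one unbiased profile by
   iterating
   P(z_b) = Σᵢ h_i(b) / Σᵢ N_i exp((f_i − U_i(z_b))/RT),
   f_i = −RT ln Σ_b P(z_b) exp(−U_i(z_b)/RT),
   to self-consistency (Anderson-accelerated), followed by vacuum
   referencing, symmetrization about z = 0, and window-level
   (Bayesian) bootstrap errors.
3. **Landmarks** — from the referenced profile:
   ΔG_gs (gas → surface: the interface minimum), ΔG_hydr (gas → bulk:
   the bulk plateau), ΔG_sl = ΔG_hydr − ΔG_gs (surface → liquid
   barrier); Boltzmann concentration enhancements exp(−ΔG/RT) at the
   surface and in bulk; hydrophilic/hydrophobic classification by the
   sign of ΔG_hydr; and experimental hydration free energies from
   Henry's-law solubility constants, −RT ln(H_cp·R·T).

All user-facing functions take and return tidy data frames, so the
whole pipeline composes with the pipe; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Two synthetic species whose generator landmarks are set to the
published H₂O₂ and O₃ values, run at reduced sampling
(1.2×10⁶ Langevin steps per window instead of the default 1.2×10⁷):

```r
library(interfep)
cfg <- pipeline_config(
  species = list(
    list(name = "H2O2-like",
         generator = list(g_bulk = -35.76, g_surface_min = -36.21)),
    list(name = "O3-like",
         generator = list(g_bulk = 3.98, g_surface_min = -3.94),
         henry = list(value = 1.0e-4))),
  base_seed = 20260922,
  sampler = list(dt = 2.5e-5, diffusion = 1, n_steps = 1.2e6, stride = 100),
  n_boot = 0)
r <- run_pipeline(cfg)
r$report
#>     species   dg_gs  dg_sl dg_hydr enhancement_surface enhancement_bulk hydro_class
#> 1 H2O2-like -36.349 0.1413 -36.208           2.132e+06        2.015e+06 hydrophilic
#> 2   O3-like  -4.504 7.6180   3.114           6.084e+00        2.870e-01 hydrophobic
```

Reading the first row: the recovered gas→surface free energy is
−36.3 kJ/mol (truth −36.21), the surface→liquid barrier is essentially
zero, and the hydration free energy −36.2 kJ/mol (truth −35.76, within
the statistical error of this shortened run), so the species is
classified hydrophilic and its equilibrium concentration at the
interface and in bulk is ~2×10⁶-fold higher than in the gas phase. The
O₃-like row shows the hydrophobic pattern: a shallow interface minimum,
an 7.6 kJ/mol barrier into the liquid, bulk enhancement below 1. At the
default sampling depth the recovered landmarks agree with the
generator to better than 0.3 kJ/mol (that check is
`tests/testthat/test-acceptance.R`).

Individual stages are plain functions on data frames:

```r
m   <- potential_model(g_bulk = -4, g_surface_min = -10)
win <- sample_windows(m, window_scheme(7, 1, 12, -3.5, 3.5),
                      force_constant = 2000,
                      cfg = sampler_config(seed = 1)) |>
  discard_equilibration()
prof <- build_histograms(win, bin_width = 0.05) |>
  wham_solve() |>
  set_reference() |>
  symmetrize()
extract_landmarks(prof)
concentration_enhancement(-22.04, 300)
#> [1] 6877.49
```

A thin command-line wrapper over the same functions lives at
`inst/cli/interfep.R` (subcommands `simulate`, `wham`, `landmarks`,
`henry`, `report`, `validate`).

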