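# walkerkinetics

Stepping kinetics of cartwheeling DNA walkers under soft steric
confinement.

A DNA walker steps along a track of single-stranded footholds: the
walker-foothold duplex pivots about its tether and its free end must
find and react with the base of the next foothold. Because the duplex is
shorter than the persistence length of dsDNA, the free end samples a
hemispherical shell rather than a Gaussian coil, and because strand
displacement is slow, stepping is reaction-limited: the rate is set by
how often the free end is found near the target. Two track
modifications prune the wasted conformational space -- a stiff dsDNA
**tail** on the foothold that suppresses out-of-plane motion, and origami
**trench** walls that suppress lateral motion. This package quantifies
what those modifications buy.

For each confinement scenario (`baseline`, `tail`, `trench`,
`trench_series`, `combined`) the package provides:

- the analytic free-end density
  (e.g. baseline `P(r) = z exp(-βk/2 (‖r‖ - L)²)`; slit sine series for
  tails; cosine factor for trenches), its normalization and 1-D
  marginals;
- the mean-field radial density `P_eq(ρ)` about a target at `(a, 0, 0)`
  and the effective potential `βU(ρ) = -ln[ρ² P_eq(ρ)]`;
- the mean stepping time via the Szabo relation
  `τ = (1/D)∫ e^{βU} [∫ e^{-βU}]² dρ + e^{βU(ε)}/κ`
  and stepping rates normalized by the baseline, swept over the
  tether-target distance `a` and contact distance `ε`;
- synthetic free-end point clouds (i.i.d. rejection samples), KS
  distribution checks, parameter fitting against cloud marginals, the
  90%-coverage minimal annulus, and mode detection (bistability);
- an independent Brownian-dynamics first-passage oracle with a
  partially absorbing contact boundary;
- an end-to-end pipeline runner (`run_pipeline()`) plus a thin CLI
  (`inst/cli/walker-steps.R`), and a minimal reader for oxDNA-style
  configuration/topology files.

Everything is tidyverse-shaped: data frames in, tibbles out,
`autoplot()` methods for clouds, potentials and rate tables, and
`tidy()`/`glance()` for fitted objects.

## Worked example

The canonical 36-bp complex (`βk = 5 nm⁻²`, `L = 11.5 nm`) with a 12-bp
tail (`βk' = 0.75 nm⁻²`, `z_max = 12.5 nm`), reaction-limited kinetics
(`D = 50 µm²/s`, `κ = 1 nm/s`), target at `a = 11.5 nm`, contact
distance `ε = 2 nm`:

```r
library(walkerkinetics)

p    <- confinement_params(beta_k = 5, L = 11.5,
                           beta_k_prime = 0.75, z_max = 12.5)
kin  <- kinetic_params(D = 5e7, kappa = 1)     # nm²/s, nm/s
geom <- target_geometry(a = 11.5, epsilon = 2)

szabo_mfpt(radial_potential("baseline", p, geom), kin)
#> # A tibble: 1 × 3
#>     tau tau_diffusion tau_reaction
#>   <dbl>         <dbl>        <dbl>
#> 1  617.     0.0000205         617.

normalized_rate("tail", p, kin, geom)
#> [1] 4.167663
```

The baseline stepping time is ~617 s and almost entirely rebound time
(`tau_reaction`), confirming the reaction-limited regime; adding the
tail at this target distance speeds stepping up ~4.2-fold. Sweeping the
target distance:

```r
tab <- sweep_rates(c("tail", "trench"), confinement_params(
         beta_k = 5, L = 11.5, beta_k_prime = 0.75, z_max = 12.5,
         h_max = 9), kin, a_grid = seq(8, 16, by = 0.25), epsilon = 2)
max(tab$normalized_rate[tab$scenario == "tail"])
#> [1] 4.535468
max(tab$normalized_rate[tab$scenario == "trench"])
#> [1] 3.185049
autoplot(tab)
```

A tailed foothold is worth about a fourfold rate gain, a trench about
threefold, and both gains shrink as the contact distance `ε` grows.
Combining tail and trench makes the system bistable: the combined-
scenario `x`-marginal has two symmetric modes
(`detect_modes(marginal_density("combined", "x", ...))`).

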